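#' Demographic model for coalescent simulation and inference
#'
#' Describes the population history used both to simulate genealogies and as
#' the prior in genealogy inference: a diploid effective population size
#' `n_e`, optional exponential growth that started `growth_onset_generations`
#' generations before the present at per-generation rate `growth_rate_alpha`,
#' and an optional clean split of the population `split_time_generations`
#' generations ago into `n_subpops_beta` subpopulations with no subsequent
#' migration. Looking backward in time the population size is
#' `N(t) = n_e * exp(-alpha * min(t, t_onset))`: the present-day size is
#' `n_e` and the ancestral (pre-onset) size is constant at
#' `n_e * exp(-alpha * t_onset)`. Under structure, each subpopulation holds
#' an equal share of `n_e` at sampling time and the ancestral population
#' after the (backward) merge has constant size `n_e`.
#'
#' @param n_e diploid effective population size (individuals).
#' @param growth_rate_alpha exponential growth rate per generation (e.g.
#'   0.05 for 5\% growth); 0 disables growth.
#' @param growth_onset_generations generations before present at which
#'   growth started (converted from years via [years_to_generations] if the
#'   scenario is given in years).
#' @param n_subpops_beta number of subpopulations (1 = panmictic).
#' @param split_time_generations time of the clean split, generations before
#'   present (required when `n_subpops_beta > 1`).
#' @param subpop_hap_counts integer vector of haplotypes sampled per
#'   subpopulation (length `n_subpops_beta`); may be left `NULL` for a
#'   panmictic model.
#' @param generation_time_years years per generation used to convert
#'   year-based times; the default 25 maps 5000 years to 200 generations and
#'   50,000 years to 2000 generations.
#' @return an object of class `demography_model`.
#' @export
demography_model <- function(n_e = 10000,
                             growth_rate_alpha = 0,
                             growth_onset_generations = 0,
                             n_subpops_beta = 1L,
                             split_time_generations = 0,
                             subpop_hap_counts = NULL,
                             generation_time_years = 25) {
  if (n_e <= 0) stop("n_e must be positive")
  if (growth_rate_alpha < 0) stop("growth_rate_alpha must be >= 0")
  if (growth_rate_alpha > 0 && growth_onset_generations <= 0)
    stop("growth needs a positive growth_onset_generations")
  n_subpops_beta <- as.integer(n_subpops_beta)
  if (n_subpops_beta < 1L) stop("n_subpops_beta must be >= 1")
  if (n_subpops_beta > 1L) {
    if (split_time_generations <= 0)
      stop("a structured model needs split_time_generations > 0")
    if (!is.null(subpop_hap_counts) &&
        length(subpop_hap_counts) != n_subpops_beta)
      stop("subpop_hap_counts must have one entry per subpopulation")
    if (growth_rate_alpha > 0 &&
        growth_onset_generations >= split_time_generations)
      stop("growth onset must predate the split looking backward ",
           "(growth_onset_generations < split_time_generations)")
  }
  structure(list(n_e = n_e,
                 growth_rate_alpha = growth_rate_alpha,
                 growth_onset_generations = growth_onset_generations,
                 n_subpops_beta = n_subpops_beta,
                 split_time_generations = split_time_generations,
                 subpop_hap_counts = subpop_hap_counts,
                 generation_time_years = generation_time_years),
            class = "demography_model")
}

#' Convert calendar years to generations
#'
#' @param years time in years.
#' @param generation_time_years years per generation (default 25).
#' @export
years_to_generations <- function(years, generation_time_years = 25) {
  years / generation_time_years
}

#' Convert a time in generations to internal coalescent units (2 N_e)
#' @noRd
generations_to_units <- function(generations, n_e) generations / (2 * n_e)

#' Simulation configuration
#'
#' Holds the sampling design of a simulated cohort: total sample size, the
#' fixed number of segregating sites, segment length, per-site mutation
#' rate, the study/reference split and the fraction of sites treated as
#' directly measured. Defaults mirror the baseline scenario: 1000 haplotypes
#' carrying 100 polymorphic sites over a 20 kb segment with
#' mu = 1.25e-8 per site per generation, 80\% of haplotypes assigned to the
#' study population and 10\% of sites directly measured.
#'
#' @param n_haplotypes total number of sampled haplotypes.
#' @param n_sites_S fixed number of polymorphic sites.
#' @param seq_length_bp_L segment length in base pairs.
#' @param mu_per_site per-site per-generation mutation rate (used to derive
#'   the scaled mutation rate theta = 4 N_e mu L for inference defaults).
#' @param study_fraction fraction of haplotypes assigned to the study
#'   population; the remainder forms the external reference panel.
#' @param measured_fraction fraction of sites assumed directly measured.
#' @param seed_sim seed for haplotype simulation.
#' @param seed_sites seed for the random selection of measured sites.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_haplotypes = 1000L,
                       n_sites_S = 100L,
                       seq_length_bp_L = 20000L,
                       mu_per_site = 1.25e-8,
                       study_fraction = 0.8,
                       measured_fraction = 0.1,
                       seed_sim = 1L,
                       seed_sites = 1L) {
  if (study_fraction <= 0 || study_fraction >= 1)
    stop("study_fraction must lie strictly between 0 and 1")
  if (measured_fraction <= 0 || measured_fraction > 1)
    stop("measured_fraction must lie in (0, 1]")
  if (n_sites_S < 1) stop("n_sites_S must be >= 1")
  if (n_sites_S > seq_length_bp_L)
    stop("cannot place more polymorphic sites than base pairs")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_sites_S = as.integer(n_sites_S),
                 seq_length_bp_L = as.integer(seq_length_bp_L),
                 mu_per_site = mu_per_site,
                 study_fraction = study_fraction,
                 measured_fraction = measured_fraction,
                 seed_sim = as.integer(seed_sim),
                 seed_sites = as.integer(seed_sites)),
            class = "sim_config")
}

## ---- population-size trajectories (backward time, in generations) -------

## Relative size nu(t) = N(t)/N_ref at t generations before present for a
## panmictic (or single-deme) population growing exponentially since onset.
rel_size_at <- function(t_gen, alpha, t_onset) {
  exp(-alpha * pmin(t_gen, t_onset))
}

## Integrated pair-coalescence hazard between two times (generations),
## for one deme with present relative share `share` of N_e and growth
## (alpha, t_onset); hazard in internal units of 2*N_e generations is
## 1/(share * nu(t)). Returns the integral of 1/(share*nu) dt in
## *generation* units; divide by 2*N_e for internal units.
integrated_inverse_size <- function(t0, t1, alpha, t_onset, share = 1) {
  stopifnot(t1 >= t0)
  if (alpha == 0) return((t1 - t0) / share)
  lo <- min(t0, t_onset); hi <- min(t1, t_onset)
  acc <- 0
  if (hi > lo) acc <- acc + (exp(alpha * hi) - exp(alpha * lo)) / alpha
  if (t1 > t_onset) acc <- acc + (t1 - max(t0, t_onset)) * exp(alpha * t_onset)
  acc / share
}

## Inverse of integrated_inverse_size in its upper limit: smallest t1 >= t0
## with integral == target. Used to draw waiting times by inversion.
invert_inverse_size <- function(t0, target, alpha, t_onset, share = 1) {
  target <- target * share
  if (alpha == 0) return(t0 + target)
  if (t0 < t_onset) {
    full <- (exp(alpha * t_onset) - exp(alpha * t0)) / alpha
    if (target <= full)
      return(log(exp(alpha * t0) + alpha * target) / alpha)
    target <- target - full
    t0 <- t_onset
  }
  t0 + target * exp(-alpha * t_onset)
}
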