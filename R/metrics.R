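#' Genotype concordance
#'
#' Rate of correctly imputed genotypes over all study individuals and all
#' imputed variants: the fraction of entries where the best-guess genotype
#' equals the truth.
#'
#' @param truth,best_guess integer matrices (individuals x variants) of
#'   genotypes in 0/1/2, identical dimensions.
#' @return the concordance rate in [0, 1].
#' @export
genotype_concordance <- function(truth, best_guess) {
  truth <- as.matrix(truth); best_guess <- as.matrix(best_guess)
  if (!all(dim(truth) == dim(best_guess)))
    stop("truth and best-guess matrices must have identical dimensions")
  mean(truth == best_guess)
}

#' Imputation quality score (IQS)
#'
#' Chance-corrected agreement between true and imputed genotypes of one
#' variant, in Cohen's-kappa form: with the 3x3 truth-vs-imputed
#' contingency table, `P_o` is the observed agreement (trace / n), `P_e`
#' the agreement expected under independence of the margins
#' (`sum_g row_g * col_g / n^2`), and IQS = (P_o - P_e) / (1 - P_e).
#' An IQS of 1 is perfect imputation, 0 corresponds to random genotype
#' assignment given the allele frequency, negative values are worse than
#' chance. When `P_e = 1` (both margins concentrated on one genotype) the
#' score is undefined and `NA` is returned.
#'
#' @param truth,best_guess integer vectors of genotypes (0/1/2) for one
#'   variant across individuals.
#' @return the IQS, or `NA` when undefined.
#' @export
iqs <- function(truth, best_guess) {
  if (length(truth) != length(best_guess))
    stop("truth and best-guess vectors must have equal length")
  n <- length(truth)
  tab <- table(factor(truth, levels = 0:2),
               factor(best_guess, levels = 0:2))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Minor-allele-frequency category
#'
#' Boundary-inclusive mapping used to stratify results: rare
#' (0 < MAF <= 0.01), low-frequency (0.01 < MAF <= 0.05), common
#' (MAF > 0.05); MAF = 0 marks a monomorphic variant, which is excluded
#' from all analyses.
#'
#' @param maf minor allele frequency in [0, 0.5] (vectorised).
#' @return character vector with levels "monomorphic", "rare",
#'   "low-frequency", "common".
#' @export
maf_category <- function(maf) {
  if (any(maf < 0 | maf > 0.5))
    stop("minor allele frequencies must lie in [0, 0.5]")
  out <- character(length(maf))
  out[maf == 0] <- "monomorphic"
  out[maf > 0 & maf <= 0.01] <- "rare"
  out[maf > 0.01 & maf <= 0.05] <- "low-frequency"
  out[maf > 0.05] <- "common"
  out
}

#' Mean and normal-approximation 95\% confidence interval over replicates
#'
#' @param values numeric vector of per-replicate statistics.
#' @return list with `mean`, `ci_lo`, `ci_hi` (the interval is
#'   mean +- 1.96 sd/sqrt(n); `NA` bounds when fewer than 2 values).
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  if (length(values) < 2L)
    return(list(mean = m, ci_lo = NA_real_, ci_hi = NA_real_))
  half <- 1.96 * stats::sd(values) / sqrt(length(values))
  list(mean = m, ci_lo = m - half, ci_hi = m + half)
}

#' Compare two methods' replicate statistics by t and F tests
#'
#' Two-sample t-test (equal variances) on the means and F-test on the
#' variances, both two-sided. With degenerate zero-variance inputs the
#' t-test p-value falls back to 1 when the means are equal and 0 otherwise,
#' and the F-test p-value to 1 when both variances are zero.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @return list with `t_p` and `f_p`.
#' @export
compare_methods <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least 2 values per method")
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    t_p <- if (mean(values_a) == mean(values_b)) 1 else 0
    return(list(t_p = t_p, f_p = 1))
  }
  t_p <- stats::t.test(values_a, values_b, var.equal = TRUE)$p.value
  f_p <- if (va == 0 || vb == 0) 0
         else stats::var.test(values_a, values_b)$p.value
  list(t_p = t_p, f_p = f_p)
}

#' Evaluate one imputation run against the held-out truth
#'
#' Builds true genotypes of the study individuals at the masked sites from
#' the cohort's truth matrix, excludes variants monomorphic in the pooled
#' truth (study + reference haplotypes), stratifies the rest by MAF
#' computed from the pooled truth, and reports concordance and mean
#' per-variant IQS for each category and overall.
#'
#' @param cohort a `cohort`.
#' @param posterior a `genotype_posterior` for this cohort.
#' @return data.frame with columns `maf_category` ("all", "rare",
#'   "low-frequency", "common"), `n_variants`, `concordance`, `iqs`.
#' @export
evaluate_imputation <- function(cohort, posterior) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(posterior, "genotype_posterior"))
  A <- cohort$haps$alleles
  masked <- posterior$sites
  pairs <- posterior$individuals
  truth <- A[pairs[, 1L], masked, drop = FALSE] +
    A[pairs[, 2L], masked, drop = FALSE]
  maf <- pmin(colMeans(A), 1 - colMeans(A))[masked]
  cat_of <- maf_category(maf)
  keep <- cat_of != "monomorphic"
  res <- list()
  groups <- list(all = keep,
                 rare = cat_of == "rare",
                 `low-frequency` = cat_of == "low-frequency",
                 common = cat_of == "common")
  for (g in names(groups)) {
    idx <- which(groups[[g]])
    if (!length(idx)) {
      res[[g]] <- data.frame(maf_category = g, n_variants = 0L,
                             concordance = NA_real_, iqs = NA_real_)
      next
    }
    conc <- genotype_concordance(truth[, idx, drop = FALSE],
                                 posterior$best[, idx, drop = FALSE])
    iq <- mean(vapply(idx, function(j) {
      iqs(truth[, j], posterior$best[, j])
    }, 0), na.rm = TRUE)
    res[[g]] <- data.frame(maf_category = g, n_variants = length(idx),
                           concordance = conc, iqs = iq)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
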