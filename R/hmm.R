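#' Parameters of the haplotype-copying HMM
#'
#' Diploid Li-Stephens model: each individual's genotype vector is an
#' imperfect mosaic of an ordered pair of reference haplotypes; switching
#' of the copied pair along the sequence is governed by the recombination
#' map, mismatches by the per-site miscopy probability epsilon. With the
#' default `miscopy_epsilon = NULL` the standard population-genetic choice
#' is used at run time: epsilon = theta~ / (2 (theta~ + N)) with
#' theta~ = 1 / sum_{i=1}^{N-1} 1/i for a panel of N haplotypes.
#'
#' @param miscopy_epsilon per-site probability that an emitted allele
#'   differs from the copied haplotype's allele (0 <= eps < 0.5), or `NULL`
#'   for the N-dependent default.
#' @param rho_map per-interval scaled recombination rates (length L-1, or a
#'   single value recycled); 0 disables switching, the setting used in all
#'   simulation comparisons.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(miscopy_epsilon = NULL, rho_map = 0) {
  if (!is.null(miscopy_epsilon) &&
      (miscopy_epsilon < 0 || miscopy_epsilon >= 0.5))
    stop("miscopy_epsilon must lie in [0, 0.5)")
  if (any(rho_map < 0)) stop("rho_map must be non-negative")
  structure(list(miscopy_epsilon = miscopy_epsilon, rho_map = rho_map),
            class = "hmm_params")
}

## Li-Stephens default epsilon for a panel of N haplotypes
default_epsilon <- function(n_ref) {
  th <- 1 / sum(1 / seq_len(max(n_ref - 1L, 1L)))
  th / (2 * (th + n_ref))
}

#' Genotype emission probability of the copying model
#'
#' Each of the two copied alleles flips independently with probability
#' epsilon; the emission is the probability of observing genotype `g` given
#' the pair of copied alleles. A missing genotype (`NA`) has probability 1
#' (it is marginalised out).
#'
#' @param g observed genotype (0, 1, 2 or `NA`).
#' @param copied_alleles length-2 binary vector of copied alleles.
#' @param epsilon miscopy probability.
#' @return the emission probability.
#' @export
emission_prob <- function(g, copied_alleles, epsilon) {
  if (is.na(g)) return(1)
  if (!(g %in% 0:2)) stop("genotype must be 0, 1, 2 or NA")
  s <- sum(copied_alleles)
  emission_table(epsilon)[g + 1L, s + 1L]
}

## 3 x 3 table P(g | s) with g = observed genotype (rows 0..2) and
## s = number of derived alleles among the copied pair (cols 0..2)
emission_table <- function(eps) {
  q <- 1 - eps
  matrix(c(q * q,     q * eps,      eps * eps,
           2 * q * eps, q * q + eps * eps, 2 * q * eps,
           eps * eps, q * eps,      q * q),
         nrow = 3L, byrow = TRUE,
         dimnames = list(g = 0:2, s = 0:2))
}

#' Impute one diploid genotype vector with the copying HMM
#'
#' Computes the posterior distribution over the missing genotypes of one
#' individual given the reference panel. With rho = 0 the copied pair of
#' haplotypes is constant along the sequence, and the posterior is an exact
#' sum over all N^2 ordered pairs weighted by their emission product at the
#' measured sites ("enumerate"). With positive recombination the pair
#' switches along the sequence and the forward-backward algorithm over the
#' N^2 pair states is used; at rho = 0 the two code paths agree exactly.
#'
#' @param G_i integer genotype vector of length L with `NA` at missing
#'   (to-be-imputed) sites.
#' @param H reference panel matrix (N haplotypes x L sites, binary).
#' @param params an [hmm_params].
#' @param method "auto" picks enumeration at rho = 0 and forward-backward
#'   otherwise.
#' @return list with `probs` (3 x L matrix of genotype posteriors at every
#'   site, columns at measured sites concentrated on the observation only
#'   through the model), `best` (best-guess genotypes at missing sites,
#'   `NA` elsewhere) and `missing` (indices of imputed sites).
#' @export
impute_diploid <- function(G_i, H, params = hmm_params(),
                           method = c("auto", "enumerate",
                                      "forward-backward")) {
  method <- match.arg(method)
  H <- as.matrix(H)
  N <- nrow(H); L <- ncol(H)
  if (N < 1L) stop("reference panel is empty")
  if (length(G_i) != L) stop("genotype vector must cover the panel's sites")
  eps <- if (is.null(params$miscopy_epsilon)) default_epsilon(N)
         else params$miscopy_epsilon
  rho <- rep_len(params$rho_map, max(L - 1L, 0L))
  if (method == "auto")
    method <- if (all(rho == 0)) "enumerate" else "forward-backward"
  ET <- emission_table(eps)
  missing <- which(is.na(G_i))

  if (method == "enumerate") {
    if (any(rho > 0)) stop("enumeration requires rho = 0 everywhere")
    ## log-weight of each ordered pair: product of emissions at measured
    logw <- matrix(0, N, N)
    for (j in which(!is.na(G_i))) {
      a <- H[, j]
      s <- outer(a, a, "+")
      logw <- logw + log(ET[G_i[j] + 1L, s + 1L])
    }
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    probs <- matrix(NA_real_, 3L, L)
    for (j in seq_len(L)) {
      a <- H[, j]
      w2 <- drop(a %*% w %*% a)
      w0 <- drop((1 - a) %*% w %*% (1 - a))
      w1 <- 1 - w0 - w2
      probs[, j] <- ET[, 1L] * w0 + ET[, 2L] * w1 + ET[, 3L] * w2
    }
  } else {
    ## forward-backward over ordered pair states with factorised switching
    p_sw <- 1 - exp(-rho / N)
    emis <- function(j) {
      if (is.na(G_i[j])) return(matrix(1, N, N))
      a <- H[, j]
      s <- outer(a, a, "+")
      matrix(ET[G_i[j] + 1L, s + 1L], N, N)
    }
    trans <- function(f, p) {
      ## per-haplotype kernel A = (1-p) I + (p/N) J applied on both sides
      rowm <- colSums(f) / N   # sums over z1 for each z2
      colm <- rowSums(f) / N
      tot <- sum(f) / N^2
      (1 - p)^2 * f +
        (1 - p) * p * (matrix(colm, N, N) + matrix(rowm, N, N, byrow = TRUE)) +
        p * p * tot
    }
    fwd <- vector("list", L)
    f <- matrix(1 / N^2, N, N) * emis(1L)
    cf <- numeric(L)
    cf[1L] <- sum(f); f <- f / cf[1L]
    fwd[[1L]] <- f
    for (j in seq_len(L - 1L)) {
      f <- trans(f, p_sw[j]) * emis(j + 1L)
      cf[j + 1L] <- sum(f); f <- f / cf[j + 1L]
      fwd[[j + 1L]] <- f
    }
    b <- matrix(1, N, N)
    probs <- matrix(NA_real_, 3L, L)
    for (j in L:1L) {
      g <- fwd[[j]] * b
      g <- g / sum(g)
      a <- H[, j]
      w2 <- drop(a %*% g %*% a)
      w0 <- drop((1 - a) %*% g %*% (1 - a))
      w1 <- 1 - w0 - w2
      probs[, j] <- ET[, 1L] * w0 + ET[, 2L] * w1 + ET[, 3L] * w2
      if (j > 1L) b <- trans(b * emis(j), p_sw[j - 1L])
    }
  }
  rownames(probs) <- 0:2
  best <- rep(NA_integer_, L)
  if (length(missing)) {
    rf <- colMeans(H[, missing, drop = FALSE])
    best[missing] <- best_guess_genotype(probs[, missing, drop = FALSE], rf)
  }
  list(probs = probs, best = best, missing = missing, epsilon = eps)
}

#' HMM-based genotype imputation of a whole cohort (rho = 0 comparator)
#'
#' Vectorised over study individuals: pair weights are products of
#' per-measured-site emission matrices shared across individuals with the
#' same observed genotype, and masked-site posteriors follow from the
#' weighted allele-sum distribution of the ordered reference pairs.
#'
#' @param cohort a `cohort`.
#' @param params an [hmm_params] with `rho_map = 0`.
#' @return a `genotype_posterior` (same layout as
#'   [impute_cohort_coalescent]).
#' @export
impute_cohort_hmm <- function(cohort, params = hmm_params()) {
  stopifnot(inherits(cohort, "cohort"))
  if (any(params$rho_map != 0))
    stop("the cohort comparator runs at rho = 0")
  A <- cohort$haps$alleles
  refs <- cohort$reference
  H <- A[refs, , drop = FALSE]
  N <- nrow(H)
  eps <- if (is.null(params$miscopy_epsilon)) default_epsilon(N)
         else params$miscopy_epsilon
  ET <- emission_table(eps)
  meas <- cohort$measured
  masked <- cohort$masked
  pairs <- cohort$study_pairs
  n_ind <- nrow(pairs)
  G <- A[pairs[, 1L], , drop = FALSE] + A[pairs[, 2L], , drop = FALSE]

  ## per measured site: three N x N emission matrices indexed by genotype
  EMl <- lapply(meas, function(j) {
    s <- outer(H[, j], H[, j], "+")
    lapply(0:2, function(g) matrix(log(ET[g + 1L, s + 1L]), N, N))
  })
  Am <- H[, masked, drop = FALSE]
  Ac <- 1 - Am
  ref_freq <- colMeans(Am)

  probs <- array(NA_real_, c(n_ind, length(masked), 3L))
  best <- matrix(NA_integer_, n_ind, length(masked))
  for (i in seq_len(n_ind)) {
    logw <- matrix(0, N, N)
    for (k in seq_along(meas))
      logw <- logw + EMl[[k]][[G[i, meas[k]] + 1L]]
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    w2 <- colSums(Am * (w %*% Am))
    w0 <- colSums(Ac * (w %*% Ac))
    w1 <- pmax(1 - w0 - w2, 0)
    pg <- rbind(ET[1L, 1L] * w0 + ET[1L, 2L] * w1 + ET[1L, 3L] * w2,
                ET[2L, 1L] * w0 + ET[2L, 2L] * w1 + ET[2L, 3L] * w2,
                ET[3L, 1L] * w0 + ET[3L, 2L] * w1 + ET[3L, 3L] * w2)
    probs[i, , ] <- t(pg)
    best[i, ] <- best_guess_genotype(pg, ref_freq)
  }
  structure(list(probs = probs, best = best, hap_probs = NULL,
                 sites = masked, individuals = pairs, epsilon = eps),
            class = "genotype_posterior")
}
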