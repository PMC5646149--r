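#' Sample posterior gene genealogies by Markov chain Monte Carlo
#'
#' Metropolis-within-Gibbs sampler over genealogies compatible (under
#' infinite sites) with the measured-site matrix of all study and reference
#' haplotypes. The tree space is restricted to binary refinements of the
#' perfect-phylogeny skeleton implied by the data, which loses no posterior
#' mass without recombination and shrinks the space dramatically. The chain
#' state is the vector of coalescence times, the resolution of every
#' skeleton multifurcation, the scaled mutation rate theta and, depending on
#' the mode, the growth rate alpha or the subpopulation proportions w.
#' Moves are (i) single-node time perturbations within the valid interval,
#' (ii) whole-tree time rescaling, (iii) re-resolution of one multifurcation
#' (merge pairs are re-drawn at the current merge times — a proposal from
#' the coalescent's conditional topology distribution, so acceptance is
#' driven by the likelihood), and (iv) log-scale random walks on theta (and
#' alpha). Proposal step sizes adapt during burn-in only.
#'
#' @param measured a `haplotype_matrix` restricted to the measured sites,
#'   rows = all study + reference haplotypes (the matrix must be pairwise
#'   four-gamete compatible).
#' @param priors a [prior_config].
#' @param demography a [demography_model] (supplies N_e, growth onset,
#'   split time, number of subpopulations).
#' @param mode demographic model used for the tree prior.
#' @param n_samples number of post-burn-in, thinned tree samples.
#' @param burn_in number of burn-in sweeps; default 25\% of the sampling
#'   sweeps (i.e. 20\% of the total chain length).
#' @param thin keep one tree every `thin` sweeps.
#' @param leaf_deme per-haplotype subpopulation labels (structure modes).
#' @param prior_only if `TRUE` the likelihood is switched off and the chain
#'   targets the coalescent prior (used for sampler validation).
#' @return an object of class `tree_sample`: list with `trees` (list of
#'   `gene_tree`), `theta`, `alpha`, `w`, `acceptance` (rates per move
#'   type), `settings` and `skeleton`.
#' @export
mcmc_sample <- function(measured,
                        priors = prior_config(),
                        demography = demography_model(),
                        mode = c("basic", "growth", "structure",
                                 "growth-structure"),
                        n_samples = 1000L,
                        burn_in = NULL,
                        thin = 5L,
                        leaf_deme = NULL,
                        prior_only = FALSE) {
  mode <- match.arg(mode)
  skel <- build_perfect_phylogeny(measured)
  n <- skel$n_leaf
  use_growth <- mode %in% c("growth", "growth-structure")
  use_struct <- mode %in% c("structure", "growth-structure")
  if (use_struct && is.null(leaf_deme))
    stop("structure mode needs leaf_deme")
  d <- demography
  two_ne <- 2 * d$n_e
  t_on <- if (use_growth) d$growth_onset_generations else 0
  tau_split <- if (use_struct)
    generations_to_units(d$split_time_generations, d$n_e) else Inf
  beta <- if (use_struct) d$n_subpops_beta else 1L
  n_d <- if (use_struct) tabulate(leaf_deme, beta) else n

  ## ---- state layout: leaves 1..n, skeleton internals n+1..n+K (root at
  ## n+1), free resolution nodes n+K+1..2n-1 in per-multifurcation blocks
  K <- length(skel$clades)
  m_tot <- 2L * n - 1L
  parent <- integer(m_tot)
  parent[seq_len(n + K)] <- skel$parent
  time <- numeric(m_tot)
  deme <- integer(m_tot)
  if (use_struct) deme[seq_len(n)] <- leaf_deme

  skel_children <- split(seq_len(n + K)[skel$parent > 0L],
                         skel$parent[skel$parent > 0L])
  blocks <- vector("list", K)
  free_ptr <- n + K
  for (i in seq_len(K)) {
    v <- n + i
    ch <- skel_children[[as.character(v)]]
    m <- length(ch)
    nf <- max(m - 2L, 0L)
    fr <- if (nf > 0L) free_ptr + seq_len(nf) else integer(0)
    free_ptr <- free_ptr + nf
    blocks[[i]] <- list(v = v, children = ch, free = fr, m = m)
  }
  resolvable <- which(vapply(blocks, function(b) b$m > 2L, TRUE))
  free_ids <- if (free_ptr > n + K) (n + K + 1L):free_ptr else integer(0)
  int_ids <- (n + 1L):m_tot
  root_id <- n + 1L
  non_root <- setdiff(seq_len(m_tot), root_id)
  ck2_const <- {k <- n:2; k * (k - 1) / 2}
  col_node <- skel$col_node[!is.na(skel$col_node)]
  S <- length(col_node)

  ## ---- initial resolution: smallest clades first so children times are
  ## known when a block is resolved
  order_blocks <- order(lengths(skel$clades))
  for (i in order_blocks) {
    b <- blocks[[i]]
    act <- b$children
    merge_ids <- c(b$free, b$v)
    t_prev <- 0
    for (s in seq_along(merge_ids)) {
      k <- length(act)
      pick <- sample.int(k, 2L)
      base <- max(time[act[pick]], t_prev)
      if (use_struct) {
        dm <- deme[act[pick]]
        if (!(dm[1L] == dm[2L] && dm[1L] != 0L))
          base <- max(base, tau_split)
      }
      node <- merge_ids[s]
      t_prev <- base + stats::rexp(1L, rate = k * (k - 1) / 2)
      parent[act[pick]] <- node
      time[node] <- t_prev
      if (use_struct) {
        dm <- deme[act[pick]]
        deme[node] <- if (dm[1L] == dm[2L]) dm[1L] else 0L
      }
      act <- c(act[-pick], node)
    }
    parent[b$v] <- skel$parent[b$v]
  }

  ## ---- priors and scalar parameters -----------------------------------
  theta_lo <- priors$theta_lower; theta_hi <- priors$theta_upper
  a_n <- sum(1 / seq_len(n - 1L))
  theta <- min(max(S / a_n, theta_lo + 1e-3), 0.99 * theta_hi)
  alpha <- if (use_growth) max(d$growth_rate_alpha, 1e-4) else 0
  g_shape <- priors$growth_shape
  g_rate <- if (!is.null(priors$growth_rate)) priors$growth_rate
            else g_shape / max(d$growth_rate_alpha, 1e-8)
  w <- rep(1 / beta, beta)
  dir_c <- priors$dirichlet_concentration

  log_post <- function() {
    ts_all <- time[int_ids]
    ord <- order(ts_all, method = "radix")
    ts <- ts_all[ord]
    lp <- if (!use_struct) {
      G <- cum_inv_size_units(c(0, ts), two_ne, alpha, t_on)
      sum(log(ck2_const)) +
        sum(log_inv_size_units(ts, two_ne, alpha, t_on)) -
        sum(ck2_const * diff(G))
    } else {
      log_prior_structured(ts, deme[int_ids][ord], n_d, w, tau_split,
                           two_ne, alpha, t_on)
    }
    if (!is.finite(lp)) return(-Inf)
    if (use_growth)
      lp <- lp + stats::dgamma(alpha, g_shape, g_rate, log = TRUE)
    if (use_struct)
      lp <- lp + sum((dir_c - 1) * log(w))
    if (!prior_only) {
      T_tot <- sum(time[parent[non_root]]) - sum(time[non_root])
      if (theta <= 0) return(-Inf)
      if (S > 0L) {
        bl <- time[parent[col_node]] - time[col_node]
        lp <- lp + sum(log(bl / T_tot)) +
          S * log(theta * T_tot / 2) - theta * T_tot / 2 - lfactorial(S)
      } else {
        lp <- lp - theta * T_tot / 2
      }
    }
    lp
  }

  lp_cur <- log_post()
  if (!is.finite(lp_cur)) stop("failed to initialise a valid state")

  steps <- list(rescale = 0.15, theta = 0.8, alpha = 0.5,
                root = 1 / max(time))
  acc_n <- c(time = 0, rescale = 0, topology = 0, theta = 0,
             alpha = 0, w = 0)
  try_n <- acc_n
  win <- c(rescale = 0, theta = 0, alpha = 0)
  win_acc <- win

  ## replay / re-draw the merge sequence of one block at its current merge
  ## times. propose = FALSE: return log proposal mass of the existing
  ## configuration. propose = TRUE: draw a new configuration (writing times
  ## for free nodes), returning its mass and parent reassignments.
  replay_block <- function(b, propose) {
    mrg <- c(b$free, b$v)
    tms <- time[mrg]
    o <- order(tms)
    times_sorted <- tms[o]
    ids_sorted <- if (propose) mrg else mrg[o]
    act <- b$children
    logq <- 0
    new_parent <- integer(0); new_child <- integer(0)
    new_deme <- integer(length(mrg))
    for (s in seq_along(ids_sorted)) {
      t_m <- times_sorted[s]
      el <- which(time[act] < t_m)
      struct_phase <- use_struct && t_m < tau_split
      if (struct_phase) {
        dmv <- deme[act[el]]
        el <- el[dmv != 0L]
        cnt <- tabulate(deme[act[el]], beta)
        pair_d <- cnt * (cnt - 1) / 2
        npairs <- sum(pair_d)
      } else {
        npairs <- length(el) * (length(el) - 1) / 2
      }
      if (npairs < 1) return(NULL)
      logq <- logq - log(npairs)
      node <- ids_sorted[s]
      if (propose) {
        if (struct_phase) {
          dpick <- sample.int(beta, 1L, prob = pair_d)
          cand <- el[deme[act[el]] == dpick]
          pick <- cand[sample.int(length(cand), 2L)]
        } else {
          pick <- el[sample.int(length(el), 2L)]
        }
        new_parent <- c(new_parent, node, node)
        new_child <- c(new_child, act[pick])
        dm <- deme[act[pick]]
        new_deme[s] <- if (dm[1L] == dm[2L]) dm[1L] else 0L
        time[node] <<- t_m
        act <- c(act[-pick], node)
      } else {
        ch <- which(parent == node)
        idx <- match(ch, act)
        if (anyNA(idx) || !all(idx %in% el)) return(NULL)
        act <- c(act[-idx], node)
      }
    }
    list(logq = logq, new_parent = new_parent, new_child = new_child,
         new_deme = new_deme, ids = ids_sorted)
  }

  move_topology <- function() {
    bi <- resolvable[sample.int(length(resolvable), 1L)]
    b <- blocks[[bi]]
    rev_info <- replay_block(b, propose = FALSE)
    if (is.null(rev_info)) return(FALSE)
    old_parent <- parent; old_time <- time; old_deme <- deme
    fwd <- replay_block(b, propose = TRUE)
    if (is.null(fwd)) {
      parent <<- old_parent; time <<- old_time; deme <<- old_deme
      return(FALSE)
    }
    parent[fwd$new_child] <<- fwd$new_parent
    if (use_struct) deme[fwd$ids] <<- fwd$new_deme
    lp_new <- log_post()
    if (is.finite(lp_new) &&
        log(stats::runif(1L)) < lp_new - lp_cur + rev_info$logq - fwd$logq) {
      lp_cur <<- lp_new
      TRUE
    } else {
      parent <<- old_parent; time <<- old_time; deme <<- old_deme
      FALSE
    }
  }

  move_time <- function(v) {
    ch <- which(parent == v)
    lo <- max(time[ch])
    if (use_struct && deme[v] == 0L) lo <- max(lo, tau_split)
    p <- parent[v]
    old <- time[v]
    if (p > 0L) {
      hi <- time[p]
      if (hi <= lo) return(FALSE)
      time[v] <<- stats::runif(1L, lo, hi)
      hast <- 0
    } else {
      time[v] <<- lo + stats::rexp(1L, steps$root)
      hast <- steps$root * (time[v] - old)
    }
    lp_new <- log_post()
    if (log(stats::runif(1L)) < lp_new - lp_cur + hast) {
      lp_cur <<- lp_new
      TRUE
    } else {
      time[v] <<- old
      FALSE
    }
  }

  move_rescale <- function() {
    u <- stats::runif(1L, -steps$rescale, steps$rescale)
    old <- time
    time[int_ids] <<- time[int_ids] * exp(u)
    lp_new <- log_post()
    if (is.finite(lp_new) &&
        log(stats::runif(1L)) < lp_new - lp_cur + (n - 1) * u) {
      lp_cur <<- lp_new
      TRUE
    } else {
      time <<- old
      FALSE
    }
  }

  move_theta <- function() {
    old <- theta
    theta <<- theta * exp(stats::rnorm(1L, 0, steps$theta))
    if (theta <= theta_lo || theta >= theta_hi) {
      theta <<- old
      return(FALSE)
    }
    lp_new <- log_post()
    if (log(stats::runif(1L)) < lp_new - lp_cur + log(theta / old)) {
      lp_cur <<- lp_new
      TRUE
    } else {
      theta <<- old
      FALSE
    }
  }

  move_alpha <- function() {
    old <- alpha
    alpha <<- alpha * exp(stats::rnorm(1L, 0, steps$alpha))
    lp_new <- log_post()
    if (log(stats::runif(1L)) < lp_new - lp_cur + log(alpha / old)) {
      lp_cur <<- lp_new
      TRUE
    } else {
      alpha <<- old
      FALSE
    }
  }

  move_w <- function() {
    ij <- sample.int(beta, 2L)
    u <- stats::runif(1L, -0.05, 0.05)
    old <- w
    w[ij[1L]] <<- w[ij[1L]] + u
    w[ij[2L]] <<- w[ij[2L]] - u
    if (any(w <= 0)) {
      w <<- old
      return(FALSE)
    }
    lp_new <- log_post()
    if (log(stats::runif(1L)) < lp_new - lp_cur) {
      lp_cur <<- lp_new
      TRUE
    } else {
      w <<- old
      FALSE
    }
  }

  bump <- function(nm, ok) {
    try_n[nm] <<- try_n[nm] + 1
    acc_n[nm] <<- acc_n[nm] + ok
    if (nm %in% names(win)) {
      win[nm] <<- win[nm] + 1
      win_acc[nm] <<- win_acc[nm] + ok
    }
  }

  n_free_moves <- min(length(free_ids), 40L)
  if (is.null(burn_in)) burn_in <- ceiling(0.25 * n_samples * thin)
  total_sweeps <- burn_in + n_samples * thin
  trees <- vector("list", n_samples)
  theta_out <- numeric(n_samples)
  alpha_out <- if (use_growth) numeric(n_samples) else NULL
  w_out <- if (use_struct) matrix(NA_real_, n_samples, beta) else NULL
  kept <- 0L
  skel_int <- (n + 1L):(n + K)

  for (sweep in seq_len(total_sweeps)) {
    for (v in skel_int) bump("time", move_time(v))
    if (n_free_moves > 0L)
      for (v in free_ids[sample.int(length(free_ids), n_free_moves)])
        bump("time", move_time(v))
    if (length(resolvable)) bump("topology", move_topology())
    bump("rescale", move_rescale())
    if (!prior_only) for (r in 1:2) bump("theta", move_theta())
    if (use_growth) for (r in 1:2) bump("alpha", move_alpha())
    if (use_struct && beta > 1L) for (r in 1:2) bump("w", move_w())

    if (sweep <= burn_in && sweep %% 25L == 0L) {
      for (nm in names(win)) {
        if (win[nm] > 0) {
          steps[[nm]] <- steps[[nm]] * exp(0.5 * (win_acc[nm] / win[nm] - 0.3))
          win[nm] <- 0; win_acc[nm] <- 0
        }
      }
    }

    if (sweep > burn_in && (sweep - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      trees[[kept]] <- gene_tree(parent, time, labels = skel$labels,
                                 leaf_deme = if (use_struct) leaf_deme
                                             else NULL)
      theta_out[kept] <- theta
      if (use_growth) alpha_out[kept] <- alpha
      if (use_struct) w_out[kept, ] <- w
      if (kept >= n_samples) break
    }
  }

  acc <- ifelse(try_n > 0, acc_n / try_n, NA_real_)
  if (isTRUE(all(acc[!is.na(acc)] == 0)))
    warning("sampler accepted no moves; check the input matrix and priors")
  structure(list(trees = trees[seq_len(kept)],
                 theta = theta_out[seq_len(kept)],
                 alpha = if (use_growth) alpha_out[seq_len(kept)] else NULL,
                 w = if (use_struct) w_out[seq_len(kept), , drop = FALSE]
                     else NULL,
                 acceptance = acc,
                 settings = list(mode = mode, n_samples = n_samples,
                                 burn_in = burn_in, thin = thin),
                 skeleton = skel),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("tree_sample: %d trees over %d leaves (mode %s)\n",
              length(x$trees),
              if (length(x$trees)) x$trees[[1]]$n_leaf else 0,
              x$settings$mode))
  cat("acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}
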