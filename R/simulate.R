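#' Construct a planted lattice-gas model
#'
#' Draws a sparse ground-truth coupling network: `n_pos_edges` edges with
#' coupling `+J_scale` and `n_neg_edges` with `-J_scale` (optionally jittered
#' by a uniform multiplicative factor), placed uniformly at random among all
#' domain pairs, plus biases uniform in `h_range`. Everything is determined
#' by `seed`.
#'
#' @param n_domains number of domains `N`.
#' @param n_pos_edges,n_neg_edges counts of positive / negative coupling
#'   edges; must total at most `N (N - 1) / 2`.
#' @param J_scale absolute coupling strength (default 1).
#' @param h_range bias range (default `c(-1, 0)`, favoring moderately rare
#'   domains as after frequency filtering).
#' @param jitter relative jitter on edge weights, e.g. 0.2 for +/-20%
#'   (default 0, exact `+/-J_scale`).
#' @param seed integer seed.
#' @param domain_ids optional identifiers (default `D01, D02, ...`).
#' @return an object of class `planted_model`: list with `J`, `h`, `edges`
#'   (data frame `domain_i`, `domain_j`, `weight`, `sign`), `domain_ids`,
#'   `seed`.
#' @export
make_planted_model <- function(n_domains, n_pos_edges, n_neg_edges = 0,
                               J_scale = 1, h_range = c(-1, 0), jitter = 0,
                               seed = NULL, domain_ids = NULL) {
  n_edges <- n_pos_edges + n_neg_edges
  n_pairs <- n_domains * (n_domains - 1) / 2
  if (n_edges > n_pairs)
    stop("requested more edges than available domain pairs")
  if (is.null(domain_ids))
    domain_ids <- sprintf("D%0*d", nchar(n_domains), seq_len(n_domains))
  with_seed(seed, {
    p <- pair_indices(n_domains)
    sel <- sample.int(n_pairs, n_edges)
    w <- c(rep(J_scale, n_pos_edges), rep(-J_scale, n_neg_edges))
    if (jitter > 0) w <- w * stats::runif(n_edges, 1 - jitter, 1 + jitter)
    h <- stats::runif(n_domains, h_range[1L], h_range[2L])
    J <- matrix(0, n_domains, n_domains, dimnames = list(domain_ids, domain_ids))
    J[cbind(p$i[sel], p$j[sel])] <- w
    J <- J + t(J)
    edges <- data.frame(domain_i = domain_ids[p$i[sel]],
                        domain_j = domain_ids[p$j[sel]],
                        weight = w, sign = ifelse(w > 0, "+", "-"),
                        stringsAsFactors = FALSE)
    structure(list(J = J, h = stats::setNames(h, domain_ids), edges = edges,
                   domain_ids = domain_ids, seed = seed),
              class = "planted_model")
  })
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("Planted lattice-gas model: %d domains, %d edges (%d positive, %d negative)\n",
              length(x$domain_ids), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

model_params <- function(model) {
  if (is.list(model) && !is.null(model$J) && !is.null(model$h)) {
    list(J = unname(model$J), h = unname(model$h),
         domain_ids = if (!is.null(model$domain_ids)) model$domain_ids
                      else colnames(model$J))
  } else stop("need a model with fields J and h")
}

#' Gibbs-sample profile matrices from a lattice-gas model
#'
#' Single-site Gibbs sampling of the model's Boltzmann distribution: one
#' sweep updates every domain once, in fixed index order, from the
#' conditional `P(n_i = 1 | rest) = logistic(h_i + sum_j J_ij n_j)`. After
#' `burn_in` sweeps one genome is emitted every `thin` sweeps. Genomes are
#' therefore i.i.d. only in the limit of large `thin`; the defaults
#' (`burn_in = 1000`, `thin = 10`) are validated against exhaustive
#' enumeration in the test suite. Fully deterministic given `seed`.
#'
#' @param model a `planted_model`, `coupling_model`/`phydca` fit, or any list
#'   with fields `J` and `h`.
#' @param n_genomes number of profile rows to emit.
#' @param burn_in discarded initial sweeps (default 1000).
#' @param thin sweeps between emitted genomes (default 10).
#' @param seed integer seed.
#' @return binary profile matrix (`n_genomes` x N) with generated genome
#'   identifiers and the model's domain identifiers.
#' @export
gibbs_sample <- function(model, n_genomes, burn_in = 1000, thin = 10,
                         seed = NULL) {
  stopifnot(n_genomes >= 1, burn_in >= 1, thin >= 1)
  mp <- model_params(model)
  J <- mp$J
  h <- mp$h
  N <- length(h)
  with_seed(seed, {
    state <- as.integer(stats::runif(N) < logistic(h))
    phi <- as.vector(J %*% state) + h   # local fields, updated incrementally
    out <- matrix(0L, n_genomes, N)
    emitted <- 0L
    total <- burn_in + thin * n_genomes
    for (sweep in seq_len(total)) {
      u <- stats::runif(N)
      for (i in seq_len(N)) {
        v <- (u[i] < 1 / (1 + exp(-phi[i])))
        if (v != state[i]) {
          phi <- phi + (v - state[i]) * J[, i]
          state[i] <- v
        }
      }
      if (sweep > burn_in && (sweep - burn_in) %% thin == 0L) {
        emitted <- emitted + 1L
        out[emitted, ] <- state
      }
    }
    dimnames(out) <- list(sprintf("G%0*d", nchar(n_genomes), seq_len(n_genomes)),
                          mp$domain_ids)
    out
  })
}

#' Exact distribution of a small lattice-gas model
#'
#' Enumerates all `2^N` states and their Boltzmann probabilities; feasible
#' for `N <= 20`. Used as the ground-truth oracle for sampler and inference
#' checks, and to build exhaustively weighted pseudo-data (`states` +
#' `prob` as [plm_couplings()] weights).
#'
#' @param J symmetric coupling matrix with zero diagonal.
#' @param h bias vector.
#' @return list with `states` (`2^N` x N binary matrix), `prob`, `f` (exact
#'   single-domain marginals) and `fij` (exact pair marginals).
#' @export
lattice_gas_exact <- function(J, h) {
  N <- length(h)
  if (N > 20) stop("exact enumeration limited to N <= 20")
  states <- as.matrix(expand.grid(rep(list(0:1), N), KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- list(NULL, colnames(J))
  E <- as.vector(states %*% h) + rowSums((states %*% J) * states) / 2
  p <- exp(E - max(E))
  p <- p / sum(p)
  fij <- crossprod(states, states * p)
  list(states = states, prob = p, f = colSums(states * p), fij = fij)
}

#' Tree-correlated profile sampling
#'
#' Optional confound emulation: instead of i.i.d. genomes, profiles are
#' evolved along a random binary genealogy. The root profile is drawn by
#' Gibbs sampling; lineages are then duplicated uniformly at random until
#' `n_genomes` exist, and along every branch a random fraction
#' `resample_frac` of the domains is resampled from the model's single-site
#' conditionals. Shared ancestry induces correlations between profiles that
#' mimic phylogenetic amplification of single evolutionary events.
#'
#' @inheritParams gibbs_sample
#' @param resample_frac fraction of domains resampled per branch (default 0.1).
#' @return binary profile matrix (`n_genomes` x N).
#' @export
tree_gibbs_sample <- function(model, n_genomes, resample_frac = 0.1,
                              burn_in = 1000, seed = NULL) {
  stopifnot(n_genomes >= 1, resample_frac > 0, resample_frac <= 1)
  mp <- model_params(model)
  J <- mp$J
  h <- mp$h
  N <- length(h)
  root <- gibbs_sample(model, 1L, burn_in = burn_in, thin = 1L, seed = seed)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    lineages <- list(as.integer(root[1L, ]))
    k <- max(1L, round(resample_frac * N))
    mutate <- function(state) {
      for (i in sample.int(N, k)) {
        phi <- sum(J[, i] * state) + h[i]
        state[i] <- as.integer(stats::runif(1L) < logistic(phi))
      }
      state
    }
    while (length(lineages) < n_genomes) {
      pick <- sample.int(length(lineages), 1L)
      parent <- lineages[[pick]]
      lineages[[pick]] <- mutate(parent)
      lineages[[length(lineages) + 1L]] <- mutate(parent)
    }
    out <- do.call(rbind, lineages)
    dimnames(out) <- list(sprintf("G%0*d", nchar(n_genomes), seq_len(n_genomes)),
                          mp$domain_ids)
    out
  })
}

#' Parameter-recovery metrics against a planted model
#'
#' Compares inferred couplings to the planted ground truth: root-mean-square
#' error on the planted edges, the largest absolute inferred coupling on
#' non-edges, and the edge-detection AUC when ranking pairs by `|J|`
#' (Mann-Whitney concordance of edges versus non-edges). If the sampled
#' profile matrix is supplied, the AUC of ranking by absolute Pearson
#' correlation on the same data is reported for comparison — the synthetic
#' analogue of couplings-beat-correlations.
#'
#' @param model the `planted_model` ground truth.
#' @param inferred a `coupling_model`/`phydca` fit on data from `model`.
#' @param ppm optional profile matrix used for the fit.
#' @param use_apc evaluate APC-corrected scores.
#' @return list with `rmse_edges`, `max_abs_nonedge`, `auc_coupling` and
#'   (when `ppm` is given) `auc_pearson`.
#' @export
recovery_report <- function(model, inferred, ppm = NULL, use_apc = FALSE) {
  stopifnot(inherits(model, "planted_model"),
            inherits(inferred, "coupling_model"))
  if (!identical(model$domain_ids, inferred$domain_ids))
    stop("planted and inferred models cover different domain sets")
  if (use_apc && is.null(inferred$J_apc)) inferred <- apc_correct(inferred)
  S <- if (use_apc) inferred$J_apc else inferred$J
  ut <- upper.tri(S)
  edge <- model$J != 0
  rmse <- sqrt(mean((S[ut & edge] - model$J[ut & edge])^2))
  out <- list(rmse_edges = rmse,
              max_abs_nonedge = max(abs(S[ut & !edge])),
              auc_coupling = rank_auc(abs(S[ut & edge]), abs(S[ut & !edge])))
  if (!is.null(ppm)) {
    r <- stats::cor(ppm[, model$domain_ids, drop = FALSE])
    out$auc_pearson <- rank_auc(abs(r[ut & edge]), abs(r[ut & !edge]))
  }
  out
}
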