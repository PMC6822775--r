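#' Fit a lattice-gas model of phyletic couplings
#'
#' The central fitting function. A binary genome x domain profile matrix is
#' modelled by the global maximum-entropy (lattice-gas) distribution
#' \deqn{P(n_1, \dots, n_N) = \frac{1}{Z}\exp\Big\{\sum_{i<j} J_{ij} n_i n_j
#'   + \sum_i h_i n_i\Big\},}{P(n) = exp(sum_{i<j} J_ij n_i n_j + sum_i h_i n_i)/Z,}
#' whose couplings \eqn{J_{ij}} and biases \eqn{h_i} are chosen to reproduce
#' the single- and pairwise presence frequencies of the data. A positive
#' coupling favors co-occurrence of two domains across genomes (functional or
#' physical association); a negative coupling favors mutual exclusion
#' (alternative solutions for the same function). The partition function `Z`
#' is never evaluated: inference uses the mean-field or pseudo-likelihood
#' approximation (see [mf_couplings()], [plm_couplings()]).
#'
#' @param x binary profile matrix (genomes x domains) as built by
#'   [build_ppm()] and filtered by [filter_by_frequency()].
#' @param method `"plm"` (pseudo-likelihood maximization, the default) or
#'   `"mf"` (mean-field covariance inversion).
#' @param pseudocount MF frequency shrinkage, passed to [mf_couplings()].
#' @param l2_J,l2_h PLM ridge penalties, passed to [plm_couplings()].
#' @param weights optional per-genome weights.
#' @param apc also compute the average-product-corrected score matrix
#'   (default `TRUE`); ranking still uses raw couplings unless requested.
#' @param ... further arguments passed to the underlying inference routine.
#' @return an object of class `c("phydca", "coupling_model")`: a list with
#'   the coupling matrix `J`, biases `h`, APC scores `J_apc`, `method`,
#'   `regularization`, `domain_ids`, frequency statistics `freqs`, the number
#'   of genomes `M` and the matched `call`.
#' @examples
#' truth <- make_planted_model(12, n_pos_edges = 4, n_neg_edges = 1, seed = 1)
#' ppm <- gibbs_sample(truth, n_genomes = 400, seed = 2)
#' fit <- phydca(ppm, method = "mf")
#' fit
#' head(rank_pairs(fit), 4)
#' @seealso [rank_pairs()], [ppv_curve()], [gibbs_sample()]
#' @export
phydca <- function(x, method = c("plm", "mf"), pseudocount = 0.01,
                   l2_J = 0.01, l2_h = 0.01, weights = NULL, apc = TRUE, ...) {
  method <- match.arg(method)
  validate_ppm(x)
  freqs <- empirical_frequencies(x, weights)
  model <- switch(method,
    mf = mf_couplings(freqs, pseudocount = pseudocount, ...),
    plm = plm_couplings(x, l2_J = l2_J, l2_h = l2_h, weights = weights, ...))
  if (apc) model <- apc_correct(model)
  model$freqs <- freqs
  model$M <- nrow(x)
  model$call <- match.call()
  class(model) <- c("phydca", class(model))
  model
}

#' @export
print.phydca <- function(x, ...) {
  cat("Phyletic direct coupling analysis\n")
  cat(sprintf("  %d genomes x %d domains, inference: %s\n",
              x$M, length(x$domain_ids), toupper(x$method)))
  off <- x$J[upper.tri(x$J)]
  cat(sprintf("  couplings: %d pairs, range [%.3f, %.3f]\n",
              length(off), min(off), max(off)))
  top <- utils::head(rank_pairs(x), 3L)
  cat("  strongest positive couplings:\n")
  for (k in seq_len(nrow(top)))
    cat(sprintf("    %s -- %s   J = %.3f\n",
                top$domain_i[k], top$domain_j[k], top$score[k]))
  invisible(x)
}

#' Summarize a fitted phyletic coupling model
#'
#' @param object a `phydca` fit.
#' @param thresholds absolute-coupling cutoffs at which to count links in the
#'   positive and negative tails (default `c(0.3, 0.5)`, the range in which
#'   couplings become individually significant against the bulk).
#' @param n_top number of top pairs of each sign to tabulate.
#' @param ... unused.
#' @return an object of class `summary.phydca`.
#' @export
summary.phydca <- function(object, thresholds = c(0.3, 0.5), n_top = 5L, ...) {
  off <- object$J[upper.tri(object$J)]
  tail_counts <- t(vapply(thresholds, function(t)
    c(positive = sum(off > t), negative = sum(off < -t)), c(0, 0)))
  rownames(tail_counts) <- sprintf("|J| > %g", thresholds)
  structure(list(method = object$method, M = object$M,
                 n_domains = length(object$domain_ids),
                 coupling_quantiles = stats::quantile(off, c(0, .01, .25, .5, .75, .99, 1)),
                 tail_counts = tail_counts,
                 top_positive = utils::head(rank_pairs(object, tail = "positive"), n_top),
                 top_negative = utils::head(rank_pairs(object, tail = "negative"), n_top)),
            class = "summary.phydca")
}

#' @export
print.summary.phydca <- function(x, ...) {
  cat(sprintf("Phyletic couplings (%s), %d genomes x %d domains\n",
              toupper(x$method), x$M, x$n_domains))
  cat("Coupling quantiles:\n")
  print(signif(x$coupling_quantiles, 3))
  cat("Links beyond significance cutoffs:\n")
  print(x$tail_counts)
  cat("Strongest positive couplings:\n")
  print.data.frame(as.data.frame(x$top_positive))
  if (nrow(x$top_negative)) {
    cat("Strongest negative couplings:\n")
    print.data.frame(as.data.frame(x$top_negative))
  }
  invisible(x)
}

#' Extract the coupling matrix
#'
#' @param object a `phydca` fit.
#' @param use_apc return APC-corrected scores instead of raw couplings.
#' @param ... unused.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
coef.phydca <- function(object, use_apc = FALSE, ...) {
  if (use_apc) {
    if (is.null(object$J_apc)) object <- apc_correct(object)
    object$J_apc
  } else object$J
}

#' Histogram of inferred couplings
#'
#' Plots the distribution of all pairwise couplings on a logarithmic count
#' scale — a bulk concentrated near zero with a fat positive tail and a
#' smaller negative tail. If a positive relation set is supplied, the
#' histogram of couplings restricted to known-related pairs is overlaid,
#' showing how the tail is dominated by true relations.
#'
#' @param x a `phydca` fit.
#' @param positives optional `relation_set` of known related pairs.
#' @param breaks passed to [graphics::hist()].
#' @param ... further graphical parameters.
#' @export
plot.phydca <- function(x, positives = NULL, breaks = 50, ...) {
  off <- x$J[upper.tri(x$J)]
  hh <- graphics::hist(off, breaks = breaks, plot = FALSE)
  graphics::plot(hh$mids, pmax(hh$counts, 0.5), type = "h", log = "y",
                 xlab = "phyletic coupling J", ylab = "pairs (log scale)",
                 main = "Distribution of phyletic couplings", col = "steelblue", ...)
  if (!is.null(positives) && nrow(positives)) {
    p <- pair_indices(ncol(x$J))
    keys <- pair_key(x$domain_ids[p$i], x$domain_ids[p$j])
    inpos <- keys %in% pair_key(positives$domain_i, positives$domain_j)
    hp <- graphics::hist(x$J[cbind(p$i, p$j)][inpos], breaks = hh$breaks, plot = FALSE)
    graphics::lines(hp$mids, pmax(hp$counts, 0.5), type = "h", col = "brown")
    graphics::legend("topright", legend = c("all pairs", "known relations"),
                     col = c("steelblue", "brown"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate profile matrices from a fitted model
#'
#' Draws genomes from the fitted lattice-gas distribution by Gibbs sampling
#' (see [gibbs_sample()]), e.g. for parametric-bootstrap checks.
#'
#' @param object a `phydca` fit.
#' @param nsim number of matrices to generate.
#' @param seed integer seed; sub-seeds are derived per replicate.
#' @param n_genomes rows per simulated matrix (default: as fitted).
#' @param ... passed to [gibbs_sample()] (`burn_in`, `thin`).
#' @return a single profile matrix if `nsim = 1`, else a list of matrices.
#' @export
simulate.phydca <- function(object, nsim = 1, seed = NULL,
                            n_genomes = object$M, ...) {
  sims <- lapply(seq_len(nsim), function(k)
    gibbs_sample(object, n_genomes = n_genomes,
                 seed = if (is.null(seed)) NULL else seed + k - 1L, ...))
  if (nsim == 1L) sims[[1L]] else sims
}

#' Conditional presence probabilities
#'
#' For each genome (row) of `newdata` and each domain `i`, the model's
#' conditional probability `P(n_i = 1 | n_rest) = logistic(h_i + sum_j J_ij
#' n_j)` of observing the domain given the rest of the profile.
#'
#' @param object a `phydca` fit.
#' @param newdata binary profile matrix over the fitted domain set (default:
#'   refitted data frequencies are not stored; supply explicitly).
#' @param ... unused.
#' @return matrix of probabilities, same shape as `newdata`.
#' @export
predict.phydca <- function(object, newdata, ...) {
  validate_ppm(newdata)
  if (!identical(colnames(newdata), object$domain_ids))
    newdata <- newdata[, object$domain_ids, drop = FALSE]
  eta <- newdata %*% object$J
  logistic(sweep(eta, 2L, object$h, "+"))
}
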