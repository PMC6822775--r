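## Frequency statistics ------------------------------------------------------

#' Single and pairwise presence frequencies of a profile matrix
#'
#' Computes `f_i`, the (weighted) fraction of genomes carrying domain `i`, and
#' the symmetric matrix `f_ij` of fractions of genomes carrying both `i` and
#' `j`; `f_ii = f_i`. These are the marginals the lattice-gas model is fitted
#' to.
#'
#' @param ppm binary profile matrix.
#' @param weights optional non-negative per-genome weights (default: all 1).
#'   Weighted frequencies are weighted sums divided by the total weight.
#' @return an object of class `phyletic_freqs`: list with elements `f` (length
#'   N), `fij` (N x N), `M` (number of genomes), `domain_ids`.
#' @export
empirical_frequencies <- function(ppm, weights = NULL) {
  validate_ppm(ppm)
  M <- nrow(ppm)
  if (M < 1L) stop("profile matrix has no genomes")
  if (is.null(weights)) weights <- rep(1, M)
  stopifnot(length(weights) == M, all(weights >= 0), sum(weights) > 0)
  W <- sum(weights)
  f <- as.vector(crossprod(ppm, weights)) / W
  fij <- crossprod(ppm, ppm * weights) / W
  fij <- (fij + t(fij)) / 2
  diag(fij) <- f
  structure(list(f = stats::setNames(f, colnames(ppm)), fij = fij, M = M,
                 domain_ids = colnames(ppm)),
            class = "phyletic_freqs")
}

## Coupling models ------------------------------------------------------------

new_coupling_model <- function(J, h, method, regularization, domain_ids) {
  dimnames(J) <- list(domain_ids, domain_ids)
  structure(list(J = J, h = stats::setNames(h, domain_ids), J_apc = NULL,
                 method = method, regularization = regularization,
                 domain_ids = domain_ids),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("Lattice-gas coupling model (%s): %d domains\n",
              toupper(x$method), length(x$domain_ids)))
  off <- x$J[upper.tri(x$J)]
  cat(sprintf("  couplings J: range [%.3g, %.3g], %d positive / %d negative\n",
              min(off), max(off), sum(off > 0), sum(off < 0)))
  cat(sprintf("  APC scores: %s\n", if (is.null(x$J_apc)) "not computed" else "available"))
  invisible(x)
}

#' Mean-field coupling inference
#'
#' Estimates the couplings of the lattice-gas model by inversion of the
#' regularized connected-correlation matrix. Frequencies are shrunk towards
#' the uniform independent model by a pseudocount `lambda`:
#' `f' = (1 - lambda) f + lambda / 2` and, off-diagonal,
#' `f'_ij = (1 - lambda) f_ij + lambda / 4`. With
#' `C_ij = f'_ij - f'_i f'_j`, the mean-field couplings are
#' `J_ij = -(C^{-1})_ij` (zero diagonal), and the biases solve the mean-field
#' consistency relation `h_i = logit(f'_i) - sum_j J_ij f'_j`.
#'
#' @param stats a `phyletic_freqs` object from [empirical_frequencies()].
#' @param pseudocount shrinkage weight `lambda` in `[0, 1)`; default 0.01.
#' @return an object of class `coupling_model` with fields `J` (symmetric,
#'   zero diagonal), `h`, `method = "mf"`, `regularization`, `domain_ids`.
#' @export
mf_couplings <- function(stats, pseudocount = 0.01) {
  stopifnot(inherits(stats, "phyletic_freqs"),
            pseudocount >= 0, pseudocount < 1)
  lam <- pseudocount
  fp <- (1 - lam) * stats$f + lam / 2
  fpij <- (1 - lam) * stats$fij + lam / 4
  diag(fpij) <- fp
  C <- fpij - outer(fp, fp)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("connected-correlation matrix is singular; increase the pseudocount",
         call. = FALSE))
  J <- -(Cinv + t(Cinv)) / 2
  diag(J) <- 0
  h <- stats::qlogis(fp) - as.vector(J %*% fp)
  new_coupling_model(J, h, method = "mf",
                     regularization = list(pseudocount = lam),
                     domain_ids = stats$domain_ids)
}

## ridge-penalized logistic fit of column y on X by Newton-Raphson;
## pen is the per-coefficient L2 strength (already doubled into grad/Hess)
plm_node_fit <- function(X, y, w, pen, grad_tol, max_iter) {
  beta <- numeric(ncol(X))
  eps <- 1e-12
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    p <- pmin(pmax(logistic(eta), eps), 1 - eps)
    -sum(w * (y * log(p) + (1 - y) * log(1 - p))) + sum(pen * b^2)
  }
  f0 <- nll(beta)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- logistic(eta)
    g <- as.vector(crossprod(X, w * (p - y))) + 2 * pen * beta
    gn <- sqrt(sum(g^2))
    if (gn <= grad_tol) return(list(beta = beta, grad_norm = gn, iter = it))
    Wd <- w * p * (1 - p)
    H <- crossprod(X, X * Wd) + diag(2 * pen, ncol(X))
    step <- solve(H, g)
    # damped Newton: halve the step until the objective decreases
    t <- 1
    repeat {
      cand <- beta - t * step
      if (nll(cand) <= f0 + 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    beta <- cand
    f0 <- nll(beta)
  }
  p <- logistic(as.vector(X %*% beta))
  g <- as.vector(crossprod(X, w * (p - y))) + 2 * pen * beta
  list(beta = beta, grad_norm = sqrt(sum(g^2)), iter = max_iter, failed = TRUE)
}

#' Pseudo-likelihood coupling inference
#'
#' For each domain `i`, fits the conditional model
#' `P(n_i = 1 | n_rest) = logistic(h_i + sum_j J_ij n_j)` by maximizing the
#' L2-penalized conditional log-likelihood of column `i` given all others
#' (ridge logistic regression, damped Newton iterations). The two asymmetric
#' estimates of each coupling are then symmetrized by their arithmetic mean,
#' `J_ij = (J_ij^(i) + J_ij^(j)) / 2`. Inference is deterministic.
#'
#' @param ppm binary profile matrix; every column must be non-constant.
#' @param l2_J,l2_h L2 penalty strengths on couplings and biases per node;
#'   defaults 0.01.
#' @param weights optional non-negative per-genome weights (e.g. exact state
#'   probabilities when fitting an exhaustively enumerated distribution).
#' @param grad_tol convergence threshold on the gradient L2 norm (default 1e-6).
#' @param max_iter Newton iteration cap per node (default 500).
#' @return an object of class `coupling_model` with `method = "plm"`.
#' @export
plm_couplings <- function(ppm, l2_J = 0.01, l2_h = 0.01, weights = NULL,
                          grad_tol = 1e-6, max_iter = 500L) {
  validate_ppm(ppm)
  N <- ncol(ppm)
  if (N < 2L) stop("need at least two domains")
  if (is.null(weights)) weights <- rep(1, nrow(ppm))
  stopifnot(l2_J >= 0, l2_h >= 0, length(weights) == nrow(ppm))
  cm <- colMeans(ppm)
  if (any(cm == 0 | cm == 1))
    stop("constant domain column(s): ",
         paste(colnames(ppm)[cm == 0 | cm == 1], collapse = ", "))
  Jraw <- matrix(0, N, N)
  h <- numeric(N)
  storage.mode(ppm) <- "double"
  for (i in seq_len(N)) {
    X <- cbind(1, ppm[, -i, drop = FALSE])
    fit <- plm_node_fit(X, ppm[, i], weights,
                        pen = c(l2_h, rep(l2_J, N - 1L)),
                        grad_tol = grad_tol, max_iter = max_iter)
    if (isTRUE(fit$failed))
      stop(sprintf("pseudo-likelihood fit for domain '%s' did not converge (gradient norm %.3g after %d iterations)",
                   colnames(ppm)[i], fit$grad_norm, fit$iter))
    h[i] <- fit$beta[1L]
    Jraw[i, -i] <- fit$beta[-1L]
  }
  J <- (Jraw + t(Jraw)) / 2
  diag(J) <- 0
  new_coupling_model(J, h, method = "plm",
                     regularization = list(l2_J = l2_J, l2_h = l2_h,
                                           grad_tol = grad_tol),
                     domain_ids = colnames(ppm))
}

#' Average product correction of a coupling matrix
#'
#' Subtracts the product of row and column means divided by the grand mean
#' (all means over off-diagonal entries) from each coupling:
#' `S_ij = J_ij - mean_i(J) * mean_j(J) / mean(J)`. APC removes the uniform
#' background a heterogeneously conserved domain contributes to every one of
#' its couplings. Applied to the signed couplings directly.
#'
#' @param model a `coupling_model`.
#' @return the model with its `J_apc` field filled (symmetric, zero
#'   diagonal). If the grand mean is zero the correction is skipped with a
#'   warning and `J_apc` is left `NULL`.
#' @export
apc_correct <- function(model) {
  stopifnot(inherits(model, "coupling_model"))
  J <- model$J
  N <- nrow(J)
  rowm <- rowSums(J) / (N - 1)          # diagonal is zero
  grand <- sum(J) / (N * (N - 1))
  if (grand == 0) {
    warning("grand mean of couplings is zero; APC skipped")
    return(model)
  }
  S <- J - outer(rowm, rowm) / grand
  diag(S) <- 0
  model$J_apc <- S
  model
}

#' Rank domain pairs by coupling strength
#'
#' Orders the pairs of a coupling model by their coupling: the positive tail
#' descending (strongest co-occurrence couplings first) or the negative tail
#' ascending (strongest avoidance first). Pairs with exactly zero coupling
#' belong to neither tail. Ties are broken lexicographically; the biases `h`
#' play no role.
#'
#' @param model a `coupling_model`.
#' @param use_apc rank by APC-corrected scores instead of raw couplings
#'   (computed on the fly if absent). Default `FALSE`: raw couplings.
#' @param tail `"positive"` or `"negative"`.
#' @return a `pair_scores` data frame, most related (or most avoided) first.
#' @export
rank_pairs <- function(model, use_apc = FALSE, tail = c("positive", "negative")) {
  stopifnot(inherits(model, "coupling_model"))
  tail <- match.arg(tail)
  if (use_apc && is.null(model$J_apc)) model <- apc_correct(model)
  S <- if (use_apc) model$J_apc else model$J
  p <- pair_indices(ncol(S))
  s <- S[cbind(p$i, p$j)]
  keep <- if (tail == "positive") s > 0 else s < 0
  new_pair_scores(model$domain_ids[p$i][keep], model$domain_ids[p$j][keep],
                  s[keep],
                  score_kind = if (use_apc) "coupling_apc" else "coupling",
                  direction = if (tail == "positive") "desc" else "asc")
}

#' Write a coupling model to plain text
#'
#' Couplings go to `path` as a TSV `domain_i<TAB>domain_j<TAB>J<TAB>J_apc`
#' (all unordered pairs); biases and metadata go to a `key<TAB>value` sidecar
#' `paste0(path, ".meta")`.
#'
#' @param model a `coupling_model`.
#' @param path output TSV path.
#' @export
write_couplings <- function(model, path) {
  stopifnot(inherits(model, "coupling_model"))
  if (is.null(model$J_apc)) model <- apc_correct(model)
  p <- pair_indices(ncol(model$J))
  df <- data.frame(domain_i = model$domain_ids[p$i],
                   domain_j = model$domain_ids[p$j],
                   J = model$J[cbind(p$i, p$j)],
                   J_apc = if (is.null(model$J_apc)) NA_real_
                           else model$J_apc[cbind(p$i, p$j)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("method\t%s", model$method),
            sprintf("regularization.%s\t%g", names(model$regularization),
                    unlist(model$regularization)),
            sprintf("h.%s\t%.17g", model$domain_ids, model$h))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
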