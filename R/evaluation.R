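rel_keys <- function(positives) {
  if (!nrow(positives)) character(0)
  else pair_key(positives$domain_i, positives$domain_j)
}

#' Positive predictive value curve
#'
#' For a ranked prediction list, `PPV(k)` is the fraction of the `k`
#' highest-ranked pairs that belong to the positive relation set,
#' `k = 1..k_max`. A random ranking gives a flat curve near the base rate; a
#' perfect ranking stays at 1 until the positives are exhausted.
#'
#' @param predictions a `pair_scores` ranking (most related first).
#' @param positives a `relation_set` of known related pairs.
#' @param k_max deepest rank to evaluate (default: full list).
#' @return data frame with columns `k` and `ppv`.
#' @export
ppv_curve <- function(predictions, positives, k_max = nrow(predictions)) {
  stopifnot(k_max >= 1, k_max <= nrow(predictions))
  if (!nrow(positives)) {
    warning("empty positive set: PPV curve is identically zero")
    return(data.frame(k = seq_len(k_max), ppv = 0))
  }
  hit <- pair_key(predictions$domain_i, predictions$domain_j)[seq_len(k_max)] %in%
    rel_keys(positives)
  data.frame(k = seq_len(k_max), ppv = cumsum(hit) / seq_len(k_max))
}

#' Per-bin category membership of ranked predictions
#'
#' Cuts a ranked prediction list into consecutive bins of `bin_size` pairs
#' and counts, independently for each named category, how many pairs of each
#' bin belong to it. Categories may overlap, so per-bin counts can sum to
#' more than the bin size.
#'
#' @param predictions a `pair_scores` ranking.
#' @param categories named list of `relation_set` objects.
#' @param bin_size pairs per bin (default 100).
#' @return data frame with columns `bin`, `from`, `to` and one count column
#'   per category.
#' @export
enrichment_bins <- function(predictions, categories, bin_size = 100) {
  stopifnot(bin_size >= 1, length(names(categories)) == length(categories))
  n <- nrow(predictions)
  keys <- pair_key(predictions$domain_i, predictions$domain_j)
  bin <- ceiling(seq_len(n) / bin_size)
  out <- data.frame(bin = seq_len(max(bin)),
                    from = (seq_len(max(bin)) - 1L) * bin_size + 1L,
                    to = pmin(seq_len(max(bin)) * bin_size, n))
  for (nm in names(categories))
    out[[nm]] <- as.vector(tapply(keys %in% rel_keys(categories[[nm]]), bin, sum))
  out
}

#' Cross-tabulate overlapping prediction sets
#'
#' Given two or three named top-k prediction sets over the same pair
#' universe, reports for every membership pattern — `YES` (in the set), `NO`
#' (not in it) or `-` (set ignored, aggregating over both) — the number of
#' pairs, the true positives among them, and their PPV. Patterns without any
#' `YES` are undefined (the complement of all sets is unbounded) and omitted.
#'
#' @param sets named list of 2-3 `pair_scores` objects (or data frames with
#'   `domain_i`/`domain_j`).
#' @param positives a `relation_set`.
#' @return data frame with one column per set (values `YES`/`NO`/`-`) plus
#'   `elements`, `tp`, `ppv`.
#' @export
compare_prediction_sets <- function(sets, positives) {
  stopifnot(length(sets) %in% 2:3, !is.null(names(sets)))
  keysets <- lapply(sets, function(s) unique(pair_key(s$domain_i, s$domain_j)))
  universe <- unique(unlist(keysets))
  member <- vapply(keysets, function(k) universe %in% k, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  tp <- universe %in% rel_keys(positives)
  patterns <- expand.grid(rep(list(c("YES", "NO", "-")), length(sets)),
                          stringsAsFactors = FALSE)
  names(patterns) <- names(sets)
  patterns <- patterns[apply(patterns == "YES", 1L, any), , drop = FALSE]
  res <- lapply(seq_len(nrow(patterns)), function(r) {
    sel <- rep(TRUE, length(universe))
    for (s in seq_along(sets)) {
      want <- patterns[r, s]
      if (want == "YES") sel <- sel & member[, s]
      else if (want == "NO") sel <- sel & !member[, s]
    }
    c(elements = sum(sel), tp = sum(tp[sel]))
  })
  res <- do.call(rbind, res)
  out <- cbind(patterns, as.data.frame(res))
  out$ppv <- ifelse(out$elements > 0, out$tp / out$elements, NA_real_)
  rownames(out) <- NULL
  out
}

#' Coupling significance threshold from local PPV
#'
#' Operationalizes reading a significance cutoff off the overlaid histograms
#' of all couplings versus known-positive couplings: pairs are ranked by
#' descending coupling, the local PPV at rank `k` is the positive fraction in
#' a window of `window` ranked pairs centered on `k`, and the threshold is
#' the coupling value at the deepest rank down to which the local PPV has
#' stayed at or above `min_ppv`.
#'
#' @param model a `coupling_model` (or `phydca` fit).
#' @param positives a nonempty `relation_set`.
#' @param window window size in ranked pairs (default 100).
#' @param min_ppv local-PPV requirement (default 0.5).
#' @param use_apc rank by APC-corrected scores.
#' @return an object of class `significance_threshold`: list with `threshold`
#'   (`NA` if the criterion is never met), `rank`, `local_ppv`, and the two
#'   histograms `hist_all` and `hist_positive` on common breaks.
#' @export
significance_threshold <- function(model, positives, window = 100,
                                   min_ppv = 0.5, use_apc = FALSE) {
  if (!nrow(positives)) stop("positive set is empty")
  ranked <- rank_pairs(model, use_apc = use_apc, tail = "positive")
  n <- nrow(ranked)
  hit <- pair_key(ranked$domain_i, ranked$domain_j) %in% rel_keys(positives)
  half_lo <- ceiling(window / 2) - 1L
  half_hi <- window - half_lo - 1L
  cs <- c(0, cumsum(hit))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  local_ppv <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  below <- which(local_ppv < min_ppv)
  rank_star <- if (!length(below)) n else below[1L] - 1L
  off <- model$J[upper.tri(model$J)]
  br <- pretty(range(off), n = 80)
  hist_all <- graphics::hist(off, breaks = br, plot = FALSE)
  pos_scores <- ranked$score[hit]
  hist_pos <- if (length(pos_scores))
    graphics::hist(pos_scores, breaks = br, plot = FALSE) else NULL
  structure(list(threshold = if (rank_star >= 1L) ranked$score[rank_star] else NA_real_,
                 rank = rank_star, window = window, min_ppv = min_ppv,
                 local_ppv = local_ppv, hist_all = hist_all,
                 hist_positive = hist_pos),
            class = "significance_threshold")
}

#' @export
print.significance_threshold <- function(x, ...) {
  if (is.na(x$threshold))
    cat(sprintf("No significance threshold: local PPV (window %d) never reaches %.2f\n",
                x$window, x$min_ppv))
  else
    cat(sprintf("Significance threshold: J = %.4f (local PPV >= %.2f down to rank %d, window %d)\n",
                x$threshold, x$min_ppv, x$rank, x$window))
  invisible(x)
}
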