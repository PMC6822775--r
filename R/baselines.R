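## Pair-score lists ----------------------------------------------------------

new_pair_scores <- function(i, j, score, score_kind, direction) {
  stopifnot(direction %in% c("asc", "desc"), all(is.finite(score)))
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  ord <- if (direction == "desc") order(-score, i, j, method = "radix")
         else order(score, i, j, method = "radix")
  out <- data.frame(domain_i = i[ord], domain_j = j[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  structure(out, score_kind = score_kind, direction = direction,
            class = c("pair_scores", "data.frame"))
}

#' @export
print.pair_scores <- function(x, ...) {
  cat(sprintf("Pair scores: %d pairs, measure '%s' (%s = more related)\n",
              nrow(x), attr(x, "score_kind"),
              if (identical(attr(x, "direction"), "asc")) "smaller" else "larger"))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

## upper-triangle pair indices of the domain set of a PPM
pair_indices <- function(n) {
  idx <- which(upper.tri(matrix(NA, n, n)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

check_pairable <- function(ppm) {
  validate_ppm(ppm)
  if (ncol(ppm) < 2L) stop("need at least two domains to score pairs")
}

## Correlation baselines -----------------------------------------------------

#' Hamming-distance profile similarity
#'
#' Classical phylogenetic-profiling baseline: the fraction of genomes in which
#' exactly one of the two domains is present. Smaller distance means more
#' similar profiles.
#'
#' @param ppm binary profile matrix.
#' @return a `pair_scores` data frame (`domain_i`, `domain_j`, `score`) sorted
#'   most-related first, with attributes `score_kind` and `direction`.
#' @export
hamming_scores <- function(ppm) {
  check_pairable(ppm)
  co <- crossprod(ppm)                      # co-presence counts
  cnt <- diag(co)
  mism <- outer(cnt, cnt, "+") - 2 * co     # n10 + n01
  p <- pair_indices(ncol(ppm))
  new_pair_scores(colnames(ppm)[p$i], colnames(ppm)[p$j],
                  mism[cbind(p$i, p$j)] / nrow(ppm),
                  score_kind = "hamming", direction = "asc")
}

#' Pearson-correlation profile similarity
#'
#' Sample Pearson correlation between two binary profile columns. Ranking is
#' by signed correlation, descending: anti-correlated pairs are ranked last,
#' not folded into "related".
#'
#' @inheritParams hamming_scores
#' @return a `pair_scores` data frame, larger score = more related.
#' @export
pearson_scores <- function(ppm) {
  check_pairable(ppm)
  v <- apply(ppm, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance domain column(s): ", paste(colnames(ppm)[v == 0], collapse = ", "),
         " (apply filter_by_frequency first)")
  r <- stats::cor(ppm)
  p <- pair_indices(ncol(ppm))
  new_pair_scores(colnames(ppm)[p$i], colnames(ppm)[p$j], r[cbind(p$i, p$j)],
                  score_kind = "pearson", direction = "desc")
}

## two-sided Fisher exact p for a 2x2 table given by co-presence count a,
## column counts ci, cj and genome count M; "probability at most that of the
## observed table" rule with the customary 1e-7 relative tolerance
fisher_p2 <- function(a, ci, cj, M) {
  lo <- max(0L, ci + cj - M)
  hi <- min(ci, cj)
  x <- lo:hi
  pr <- stats::dhyper(x, cj, M - cj, ci)
  min(1, sum(pr[pr <= pr[a - lo + 1L] * (1 + 1e-7)]))
}

#' Fisher's exact test profile association
#'
#' Two-sided Fisher's exact test on the 2x2 contingency table of co-presence,
#' single presence and co-absence of two domains across genomes. The two-sided
#' p-value sums all hypergeometric tables with the observed margins whose
#' probability does not exceed that of the observed table. Smaller p = more
#' related.
#'
#' @inheritParams hamming_scores
#' @return a `pair_scores` data frame, smaller score = more related.
#' @export
fisher_scores <- function(ppm) {
  check_pairable(ppm)
  M <- nrow(ppm)
  co <- crossprod(ppm)
  cnt <- diag(co)
  p <- pair_indices(ncol(ppm))
  a <- co[cbind(p$i, p$j)]
  ci <- cnt[p$i]
  cj <- cnt[p$j]
  # identical tables share the p-value: compute once per unique (a, ci, cj)
  key <- paste(a, pmin(ci, cj), pmax(ci, cj))
  uk <- !duplicated(key)
  pv <- vapply(which(uk), function(k) fisher_p2(a[k], ci[k], cj[k], M), 0)
  scores <- pv[match(key, key[uk])]
  new_pair_scores(colnames(ppm)[p$i], colnames(ppm)[p$j], scores,
                  score_kind = "fisher_p", direction = "asc")
}

#' Write / read a pair-score list as TSV
#'
#' Layout: `domain_i<TAB>domain_j<TAB>score`, rows in ranked order (most
#' related first). The `score_kind` and `direction` attributes are stored in a
#' `# key=value` comment header.
#'
#' @param scores a `pair_scores` object.
#' @param path file path.
#' @export
write_pair_scores <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# score_kind=%s", attr(scores, "score_kind")),
               sprintf("# direction=%s", attr(scores, "direction"))), con)
  utils::write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_scores
#' @export
read_pair_scores <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- sub("^# [a-z_]+=", "", hdr)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                          quote = "", comment.char = "",
                          colClasses = c("character", "character", "numeric"))
  new_pair_scores(df$domain_i, df$domain_j, df$score,
                  score_kind = meta[1L], direction = meta[2L])
}
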