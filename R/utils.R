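logistic <- function(x) 1 / (1 + exp(-x))

## canonical unordered-pair key; \r never occurs in identifiers read from TSV
pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")

## evaluate expr under a local seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Wilcoxon/Mann-Whitney AUC: P(score_pos > score_neg) with ties counted 1/2
rank_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos)
  n0 <- length(scores_neg)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

validate_ppm <- function(ppm) {
  if (!is.matrix(ppm)) stop("profile matrix must be a matrix")
  if (is.null(rownames(ppm)) || is.null(colnames(ppm)))
    stop("profile matrix must carry genome (row) and domain (column) identifiers")
  if (anyDuplicated(rownames(ppm))) stop("duplicate genome identifiers")
  if (anyDuplicated(colnames(ppm))) stop("duplicate domain identifiers")
  if (length(ppm) && !all(ppm %in% c(0L, 1L)))
    stop("profile matrix entries must be 0 or 1")
  invisible(ppm)
}

split_id_list <- function(x) {
  out <- strsplit(as.character(x), ",", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}
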