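#' Build a binary phylogenetic profile matrix
#'
#' Collapses long-format domain occurrence records into a binary genome x
#' domain presence/absence matrix (phylogenetic profile matrix, PPM). A domain
#' is scored present in a genome if at least one record for the pair exists;
#' copy numbers beyond the first are discarded, so repeated or multi-copy
#' records merge idempotently.
#'
#' @param occurrences data frame with columns `genome_id`, `domain_id` and
#'   optionally `count` (copy number, strictly positive).
#' @return integer matrix with values in `{0, 1}`, rows named by genome and
#'   columns by domain, both sorted lexicographically (C collation).
#' @examples
#' occ <- data.frame(genome_id = c("g1", "g1", "g2"),
#'                   domain_id = c("dA", "dB", "dA"), count = c(3, 1, 1))
#' build_ppm(occ)
#' @seealso [filter_by_frequency()], [restrict_to_reference()], [write_ppm()]
#' @export
build_ppm <- function(occurrences) {
  occurrences <- as.data.frame(occurrences)
  if (nrow(occurrences) == 0L) stop("no occurrence records: cannot build a profile matrix")
  if (!all(c("genome_id", "domain_id") %in% names(occurrences)))
    stop("occurrences must have columns 'genome_id' and 'domain_id'")
  g <- as.character(occurrences$genome_id)
  d <- as.character(occurrences$domain_id)
  if (any(!nzchar(g)) || any(!nzchar(d))) stop("empty identifiers in occurrence records")
  if (!is.null(occurrences$count) && any(occurrences$count < 1))
    stop("copy numbers must be strictly positive")
  # C collation so ordering is independent of the session locale
  genomes <- sort(unique(g), method = "radix")
  domains <- sort(unique(d), method = "radix")
  ppm <- matrix(0L, length(genomes), length(domains),
                dimnames = list(genomes, domains))
  ppm[cbind(match(g, genomes), match(d, domains))] <- 1L
  ppm
}

#' Integer presence-count bounds implied by fractional frequency cutoffs
#'
#' For `M` genomes, a lower frequency cutoff `f_min` and an upper cutoff
#' `f_max`, a domain is retained if its presence count lies in
#' `[ceiling(f_min * M), floor(f_max * M)]`. With `M = 1041` and the 5%/95%
#' cutoffs this gives counts between 53 and 988.
#'
#' @param M number of genomes.
#' @param f_min,f_max frequency cutoffs in `[0, 1]`.
#' @return integer vector `c(lower, upper)` of inclusive presence-count bounds.
#' @export
presence_bounds <- function(M, f_min, f_max) {
  stopifnot(M >= 1, f_min >= 0, f_max <= 1, f_min <= f_max)
  c(lower = as.integer(ceiling(f_min * M)), upper = as.integer(floor(f_max * M)))
}

#' Filter domains by presence frequency
#'
#' Removes near-absent and near-omnipresent domain columns, which carry no
#' covariation signal. Column `i` is kept iff its presence count lies within
#' [presence_bounds()] for the given cutoffs. Rows are never touched.
#'
#' @param ppm binary profile matrix (see [build_ppm()]).
#' @param f_min,f_max frequency cutoffs; defaults 0.05 and 0.95.
#' @return the filtered profile matrix (possibly with zero columns, with a
#'   warning).
#' @export
filter_by_frequency <- function(ppm, f_min = 0.05, f_max = 0.95) {
  validate_ppm(ppm)
  if (nrow(ppm) == 0L) stop("profile matrix has no genomes")
  b <- presence_bounds(nrow(ppm), f_min, f_max)
  counts <- colSums(ppm)
  keep <- counts >= b[["lower"]] & counts <= b[["upper"]]
  if (!any(keep)) warning("frequency filter removed every domain")
  ppm[, keep, drop = FALSE]
}

#' Restrict a profile matrix to a reference domain set
#'
#' Keeps only the columns whose identifier belongs to `reference_domains`
#' (e.g. the domains present in a reference genome such as E. coli K12);
#' column order is preserved.
#'
#' @param ppm binary profile matrix.
#' @param reference_domains character vector of domain identifiers.
#' @return the restricted profile matrix.
#' @export
restrict_to_reference <- function(ppm, reference_domains) {
  validate_ppm(ppm)
  keep <- colnames(ppm) %in% reference_domains
  if (!any(keep) && ncol(ppm) > 0L)
    warning("reference set shares no domain with the profile matrix")
  ppm[, keep, drop = FALSE]
}

#' Read domain occurrence records
#'
#' Two plain-text layouts are supported: `"long"`, a TSV with header
#' `genome_id<TAB>domain_id<TAB>count`; and `"presence"`, one genome per line
#' as `genome_id<TAB>dom1,dom2,...`.
#'
#' @param path file path.
#' @param format `"long"` or `"presence"`.
#' @return data frame with columns `genome_id`, `domain_id`, `count`.
#' @export
read_occurrences <- function(path, format = c("long", "presence")) {
  format <- match.arg(format)
  if (format == "long") {
    occ <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character", "numeric"),
                             quote = "", comment.char = "")
    names(occ) <- c("genome_id", "domain_id", "count")
    return(occ)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  doms <- split_id_list(vapply(parts, `[`, "", 2L))
  data.frame(genome_id = rep(vapply(parts, `[`, "", 1L), lengths(doms)),
             domain_id = unlist(doms, use.names = FALSE),
             count = 1, stringsAsFactors = FALSE)
}

#' Write / read a profile matrix as TSV
#'
#' The on-disk layout is a TSV whose first column is `genome_id` and whose
#' remaining columns are the domain identifiers, with 0/1 cells. The
#' round-trip `read_ppm(write_ppm(x))` is bit-exact.
#'
#' @param ppm binary profile matrix.
#' @param path file path.
#' @return `write_ppm` returns `path` invisibly; `read_ppm` returns the matrix.
#' @export
write_ppm <- function(ppm, path) {
  validate_ppm(ppm)
  df <- data.frame(genome_id = rownames(ppm), ppm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  validate_ppm(m)
  m
}
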