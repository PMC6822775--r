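## Positive relation sets -----------------------------------------------------

## canonical constructor: unordered, deduplicated, no self-pairs, sources
## comma-joined and sorted per pair
new_relation_set <- function(i, j, sources) {
  i <- as.character(i); j <- as.character(j)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  if (length(sources) == 1L) sources <- rep(sources, length(i))
  else sources <- sources[keep]
  a <- pmin(i, j); b <- pmax(i, j)
  src <- split(strsplit(sources, ",", fixed = TRUE), paste(a, b, sep = "\r"))
  key <- names(src)
  src <- vapply(src, function(s) paste(sort(unique(unlist(s))), collapse = ","), "")
  parts <- strsplit(key, "\r", fixed = TRUE)
  out <- data.frame(domain_i = vapply(parts, `[`, "", 1L),
                    domain_j = vapply(parts, `[`, "", 2L),
                    sources = unname(src), stringsAsFactors = FALSE)
  out <- out[order(out$domain_i, out$domain_j, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("relation_set", "data.frame"))
}

empty_relation_set <- function() {
  structure(data.frame(domain_i = character(), domain_j = character(),
                       sources = character(), stringsAsFactors = FALSE),
            class = c("relation_set", "data.frame"))
}

#' @export
print.relation_set <- function(x, ...) {
  cat(sprintf("Relation set: %d unordered domain pairs\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(unlist(strsplit(x$sources, ",", fixed = TRUE)))
    cat("  by evidence source:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    print.data.frame(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("...\n")
  }
  invisible(x)
}

## all unordered pairs of distinct elements of a character vector
pairs_within <- function(doms) {
  doms <- unique(doms)
  if (length(doms) < 2L) return(NULL)
  cb <- utils::combn(doms, 2L)
  list(i = cb[1L, ], j = cb[2L, ])
}

arch_domain_list <- function(architectures) {
  doms <- if (is.list(architectures$domains) && !is.character(architectures$domains))
    architectures$domains else split_id_list(architectures$domains)
  stats::setNames(doms, architectures$protein_id)
}

#' Domain pairs co-occurring inside single proteins
#'
#' All unordered pairs of distinct domains found within one protein's
#' architecture; repeated copies of the same domain yield no self-pair.
#'
#' @param architectures data frame with columns `protein_id` and `domains`
#'   (comma-separated domain identifiers, or a list column).
#' @return a `relation_set` with source label `"intra_protein"`.
#' @export
intra_protein_pairs <- function(architectures) {
  doms <- arch_domain_list(architectures)
  ps <- lapply(doms, pairs_within)
  ps <- ps[!vapply(ps, is.null, TRUE)]
  if (!length(ps)) return(empty_relation_set())
  new_relation_set(unlist(lapply(ps, `[[`, "i")), unlist(lapply(ps, `[[`, "j")),
                   "intra_protein")
}

#' Domain pairs co-localized in operons
#'
#' All unordered pairs of distinct domains carried by (possibly different)
#' proteins belonging to the same operon.
#'
#' @param operons data frame with columns `operon_id` and `proteins`
#'   (comma-separated protein identifiers, or a list column).
#' @param architectures protein architecture table as in
#'   [intra_protein_pairs()]; operon members without an architecture are
#'   skipped with a warning.
#' @return a `relation_set` with source label `"operon"`.
#' @export
operon_pairs <- function(operons, architectures) {
  arch <- arch_domain_list(architectures)
  members <- if (is.list(operons$proteins) && !is.character(operons$proteins))
    operons$proteins else split_id_list(operons$proteins)
  unknown <- setdiff(unique(unlist(members)), names(arch))
  if (length(unknown))
    warning("operon member(s) without architecture skipped: ",
            paste(unknown, collapse = ", "))
  ps <- lapply(members, function(m)
    pairs_within(unlist(arch[intersect(m, names(arch))], use.names = FALSE)))
  ps <- ps[!vapply(ps, is.null, TRUE)]
  if (!length(ps)) return(empty_relation_set())
  new_relation_set(unlist(lapply(ps, `[[`, "i")), unlist(lapply(ps, `[[`, "j")),
                   "operon")
}

#' Domain pairs from protein-protein interactions
#'
#' For every interacting protein pair, all domains of the first protein are
#' paired with all domains of the second (full bipartite expansion, distinct
#' domains only) — a deliberately permissive rule that adds possibly
#' unrelated domain pairs alongside the truly interacting ones.
#'
#' @param interactions data frame with columns `protein_a`, `protein_b`.
#' @param architectures protein architecture table; interactions naming an
#'   unknown protein are skipped with a warning.
#' @return a `relation_set` with source label `"ppi"`.
#' @export
ppi_pairs <- function(interactions, architectures) {
  arch <- arch_domain_list(architectures)
  pa <- as.character(interactions$protein_a)
  pb <- as.character(interactions$protein_b)
  known <- pa %in% names(arch) & pb %in% names(arch)
  if (any(!known))
    warning("interaction(s) with unknown protein skipped: ",
            paste(unique(c(pa[!known], pb[!known])), collapse = ", "))
  ii <- character(0); jj <- character(0)
  for (k in which(known)) {
    da <- unique(arch[[pa[k]]]); db <- unique(arch[[pb[k]]])
    grid <- expand.grid(i = da, j = db, stringsAsFactors = FALSE)
    grid <- grid[grid$i != grid$j, , drop = FALSE]
    ii <- c(ii, grid$i); jj <- c(jj, grid$j)
  }
  if (!length(ii)) return(empty_relation_set())
  new_relation_set(ii, jj, "ppi")
}

#' Structure-derived domain contact pairs
#'
#' Passthrough reader for a pre-computed list of domain-domain pairs in
#' physical contact in solved structures (iPfam-style); the pairs participate
#' in [merge_relations()] like any computed evidence class.
#'
#' @param pairs data frame with columns `domain_i`, `domain_j`.
#' @return a `relation_set` with source label `"structure"`.
#' @export
structure_pairs <- function(pairs) {
  if (!nrow(pairs)) return(empty_relation_set())
  new_relation_set(pairs$domain_i, pairs$domain_j, "structure")
}

#' Domain pairs of metabolically related enzymes
#'
#' From a reaction table, first removes "currency" metabolites — those
#' participating (as substrate or product) in more than `currency_threshold`
#' reactions, such as water or ATP — then relates two reactions if they share
#' a substrate, share a product, or chain (a product of one is a substrate of
#' the other, in either direction). Each related reaction pair contributes
#' all cross pairs of the two reactions' enzyme domain sets.
#'
#' @param reactions data frame with columns `reaction_id`, `domains`,
#'   `substrates`, `products` (comma-separated lists or list columns).
#' @param currency_threshold reaction-participation count above which a
#'   metabolite is discarded (default 50).
#' @return a `relation_set` with source label `"metabolic"`.
#' @export
metabolic_pairs <- function(reactions, currency_threshold = 50) {
  stopifnot(currency_threshold >= 1)
  aslist <- function(x) if (is.list(x) && !is.character(x)) x else split_id_list(x)
  subs <- aslist(reactions$substrates)
  prods <- aslist(reactions$products)
  doms <- aslist(reactions$domains)
  particip <- table(unlist(mapply(function(s, p) unique(c(s, p)), subs, prods,
                                  SIMPLIFY = FALSE)))
  currency <- names(particip)[particip > currency_threshold]
  subs <- lapply(subs, setdiff, currency)
  prods <- lapply(prods, setdiff, currency)
  R <- nrow(reactions)
  ii <- character(0); jj <- character(0)
  if (R >= 2L) for (r in seq_len(R - 1L)) for (s in (r + 1L):R) {
    related <- length(intersect(subs[[r]], subs[[s]])) > 0 ||
               length(intersect(prods[[r]], prods[[s]])) > 0 ||
               length(intersect(prods[[r]], subs[[s]])) > 0 ||
               length(intersect(prods[[s]], subs[[r]])) > 0
    if (!related) next
    grid <- expand.grid(i = unique(doms[[r]]), j = unique(doms[[s]]),
                        stringsAsFactors = FALSE)
    grid <- grid[grid$i != grid$j, , drop = FALSE]
    ii <- c(ii, grid$i); jj <- c(jj, grid$j)
  }
  if (!length(ii)) return(empty_relation_set())
  new_relation_set(ii, jj, "metabolic")
}

#' Merge relation sets into one deduplicated positive list
#'
#' Set union of unordered domain pairs: a pair supported by several evidence
#' classes appears once, with the union of its source labels.
#'
#' @param ... `relation_set` objects (or a single list of them).
#' @return the merged `relation_set`.
#' @export
merge_relations <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "relation_set"))
    sets <- sets[[1L]]
  sets <- sets[vapply(sets, nrow, 0L) > 0L]
  if (!length(sets)) return(empty_relation_set())
  all <- do.call(rbind, lapply(sets, as.data.frame))
  new_relation_set(all$domain_i, all$domain_j, all$sources)
}

#' Write / read a relation set as TSV
#'
#' Layout: `domain_i<TAB>domain_j<TAB>sources` with sources comma-joined and
#' sorted.
#'
#' @param relations a `relation_set`.
#' @param path file path.
#' @export
write_relations <- function(relations, path) {
  utils::write.table(as.data.frame(relations), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_relations
#' @export
read_relations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", colClasses = "character")
  if (!nrow(df)) return(empty_relation_set())
  new_relation_set(df$domain_i, df$domain_j, df$sources)
}
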