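#' Threshold a coupling model into a signed network
#'
#' Edges are the domain pairs whose coupling exceeds `threshold` in absolute
#' value, carrying the coupling's sign and weight.
#'
#' @param model a `coupling_model` (or `phydca` fit).
#' @param threshold positive cutoff on `|J|` (strict).
#' @param use_apc threshold APC-corrected scores instead of raw couplings.
#' @return an object of class `signed_network`: list with `nodes` (all model
#'   domains), `edges` (data frame `domain_i`, `domain_j`, `weight`, `sign`)
#'   and `threshold`.
#' @export
build_signed_network <- function(model, threshold, use_apc = FALSE) {
  stopifnot(inherits(model, "coupling_model"), threshold > 0)
  if (use_apc && is.null(model$J_apc)) model <- apc_correct(model)
  S <- if (use_apc) model$J_apc else model$J
  p <- pair_indices(ncol(S))
  w <- S[cbind(p$i, p$j)]
  keep <- abs(w) > threshold
  edges <- data.frame(domain_i = model$domain_ids[p$i][keep],
                      domain_j = model$domain_ids[p$j][keep],
                      weight = w[keep],
                      sign = ifelse(w[keep] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = model$domain_ids, edges = edges, threshold = threshold),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("Signed coupling network: %d nodes, %d edges (|J| > %g): %d positive, %d negative\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' Triangle census of a signed network
#'
#' Enumerates every triangle and classifies it by the multiset of its edge
#' signs: `+++`, `++-`, `+--`, `---`. Following the convention used for
#' coupling networks, a "frustrated" triangle is `++-`: a single avoidance
#' link embedded between two co-occurrence links. Also reports how many
#' negative edges participate in at least one triangle.
#'
#' @param net a `signed_network`.
#' @return list with `census` (named counts), `n_triangles`, `frustrated`
#'   (the `++-` count) and `n_negative_edges_in_triangles`.
#' @export
triangle_census <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  census <- c("+++" = 0L, "++-" = 0L, "+--" = 0L, "---" = 0L)
  neg_in_tri <- character(0)
  e <- net$edges
  if (nrow(e) >= 3L) {
    nodes <- sort(unique(c(e$domain_i, e$domain_j)), method = "radix")
    n <- length(nodes)
    A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    s <- ifelse(e$sign == "+", 1L, -1L)
    A[cbind(match(e$domain_i, nodes), match(e$domain_j, nodes))] <- s
    A[cbind(match(e$domain_j, nodes), match(e$domain_i, nodes))] <- s
    ui <- pmin(match(e$domain_i, nodes), match(e$domain_j, nodes))
    vi <- pmax(match(e$domain_i, nodes), match(e$domain_j, nodes))
    for (k in seq_along(ui)) {
      u <- ui[k]; v <- vi[k]
      # count each triangle once at its lexicographically smallest edge
      w <- which(A[u, ] != 0L & A[v, ] != 0L)
      w <- w[w > v]
      for (t in w) {
        signs <- c(A[u, v], A[u, t], A[v, t])
        nneg <- sum(signs < 0L)
        cls <- c("+++", "++-", "+--", "---")[nneg + 1L]
        census[cls] <- census[cls] + 1L
        if (nneg > 0L) {
          tri <- nodes[c(u, v, t)]
          kk <- utils::combn(sort(tri), 2L)
          sgn <- A[cbind(match(kk[1L, ], nodes), match(kk[2L, ], nodes))]
          neg_in_tri <- c(neg_in_tri, pair_key(kk[1L, sgn < 0], kk[2L, sgn < 0]))
        }
      }
    }
  }
  list(census = census, n_triangles = sum(census),
       frustrated = unname(census[["++-"]]),
       n_negative_edges_in_triangles = length(unique(neg_in_tri)))
}

#' Profile correlation versus network distance
#'
#' Computes unweighted shortest-path distances on the signed coupling network
#' and the mean absolute Pearson correlation of profile columns per distance
#' class `d = 1..d_max`; node pairs in different components form the
#' disconnected baseline class. Directly coupled pairs are expected to be the
#' most correlated, with correlations decaying along coupling chains towards
#' a residual background level.
#'
#' @param net a `signed_network`.
#' @param ppm binary profile matrix containing all network nodes as columns.
#' @param d_max largest distance class to report (default 5).
#' @return data frame with columns `distance` (`1..d_max`, then `Inf` for the
#'   disconnected baseline), `mean_abs_r` and `n_pairs`.
#' @export
correlation_vs_distance <- function(net, ppm, d_max = 5) {
  stopifnot(inherits(net, "signed_network"))
  validate_ppm(ppm)
  if (!all(net$nodes %in% colnames(ppm)))
    stop("network nodes missing from the profile matrix")
  nodes <- net$nodes
  g <- igraph::graph_from_data_frame(net$edges[, c("domain_i", "domain_j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  D <- igraph::distances(g)[nodes, nodes]
  r <- stats::cor(ppm[, nodes, drop = FALSE])
  ut <- upper.tri(D)
  d <- D[ut]
  absr <- abs(r[ut])
  cls <- c(seq_len(d_max), Inf)
  data.frame(distance = cls,
             mean_abs_r = vapply(cls, function(k) {
               sel <- if (is.infinite(k)) is.infinite(d) else d == k
               if (any(sel)) mean(absr[sel]) else NA_real_
             }, 0),
             n_pairs = vapply(cls, function(k) {
               sel <- if (is.infinite(k)) is.infinite(d) else d == k
               sum(sel)
             }, 0))
}
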