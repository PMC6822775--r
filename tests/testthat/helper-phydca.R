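# Fixture builders and independent oracles shared across the suite.

# random binary profile matrix with independent Bernoulli(f) columns
random_ppm <- function(M, N, f = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(M * N, 1L, f), M, N,
              dimnames = list(sprintf("g%03d", seq_len(M)),
                              sprintf("d%03d", seq_len(N))))
  storage.mode(m) <- "integer"
  m
}

ppm_from_cols <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  storage.mode(m) <- "integer"
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  m
}

# wrap an arbitrary (J, h) pair as a coupling model for the evaluation tools
as_coupling_model <- function(J, h, domain_ids = colnames(J), method = "mf") {
  phydca:::new_coupling_model(J, h, method = method,
                              regularization = list(), domain_ids = domain_ids)
}

# linear-chain planted model: edges (1,2), (2,3), ...; Jval is recycled along
# the chain, so mixed strong/weak chains can be built
chain_model <- function(N, Jval = 1, h = -0.5) {
  ids <- sprintf("D%02d", seq_len(N))
  w <- rep_len(Jval, N - 1L)
  J <- matrix(0, N, N, dimnames = list(ids, ids))
  for (k in seq_len(N - 1L)) J[k, k + 1L] <- J[k + 1L, k] <- w[k]
  edges <- data.frame(domain_i = ids[-N], domain_j = ids[-1L],
                      weight = w, sign = ifelse(w > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  structure(list(J = J, h = stats::setNames(rep(h, N), ids), edges = edges,
                 domain_ids = ids, seed = NULL),
            class = "planted_model")
}

rel_set <- function(i, j, source = "test") phydca:::new_relation_set(i, j, source)

# Oracle: two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from log-binomial coefficients (independent
# of stats::dhyper). a = co-presence, ci/cj = column presence counts, M total.
oracle_fisher_p <- function(a, ci, cj, M) {
  lo <- max(0L, ci + cj - M)
  hi <- min(ci, cj)
  x <- lo:hi
  logp <- lchoose(cj, x) + lchoose(M - cj, ci - x) - lchoose(M, ci)
  pr <- exp(logp)
  min(1, sum(pr[pr <= pr[a - lo + 1L] * (1 + 1e-7)]))
}

# Oracle: cubic brute-force triangle census over all node triples
oracle_triangle_census <- function(edges) {
  nodes <- sort(unique(c(edges$domain_i, edges$domain_j)))
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  s <- ifelse(edges$sign == "+", 1L, -1L)
  A[cbind(match(edges$domain_i, nodes), match(edges$domain_j, nodes))] <- s
  A[cbind(match(edges$domain_j, nodes), match(edges$domain_i, nodes))] <- s
  census <- c("+++" = 0L, "++-" = 0L, "+--" = 0L, "---" = 0L)
  neg_keys <- character(0)
  if (n >= 3L) for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    if (A[i, j] != 0L && A[i, k] != 0L && A[j, k] != 0L) {
      signs <- c(A[i, j], A[i, k], A[j, k])
      cls <- c("+++", "++-", "+--", "---")[sum(signs < 0L) + 1L]
      census[cls] <- census[cls] + 1L
      for (e in list(c(i, j), c(i, k), c(j, k)))
        if (A[e[1L], e[2L]] < 0L)
          neg_keys <- c(neg_keys, paste(nodes[e[1L]], nodes[e[2L]]))
    }
  }
  list(census = census,
       n_negative_edges_in_triangles = length(unique(neg_keys)))
}

random_signed_edges <- function(n, p_edge = 0.1, p_neg = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  cb <- utils::combn(ids, 2L)
  keep <- runif(ncol(cb)) < p_edge
  sgn <- ifelse(runif(sum(keep)) < p_neg, "-", "+")
  data.frame(domain_i = cb[1L, keep], domain_j = cb[2L, keep],
             weight = ifelse(sgn == "+", 1, -1), sign = sgn,
             stringsAsFactors = FALSE)
}

signed_net <- function(edges, nodes = sort(unique(c(edges$domain_i, edges$domain_j))),
                       threshold = 0.3) {
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "signed_network")
}

pair_keys <- function(rs) paste(rs$domain_i, rs$domain_j, sep = "\r")
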