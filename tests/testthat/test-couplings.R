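test_that("empirical frequencies are exact counts over genomes", {
  m <- ppm_from_cols(a = c(1L, 1L), b = c(1L, 0L))
  fs <- empirical_frequencies(m)
  expect_equal(unname(fs$f), c(1, 0.5))
  expect_equal(fs$fij["a", "b"], 0.5)
  expect_equal(diag(fs$fij), fs$f, ignore_attr = TRUE)

  # an omnipresent domain co-occurs with every other at that other's frequency
  m2 <- ppm_from_cols(ones = rep(1L, 6), x = c(1L, 0L, 1L, 0L, 0L, 1L))
  fs2 <- empirical_frequencies(m2)
  expect_equal(fs2$fij["ones", "x"], fs2$f[["x"]])
})

test_that("pair frequencies respect the Frechet bounds", {
  m <- random_ppm(100, 10, f = 0.4, seed = 17)
  fs <- empirical_frequencies(m)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gte(fs$fij[i, j], max(0, fs$f[i] + fs$f[j] - 1))
    expect_lte(fs$fij[i, j], min(fs$f[i], fs$f[j]))
  }
  # all values are multiples of 1/M
  expect_equal(fs$fij * 100, round(fs$fij * 100))
})

freq_stats <- function(f, fij, M = 100) {
  ids <- sprintf("d%d", seq_along(f))
  dimnames(fij) <- list(ids, ids)
  structure(list(f = stats::setNames(f, ids), fij = fij, M = M,
                 domain_ids = ids), class = "phyletic_freqs")
}

test_that("mean-field coupling matches closed-form 2x2 covariance inversion", {
  fs <- freq_stats(c(0.5, 0.5), matrix(c(0.5, 0.4, 0.4, 0.5), 2))
  fit <- mf_couplings(fs, pseudocount = 0)
  # C = [[.25,.15],[.15,.25]] => -(C^-1)_12 = .15/.04 = 3.75
  expect_equal(fit$J[1, 2], 3.75, tolerance = 1e-10)
  expect_identical(diag(fit$J), c(d1 = 0, d2 = 0))
})

test_that("mean-field couplings vanish for exactly independent columns", {
  # f_ij = f_i f_j exactly by construction
  m <- ppm_from_cols(a = c(1L, 1L, 0L, 0L), b = c(1L, 0L, 1L, 0L))
  fit <- mf_couplings(empirical_frequencies(m), pseudocount = 0)
  expect_equal(fit$J[1, 2], 0, tolerance = 1e-12)
  # biases then reduce to independent-model log-odds
  expect_equal(unname(fit$h), qlogis(c(0.5, 0.5)), tolerance = 1e-12)
})

test_that("mean-field inference disentangles a chain's indirect correlation", {
  # planted chain 1-2-3 with J13 = 0; marginals computed exactly
  truth <- chain_model(3, Jval = 2, h = -0.5)
  ex <- lattice_gas_exact(truth$J, truth$h)
  fs <- freq_stats(ex$f, ex$fij)
  fit <- mf_couplings(fs, pseudocount = 0)
  C <- ex$fij - outer(ex$f, ex$f)
  r13 <- C[1, 3] / sqrt(C[1, 1] * C[3, 3])
  expect_gt(r13, 0.1)                       # indirect correlation is substantial
  expect_lt(abs(fit$J[1, 3]), abs(r13))     # coupling suppresses it
  expect_gt(fit$J[1, 2], 0.5)               # real edges stay strong
})

test_that("singular correlation matrices produce an instructive error", {
  fs <- freq_stats(c(0.5, 0.5), matrix(c(0.5, 0.5, 0.5, 0.5), 2))  # duplicated column
  expect_error(mf_couplings(fs, pseudocount = 0), "pseudocount")
})

test_that("PLM on exhaustively weighted states recovers planted parameters", {
  truth <- make_planted_model(4, n_pos_edges = 2, n_neg_edges = 1,
                              J_scale = 1, h_range = c(-0.8, -0.2), seed = 5)
  ex <- lattice_gas_exact(truth$J, truth$h)
  states <- ex$states
  rownames(states) <- sprintf("s%02d", seq_len(nrow(states)))
  fit <- plm_couplings(states, l2_J = 1e-9, l2_h = 1e-9, weights = ex$prob)
  expect_lt(max(abs(fit$J - truth$J)), 0.05)
  expect_lt(max(abs(fit$h - truth$h)), 0.05)
})

test_that("PLM infers near-zero couplings from an uncoupled model", {
  ids <- sprintf("D%d", 1:6)
  J0 <- matrix(0, 6, 6, dimnames = list(ids, ids))
  h0 <- stats::setNames(seq(-1, 0.2, length.out = 6), ids)
  M <- 10000
  m <- gibbs_sample(list(J = J0, h = h0), n_genomes = M, seed = 8)
  fit <- plm_couplings(m, l2_J = 0.01, l2_h = 0.01)
  # standardize by the asymptotic s.e. of a null logistic coupling,
  # var(J_ij^(i)) ~ 1 / (M p_i(1-p_i) f_j(1-f_j)); the symmetrized estimate
  # averages two near-independent node fits
  f <- plogis(h0)
  v <- 1 / (M * outer(f * (1 - f), f * (1 - f)))
  se_sym <- sqrt((v + t(v)) / 4)
  dev <- abs(fit$J) / se_sym
  diag(dev) <- 0
  expect_lt(max(dev), 4)
})

test_that("PLM output is exactly symmetric with zero diagonal", {
  m <- random_ppm(300, 8, f = 0.4, seed = 19)
  fit <- plm_couplings(m)
  expect_identical(fit$J, t(fit$J))
  expect_identical(diag(fit$J), stats::setNames(rep(0, 8), colnames(m)))
  expect_error(plm_couplings(ppm_from_cols(a = rep(1L, 5), b = c(1L, 0L, 1L, 0L, 1L))),
               "constant")
})

test_that("APC annihilates a uniform coupling background", {
  ids <- sprintf("D%d", 1:8)
  J <- matrix(0.7, 8, 8, dimnames = list(ids, ids)); diag(J) <- 0
  fit <- apc_correct(as_coupling_model(J, rep(0, 8)))
  expect_equal(max(abs(fit$J_apc)), 0, tolerance = 1e-12)
})

test_that("APC of a single nonzero coupling matches direct evaluation", {
  # lone coupling c at N=50: row means c/(N-1), grand mean 2c/(N(N-1)),
  # so the subtracted term is c*N/(2(N-1)) -- roughly half the signal
  N <- 50; cval <- 0.8
  ids <- sprintf("D%02d", 1:N)
  J <- matrix(0, N, N, dimnames = list(ids, ids))
  J[1, 2] <- J[2, 1] <- cval
  fit <- apc_correct(as_coupling_model(J, rep(0, N)))
  expect_equal(fit$J_apc[1, 2], cval - cval * N / (2 * (N - 1)), tolerance = 1e-12)
  # untouched pairs not adjacent to the edge stay at zero
  expect_equal(fit$J_apc[5, 9], 0, tolerance = 1e-12)
})

test_that("APC is equivariant under domain relabeling and preserves structure", {
  set.seed(23)
  m <- random_ppm(200, 10, f = 0.4, seed = 23)
  fit <- apc_correct(phydca(m, method = "mf", apc = FALSE))
  expect_equal(fit$J_apc, t(fit$J_apc))
  expect_equal(unname(diag(fit$J_apc)), rep(0, 10))
  perm <- sample(10)
  fitp <- apc_correct(phydca(m[, perm], method = "mf", apc = FALSE))
  expect_equal(fitp$J_apc[colnames(m), colnames(m)], fit$J_apc, tolerance = 1e-10)
})

test_that("pair ranking splits tails by sign with lexicographic tie-breaks", {
  ids <- c("A", "B", "C")
  J <- matrix(0, 3, 3, dimnames = list(ids, ids))
  J["A", "B"] <- J["B", "A"] <- 0.9
  J["A", "C"] <- J["C", "A"] <- -0.5
  J["B", "C"] <- J["C", "B"] <- 0.1
  mod <- as_coupling_model(J, rep(0, 3))
  pos <- rank_pairs(mod, tail = "positive")
  neg <- rank_pairs(mod, tail = "negative")
  expect_identical(paste(pos$domain_i, pos$domain_j), c("A B", "B C"))
  expect_identical(paste(neg$domain_i, neg$domain_j), "A C")

  # equal scores fall back to lexicographic pair order
  J2 <- J; J2["B", "C"] <- J2["C", "B"] <- 0.9
  pos2 <- rank_pairs(as_coupling_model(J2, rep(0, 3)))
  expect_identical(paste(pos2$domain_i, pos2$domain_j), c("A B", "B C"))

  # biases never enter the ranking
  mod$h <- mod$h + 5
  expect_identical(as.data.frame(rank_pairs(mod)), as.data.frame(pos))
})

test_that("coupling models serialize couplings, APC scores and biases", {
  m <- random_ppm(200, 6, f = 0.4, seed = 29)
  fit <- phydca(m, method = "mf")
  path <- tempfile(fileext = ".tsv")
  write_couplings(fit, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), choose(6, 2))
  expect_equal(df$J, fit$J[cbind(match(df$domain_i, colnames(m)),
                                 match(df$domain_j, colnames(m)))],
               tolerance = 1e-10)
  expect_equal(df$J_apc, fit$J_apc[cbind(match(df$domain_i, colnames(m)),
                                         match(df$domain_j, colnames(m)))],
               tolerance = 1e-10)
  meta <- readLines(paste0(path, ".meta"))
  expect_true(any(grepl("^method\tmf$", meta)))
  expect_length(grep("^h\\.", meta), 6)
})
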