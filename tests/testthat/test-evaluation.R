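# a ranking whose pairs and scores are fully under our control
ranking_fixture <- function(pairs, scores) {
  phydca:::new_pair_scores(vapply(pairs, `[`, "", 1L), vapply(pairs, `[`, "", 2L),
                           scores, score_kind = "coupling", direction = "desc")
}

test_that("PPV is the cumulative positive fraction of the ranking", {
  preds <- ranking_fixture(list(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c")),
                           c(4, 3, 2, 1))
  pos <- rel_set(c("a", "a"), c("b", "d"))  # positives at ranks 1 and 3
  curve <- ppv_curve(preds, pos)
  expect_equal(curve$ppv, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(curve$ppv * curve$k, round(curve$ppv * curve$k))  # integer TP counts

  all_pos <- rel_set(preds$domain_i, preds$domain_j)
  expect_equal(ppv_curve(preds, all_pos)$ppv, rep(1, 4))  # perfect-prediction envelope

  expect_warning(z <- ppv_curve(preds, rel_set(character(), character())), "empty")
  expect_equal(z$ppv, rep(0, 4))
})

test_that("random rankings have hypergeometric expected PPV", {
  set.seed(47)
  doms <- sprintf("d%02d", 1:25)
  cb <- utils::combn(doms, 2L)                 # 300 pairs
  n <- ncol(cb)
  pos_idx <- sample(n, 30)                     # base rate 0.1
  pos <- rel_set(cb[1L, pos_idx], cb[2L, pos_idx])
  k <- 50
  vals <- replicate(200, {
    ord <- sample(n)
    preds <- ranking_fixture(asplit(cb[, ord], 2L), seq(n, 1))
    ppv_curve(preds, pos, k_max = k)$ppv[k]
  })
  expect_lt(abs(mean(vals) - 30 / n), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("enrichment bins count overlapping category membership per bin", {
  doms <- sprintf("d%02d", 1:30)
  cb <- utils::combn(doms, 2L)
  preds <- ranking_fixture(asplit(cb[, 1:200], 2L), seq(200, 1))
  cat40 <- rel_set(cb[1L, 1:40], cb[2L, 1:40])           # first 40 ranked pairs
  cat_overlap <- rel_set(cb[1L, 1:100], cb[2L, 1:100])   # overlaps cat40 entirely
  out <- enrichment_bins(preds, list(a = cat40, b = cat_overlap), bin_size = 100)
  expect_equal(out$a, c(40, 0))
  expect_equal(out$b, c(100, 0))
  expect_gt(out$a[1] + out$b[1], 100)  # categories overlap, sums may exceed the bin
  empty <- enrichment_bins(preds, list(none = rel_set(character(), character())),
                           bin_size = 100)
  expect_equal(empty$none, c(0, 0))
})

test_that("prediction-set comparison enumerates membership patterns", {
  A <- ranking_fixture(list(c("dA", "dB"), c("dA", "dC")), c(2, 1))
  B <- ranking_fixture(list(c("dA", "dB"), c("dA", "dD")), c(2, 1))
  pos <- rel_set("dA", "dB")
  tab <- compare_prediction_sets(list(A = A, B = B), pos)
  row <- function(a, b) tab[tab$A == a & tab$B == b, ]
  expect_equal(row("YES", "YES")[, c("elements", "tp", "ppv")],
               data.frame(elements = 1, tp = 1, ppv = 1), ignore_attr = TRUE)
  expect_equal(row("YES", "NO")$elements, 1)
  expect_equal(row("YES", "NO")$tp, 0)
  expect_equal(row("NO", "YES")$elements, 1)

  same <- compare_prediction_sets(list(A = A, B = A), pos)
  expect_equal(same[same$A == "YES" & same$B == "NO", "elements"], 0)
  expect_equal(same[same$A == "NO" & same$B == "YES", "elements"], 0)
})

test_that("pattern counts satisfy aggregation and inclusion-exclusion identities", {
  set.seed(53)
  doms <- sprintf("d%02d", 1:20)
  cb <- utils::combn(doms, 2L)
  mk_set <- function(k) {
    idx <- sample(ncol(cb), k)
    ranking_fixture(asplit(cb[, idx], 2L), seq(k, 1))
  }
  sets <- list(X = mk_set(60), Y = mk_set(80), Z = mk_set(50))
  pos_idx <- sample(ncol(cb), 40)
  pos <- rel_set(cb[1L, pos_idx], cb[2L, pos_idx])
  tab <- compare_prediction_sets(sets, pos)
  g <- function(x, y, z) {
    r <- tab[tab$X == x & tab$Y == y & tab$Z == z, ]
    if (nrow(r)) r$elements else 0
  }
  # aggregated '-' rows equal the sum of their YES/NO refinements
  expect_equal(g("YES", "-", "-"), g("YES", "YES", "-") + g("YES", "NO", "-"))
  expect_equal(g("YES", "-", "-"), g("YES", "-", "YES") + g("YES", "-", "NO"))
  # fully specified patterns partition the union of the three sets
  full <- tab[tab$X != "-" & tab$Y != "-" & tab$Z != "-", ]
  universe <- unique(c(pair_keys(sets$X), pair_keys(sets$Y), pair_keys(sets$Z)))
  expect_equal(sum(full$elements), length(universe))
})

test_that("significance threshold is read off where local PPV drops below 1/2", {
  # 780 ranked pairs; the top 500 are exactly the positives
  N <- 40
  ids <- sprintf("D%02d", 1:N)
  J <- matrix(0, N, N, dimnames = list(ids, ids))
  p <- phydca:::pair_indices(N)
  scores <- seq(2, 0.05, length.out = length(p$i))
  J[cbind(p$i, p$j)] <- scores
  J <- J + t(J)
  mod <- as_coupling_model(J, rep(0, N))
  ranked <- rank_pairs(mod)
  pos <- rel_set(ranked$domain_i[1:500], ranked$domain_j[1:500])
  th <- significance_threshold(mod, pos, window = 100)
  expect_equal(th$rank, 500)
  expect_equal(th$threshold, ranked$score[500])

  # positives scattered uniformly -> no threshold
  set.seed(59)
  scat <- sample(nrow(ranked), 60)
  th2 <- significance_threshold(mod, rel_set(ranked$domain_i[scat],
                                             ranked$domain_j[scat]), window = 100)
  expect_true(is.na(th2$threshold))
  expect_error(significance_threshold(mod, rel_set(character(), character())),
               "empty")
})

test_that("signed networks keep couplings above threshold with their signs", {
  ids <- c("A", "B", "C")
  J <- matrix(0, 3, 3, dimnames = list(ids, ids))
  J["A", "B"] <- J["B", "A"] <- 0.4
  J["A", "C"] <- J["C", "A"] <- -0.35
  J["B", "C"] <- J["C", "B"] <- 0.1
  mod <- as_coupling_model(J, rep(0, 3))
  net <- build_signed_network(mod, 0.3)
  expect_identical(paste(net$edges$domain_i, net$edges$domain_j, net$edges$sign),
                   c("A B +", "A C -"))
  expect_identical(nrow(build_signed_network(mod, 10)$edges), 0L)
  # edge count non-increasing in the threshold
  counts <- vapply(c(0.05, 0.2, 0.36, 0.5), function(t)
    nrow(build_signed_network(mod, t)$edges), 0L)
  expect_true(all(diff(counts) <= 0))
})
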