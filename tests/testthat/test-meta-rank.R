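test_that("effect-size conversion chain matches the quantile oracle", {
  # independent evaluation of the p -> chi2 -> phi -> d chain
  p <- 0.3173; n <- 100
  chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  phi <- sqrt(chi2 / n)
  d_expected <- 2 * phi / sqrt(1 - phi^2)
  res <- effect_size_meta(p, n, +1)
  expect_equal(res$d, d_expected, tolerance = 1e-10)
  expect_equal(res$d, 0.2010, tolerance = 1e-3)

  # zero-effect identity
  expect_equal(effect_size_meta(1, 50, +1)$pooled_d, 0)

  # k identical studies: pooled d equals the single-study d
  one <- effect_size_meta(0.05, 20, -1)
  many <- effect_size_meta(rep(0.05, 7), 20, rep(-1, 7))
  expect_equal(many$pooled_d, one$pooled_d, tolerance = 1e-12)
  expect_lt(many$p, one$p)  # variance scales 1/k, so evidence accumulates

  expect_error(effect_size_meta(0.5, 3, 1), "sample size")
})

test_that("Fisher sum-of-logs matches closed forms", {
  r <- fisher_meta(c(0.5, 0.5))
  expect_equal(r$X2, -2 * (log(0.5) + log(0.5)), tolerance = 1e-12)
  expect_equal(r$df, 4)
  # chi-square survival closed form for df = 4: e^{-x/2} (1 + x/2)
  expect_equal(r$combined_p, exp(-r$X2 / 2) * (1 + r$X2 / 2),
               tolerance = 1e-12)

  r1 <- fisher_meta(c(1, 1, 1))
  expect_equal(r1$X2, 0)
  expect_equal(r1$combined_p, 1)

  r2 <- fisher_meta(c(0.01, 0.02, 0.03))
  expect_equal(r2$X2, -2 * sum(log(c(0.01, 0.02, 0.03))), tolerance = 1e-10)
  expect_equal(r2$X2, 24.0476, tolerance = 1e-4)
  expect_equal(r2$df, 6)

  expect_error(fisher_meta(numeric(0)), "empty")
})

test_that("rank product equals geometric means and exhaustive null", {
  # ranks (1,2,4) over 3 contrasts -> RP = 2 exactly
  p <- matrix(c(0.1, 0.2, 0.3, 0.4,
                0.1, 0.2, 0.3, 0.4,
                0.2, 0.3, 0.1, 0.4), 4, 3,
              dimnames = list(letters[1:4], NULL))
  rp <- rank_product_meta(p)
  expect_equal(unname(rp$rp_values["a"]), (1 * 1 * 2)^(1 / 3))
  expect_equal(unname(rp$rp_values["c"]), (3 * 3 * 1)^(1 / 3))

  # all ranks 1 -> RP = 1, the minimum
  p2 <- matrix(c(0.01, 0.5, 0.9, 0.01, 0.4, 0.8), 3, 2,
               dimnames = list(letters[1:3], NULL))
  rp2 <- rank_product_meta(p2)
  expect_equal(unname(rp2$rp_values["a"]), 1)
  # exhaustive null for G = 3, D = 2: P(RP = 1) = 1/9
  expect_equal(unname(rp2$rp_p["a"]), 1 / 9)
})

test_that("rank product depends only on within-contrast orderings", {
  set.seed(11)
  p <- matrix(runif(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), NULL))
  a <- rank_product_meta(p, n_perm = 200, seed = 5)
  b <- rank_product_meta(sqrt(p), n_perm = 200, seed = 5)  # monotone map
  expect_equal(a$rp_values, b$rp_values)
  expect_equal(a$rp_p, b$rp_p)
})

test_that("Borda consensus averages ranks with lexicographic ties", {
  expect_equal(borda_consensus(list(c("A", "B", "C")))$order,
               c("A", "B", "C"))
  r <- borda_consensus(list(c("A", "B", "C"), c("B", "A", "C")))
  expect_equal(unname(r$mean_rank[c("A", "B", "C")]), c(1.5, 1.5, 3))
  expect_equal(r$order, c("A", "B", "C"))
  # three cyclic shifts: full tie, fully lexicographic output
  shifts <- list(c("A", "B", "C"), c("B", "C", "A"), c("C", "A", "B"))
  r3 <- borda_consensus(shifts)
  expect_true(all(r3$mean_rank == 2))
  expect_equal(r3$order, c("A", "B", "C"))
  expect_error(borda_consensus(list(c("A", "B"), c("A", "C"))), "gene set")
})

test_that("Borda mean ranks are equivariant under gene relabelling", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:8)
  lists <- replicate(3, sample(genes), simplify = FALSE)
  base <- borda_consensus(lists)$mean_rank
  relabel <- setNames(sprintf("x%02d", sample(8)), genes)
  perm <- borda_consensus(lapply(lists, function(l)
    unname(relabel[l])))$mean_rank
  expect_equal(unname(perm[unname(relabel[names(base)])]), unname(base))
})

test_that("ensemble meta-analysis ranks a dominating gene first", {
  set.seed(7)
  p <- matrix(runif(30, 0.2, 1), 10, 3,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:3)))
  p["g05", ] <- 1e-6
  lfc <- matrix(rnorm(30), 10, 3, dimnames = dimnames(p))
  coll <- tiny_collection(p, logfc = lfc)
  cons <- run_meta_analysis(coll, n_perm = 200, seed = 1)
  expect_equal(cons$order[1], "g05")
  expect_true(all(cons$per_method_rank["g05", ] == 1))
  # mean rank is the arithmetic mean of the three per-method ranks
  expect_equal(unname(cons$mean_rank[coll$genes]),
               unname(rowMeans(cons$per_method_rank)))
})

test_that("constant fold change makes the weighted variant identical", {
  set.seed(8)
  p <- matrix(runif(40, 0.01, 1), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:4)))
  coll <- tiny_collection(p)  # logfc defaults to a constant 1
  a <- run_meta_analysis(coll, n_perm = 200, seed = 2)
  b <- run_meta_analysis(coll, n_perm = 200, seed = 2,
                         include_fold_change = TRUE)
  expect_equal(a$order, b$order)
})

test_that("rank comparison matches pair-counting for Kendall's tau", {
  g <- c("a", "b", "c", "d")
  same <- compare_ranks(g, g)
  expect_equal(same$tau, 1)
  expect_equal(same$r2, 1)
  rev_ <- compare_ranks(g, rev(g))
  expect_equal(rev_$tau, -1)
  expect_equal(rev_$r2, 1)
  # (1,2,3,4) vs (1,2,4,3): 5 concordant, 1 discordant -> tau = 2/3
  swapped <- compare_ranks(g, c("a", "b", "d", "c"))
  expect_equal(swapped$tau, 2 / 3, tolerance = 1e-10)
})

test_that("robustness analysis is exact under duplicate contrasts", {
  set.seed(9)
  p <- matrix(runif(20, 0.01, 1), 10, 2,
              dimnames = list(sprintf("g%02d", 1:10), c("c1", "c2")))
  pp <- cbind(p, p)
  colnames(pp) <- c("c1", "c2", "c3", "c4")
  coll <- tiny_collection(pp, enm = c("keep", "keep", "drop", "drop"))
  out <- subset_robustness(coll, "drop", n_perm = 200, seed = 4)
  expect_length(out, 2)
  expect_equal(out$step0$tau, 1)
  # removing exact duplicates leaves identical per-gene statistics
  expect_equal(out$step1$tau, 1)
  expect_error(subset_robustness(coll, c("drop", "keep")), "empties")
})
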