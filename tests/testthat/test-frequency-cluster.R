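test_that("duration classes follow the in vitro / in vivo boundary rules", {
  cases <- list(
    list(24, "h", "in_vitro", "short"),
    list(25, "h", "in_vitro", "intermediate"),
    list(72, "h", "in_vitro", "intermediate"),
    list(96, "h", "in_vitro", "long"),
    list(3, "d", "in_vivo", "short"),
    list(28, "d", "in_vivo", "intermediate"),
    list(30, "d", "in_vivo", "intermediate"),
    list(31, "d", "in_vivo", "long"),
    list(6, "h", "in_vivo", "short")
  )
  for (cs in cases) {
    expect_equal(assign_duration_class(cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                 info = paste(cs[[1]], cs[[2]], cs[[3]]))
  }
  expect_error(assign_duration_class(24, "fortnights", "in_vitro"), "unit")
  expect_error(assign_duration_class(NA_real_, "h", "in_vitro"), "duration")
})

test_that("frequency scores are exact percentages per group", {
  # 5 long in-vitro contrasts; gene significant (tiny p) in exactly 2
  p <- matrix(0.9, 3, 5, dimnames = list(c("gA", "gB", "gC"), NULL))
  p["gA", 1:2] <- 1e-12
  p["gB", ] <- 1e-12
  coll <- tiny_collection(p, systems = rep("in_vitro", 5),
                          durations = rep("long", 5))
  # restrict to a single duration class by building all classes from it
  coll$meta$duration_class <- rep("long", 5)
  expect_error(frequency_scores(coll, c("gA")), "no contrasts in group")

  coll2 <- tiny_collection(
    cbind(p, p[, 1, drop = FALSE], p[, 1, drop = FALSE]),
    systems = rep("in_vitro", 7),
    durations = c(rep("long", 5), "short", "intermediate"))
  fs <- frequency_scores(coll2, c("gA", "gB", "gC"))$in_vitro
  expect_equal(unname(fs["gA", "long"]), 40)
  expect_equal(unname(fs["gB", "long"]), 100)
  expect_equal(unname(fs["gC", "long"]), 0)
  expect_true(all(fs >= 0 & fs <= 100))
})

test_that("adding a non-significant contrast never raises a score", {
  set.seed(31)
  p <- matrix(runif(30, 1e-6, 1), 6, 5,
              dimnames = list(sprintf("g%02d", 1:6), NULL))
  coll <- tiny_collection(p, systems = rep("in_vitro", 5),
                          durations = rep("long", 5))
  coll_ext <- tiny_collection(cbind(p, rep(0.999, 6)),
                              systems = rep("in_vitro", 6),
                              durations = rep("long", 6))
  # give both a token short/intermediate group so scoring succeeds
  add_classes <- function(cl) {
    m <- cbind(cl$p, 0.99, 0.99)
    tiny_collection(m, systems = rep("in_vitro", ncol(m)),
                    durations = c(rep("long", ncol(cl$p)), "short",
                                  "intermediate"))
  }
  f1 <- frequency_scores(add_classes(coll), rownames(p))$in_vitro
  f2 <- frequency_scores(add_classes(coll_ext), rownames(p))$in_vitro
  expect_true(all(f2[, "long"] <= f1[, "long"] + 1e-9))
})

test_that("Ward clustering splits identical-profile blocks perfectly", {
  prof <- rbind(
    matrix(rep(c(0, 0, 100), each = 10), 10, 3,
           dimnames = list(sprintf("p%02d", 1:10),
                           c("short", "intermediate", "long"))),
    matrix(rep(c(100, 0, 0), each = 10), 10, 3,
           dimnames = list(sprintf("q%02d", 1:10),
                           c("short", "intermediate", "long"))))
  cl <- ward_clusters(prof, 2)
  labs_p <- unique(cl$cluster[sprintf("p%02d", 1:10)])
  labs_q <- unique(cl$cluster[sprintf("q%02d", 1:10)])
  expect_length(labs_p, 1)
  expect_length(labs_q, 1)
  expect_false(labs_p == labs_q)

  singletons <- ward_clusters(prof, nrow(prof))
  expect_equal(length(unique(singletons$cluster)), nrow(prof))
  expect_error(ward_clusters(prof, 0), "n_clusters")
  expect_error(ward_clusters(prof, nrow(prof) + 1), "more clusters")
})

test_that("noisy two-block profiles are recovered", {
  set.seed(32)
  block1 <- matrix(c(5, 5, 80), 20, 3, byrow = TRUE) + rnorm(60, 0, 6)
  block2 <- matrix(c(40, 10, 5), 20, 3, byrow = TRUE) + rnorm(60, 0, 6)
  prof <- pmin(pmax(rbind(block1, block2), 0), 100)
  dimnames(prof) <- list(sprintf("g%02d", 1:40),
                         c("short", "intermediate", "long"))
  cl <- ward_clusters(prof, 2)
  persistent <- select_persistent_cluster(cl, prof, threshold = 40)
  expect_gte(jaccard(persistent, sprintf("g%02d", 1:20)), 0.8)
})

test_that("persistent-cluster selection follows threshold and tie rules", {
  prof <- rbind(
    matrix(c(0, 0, 10), 5, 3, byrow = TRUE,
           dimnames = list(sprintf("a%d", 1:5),
                           c("short", "intermediate", "long"))),
    matrix(c(0, 0, 55), 5, 3, byrow = TRUE,
           dimnames = list(sprintf("b%d", 1:5),
                           c("short", "intermediate", "long"))))
  cl <- ward_clusters(prof, 2)
  expect_setequal(select_persistent_cluster(cl, prof), sprintf("b%d", 1:5))

  low <- prof * 0.5  # all means below 40
  cl2 <- ward_clusters(low, 2)
  expect_warning(res <- select_persistent_cluster(cl2, low), "no cluster")
  expect_length(res, 0)

  # tie on mean long frequency: the larger cluster wins
  prof3 <- rbind(
    matrix(c(0, 0, 60), 6, 3, byrow = TRUE,
           dimnames = list(sprintf("big%d", 1:6),
                           c("short", "intermediate", "long"))),
    matrix(c(90, 0, 60), 2, 3, byrow = TRUE,
           dimnames = list(sprintf("sml%d", 1:2),
                           c("short", "intermediate", "long"))))
  cl3 <- ward_clusters(prof3, 2)
  expect_setequal(select_persistent_cluster(cl3, prof3),
                  sprintf("big%d", 1:6))
})

test_that("overlap counts are exact Venn counts", {
  expect_equal(overlap_counts(c("a", "b", "c"), c("b", "c", "d")),
               c(only_a = 1L, only_b = 1L, shared = 2L))
  expect_equal(unname(overlap_counts(c("a"), c("b"))["shared"]), 0L)
  expect_equal(unname(overlap_counts(c("a", "b"), c("a", "b"))[c(1, 2)]),
               c(0L, 0L))
})
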