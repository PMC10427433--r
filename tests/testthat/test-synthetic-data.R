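test_that("identical config and seed reproduce the collection exactly", {
  cfg <- synth_config(n_genes = 200, n_contrasts = 12,
                      planted_signature = 30, seed = 81)
  a <- generate_de_collection(cfg)
  b <- generate_de_collection(cfg)
  expect_identical(a$collection$p, b$collection$p)
  expect_identical(a$collection$logfc, b$collection$logfc)
  expect_identical(a$truth, b$truth)

  other <- generate_de_collection(synth_config(n_genes = 200,
                                               n_contrasts = 12,
                                               planted_signature = 30,
                                               seed = 82))
  expect_false(identical(a$collection$p, other$collection$p))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_genes = 0), "positive")
  expect_error(synth_config(n_genes = 10, planted_signature = 20), "larger")
  expect_error(synth_config(duration_mix = c(short = 0.5,
                                             intermediate = 0.5,
                                             long = 0.5)), "sum to 1")
})

test_that("null-only collections are BH calibrated", {
  frac <- vapply(1:5, function(s) {
    cfg <- synth_config(n_genes = 500, n_contrasts = 8,
                        planted_signature = 0, seed = 900 + s)
    coll <- generate_de_collection(cfg)$collection
    mean(coll$adj_p < 0.05)
  }, 0)
  expect_lte(mean(frac), 0.05)
  # p-values themselves are uniform
  cfg <- synth_config(n_genes = 400, n_contrasts = 5,
                      planted_signature = 0, seed = 83)
  coll <- generate_de_collection(cfg)$collection
  expect_gt(ks.test(as.vector(coll$p), "punif")$p.value, 0.001)
})

test_that("planted z-scores realize the configured effect size", {
  # persistent boost off isolates the baseline effect
  zbar <- vapply(1:10, function(s) {
    cfg <- synth_config(n_genes = 300, n_contrasts = 24,
                        planted_signature = 150, effect_size_d = 1.0,
                        per_contrast_noise_sd = 0.3, persistent_frac = 0,
                        enm_effect_sd = 0, seed = 840 + s)
    gen <- generate_de_collection(cfg)
    z <- qnorm(gen$collection$p[gen$truth$signature_genes, ] / 2,
               lower.tail = FALSE) *
      sign(gen$collection$logfc[gen$truth$signature_genes, ])
    mean(sweep(z, 1, gen$truth$directions, "*"))
  }, 0)
  se <- sd(zbar) / sqrt(length(zbar))
  expect_lt(abs(mean(zbar) - 1.0), 3 * se + 0.02)
})

test_that("metadata respects the configured composition", {
  cfg <- synth_config(n_genes = 100, n_contrasts = 24,
                      planted_signature = 10, frac_invivo = 0.5, seed = 85)
  meta <- generate_de_collection(cfg)$collection$meta
  expect_equal(sum(meta$system == "in_vivo"), 12)
  expect_equal(as.vector(table(meta$duration_class)[c("short",
                                                      "intermediate",
                                                      "long")]),
               c(8L, 8L, 8L))
})

test_that("promoter generator plants at the binomial rate", {
  word <- "GGGGCGGGG"
  m <- motif_from_word(word, concentration = 1)
  genes <- sprintf("s%03d", 1:300)

  none <- generate_promoters(genes[1:30], m, genes[1:30],
                             insertion_prob = 0, length = 200, seed = 86)
  expect_false(any(grepl(word, none, fixed = TRUE)))
  expect_true(all(nchar(none) == 200))
  # background composition roughly uniform
  tab <- table(strsplit(paste(none, collapse = ""), "")[[1]])
  expect_true(all(abs(tab / sum(tab) - 0.25) < 0.03))

  planted <- generate_promoters(genes, m, genes, insertion_prob = 0.4,
                                length = 200, seed = 87)
  hits <- sum(vapply(planted, function(s)
    grepl(word, s, fixed = TRUE) || grepl(revcomp(word), s, fixed = TRUE),
    TRUE))
  # binomial oracle: 300 * 0.4 = 120, keep 4 sigma of slack
  expect_lt(abs(hits - 120), 4 * sqrt(300 * 0.4 * 0.6) + 1)

  expect_error(generate_promoters(genes[1:10], m, genes[1:10],
                                  insertion_prob = 1, length = 5, seed = 1),
               "wider")
})

test_that("descriptor generator controls linkage and missingness", {
  cfg <- synth_config(n_genes = 150, n_contrasts = 16,
                      planted_signature = 30, n_enm_groups = 8, seed = 88)
  gen <- generate_de_collection(cfg)
  coll <- gen$collection
  enm <- unique(coll$meta$enm_group)
  g1 <- gen$truth$signature_genes[1]

  # noise 0 and a single linked gene: the descriptor is an affine map of
  # that gene's per-ENM fold-change profile
  tab <- generate_descriptor_table(enm, list(d = g1), coll, noise_sd = 0,
                                   seed = 89)
  prof <- sapply(enm, function(e)
    mean(coll$logfc[g1, coll$meta$enm_group == e]))
  expect_equal(abs(cor(tab[, "d"], prof)), 1, tolerance = 1e-10)

  # missingness close to the requested fraction
  tabm <- generate_descriptor_table(enm, rep(list(character()), 8) |>
                                      setNames(sprintf("n%d", 1:8)),
                                    coll, seed = 90, missing_frac = 0.2)
  frac <- mean(is.na(tabm))
  expect_lt(abs(frac - 0.2), 0.12)

  expect_error(generate_descriptor_table(enm, list(d = "not_a_gene"), coll),
               "not")
})

test_that("unlinked descriptor-gene pairs have near-zero mean correlation", {
  cfg <- synth_config(n_genes = 100, n_contrasts = 32,
                      planted_signature = 20, n_enm_groups = 16, seed = 91)
  gen <- generate_de_collection(cfg)
  coll <- gen$collection
  enm <- unique(coll$meta$enm_group)
  rs <- vapply(1:5, function(s) {
    tab <- generate_descriptor_table(enm, list(null = character()), coll,
                                     seed = 91 + s)
    prof <- sapply(enm, function(e)
      rowMeans(coll$logfc[, coll$meta$enm_group == e, drop = FALSE]))
    mean(cor(t(prof), tab[, "null"]))
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})
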