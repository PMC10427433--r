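test_that("liquid-drop relations hit their closed-form landmarks", {
  # TiO2: unit-tracked evaluation of the Wigner-Seitz radius
  ld <- liquid_drop_descriptors(M = 79.866, rho = 4.23, r0 = 10)
  r_w_oracle <- (3 * 79.866 / (4 * pi * 4.23 * 6.02214076e23))^(1 / 3) * 1e7
  expect_equal(ld$r_w, r_w_oracle, tolerance = 1e-12)
  expect_equal(ld$r_w, 0.1956, tolerance = 1e-3)

  # n = 64 makes S exactly 1
  ld64 <- liquid_drop_descriptors(M = 79.866, rho = 4.23,
                                  r0 = r_w_oracle * 4)
  expect_equal(ld64$n, 64, tolerance = 1e-9)
  expect_equal(ld64$S, 1, tolerance = 1e-9)
  # below 64 units the surface ratio exceeds 1 and SV is undefined
  ld_small <- liquid_drop_descriptors(M = 79.866, rho = 4.23,
                                      r0 = r_w_oracle * 3.9)
  expect_gt(ld_small$S, 1)
  expect_true(is.na(ld_small$SV))
  expect_true("SV_undefined_S_ge_1" %in% ld_small$flags)

  # T = 273 K zeroes the interfacial thickness; below it h < 0 is flagged
  expect_equal(liquid_drop_descriptors(79.866, 4.23, 10, T = 273)$h, 0)
  cold <- liquid_drop_descriptors(79.866, 4.23, 10, T = 263)
  expect_lt(cold$h, 0)
  expect_true("negative_h_below_273K" %in% cold$flags)

  expect_error(liquid_drop_descriptors(-1, 4.23, 10))
})

test_that("Wigner-Seitz radius scales as (M/rho)^(1/3)", {
  base <- liquid_drop_descriptors(100, 5, 10)$r_w
  doubled <- liquid_drop_descriptors(200, 10, 10)$r_w
  expect_equal(doubled, base, tolerance = 1e-12)
  m8 <- liquid_drop_descriptors(800, 5, 10)$r_w
  expect_equal(m8, 2 * base, tolerance = 1e-12)
})

test_that("surface-volume ratio is increasing in S below 1", {
  s <- seq(0.05, 0.95, by = 0.05)
  sv <- s / (1 - s)
  expect_true(all(diff(sv) > 0))
})

test_that("coordination numbers match brute-force neighbour counting", {
  radii <- c(Ti = 0.5, O = 0.4)
  lone <- data.frame(species = "Ti", x = 0, y = 0, z = 0)
  expect_equal(coordination_numbers(lone, radii), 0L)

  pair <- data.frame(species = c("Ti", "O"), x = c(0, 0.9 * 1.2 * 0.9),
                     y = 0, z = 0)
  expect_equal(coordination_numbers(pair, radii), c(1L, 1L))

  # simple-cubic 3x3x3 lattice: interior atom has 6 neighbours at the
  # spacing, corner atoms 3
  grid <- expand.grid(x = 0:2, y = 0:2, z = 0:2)
  lattice <- data.frame(species = "Ti", grid)
  rad <- c(Ti = 0.45)  # cutoff 1.2 * 0.9 = 1.08, just above spacing 1
  cn <- coordination_numbers(lattice, rad)
  brute <- vapply(seq_len(27), function(i) {
    d <- sqrt((grid$x - grid$x[i])^2 + (grid$y - grid$y[i])^2 +
                (grid$z - grid$z[i])^2)
    sum(d > 0 & d <= 1.08)
  }, 0)
  expect_equal(cn, as.integer(brute))
  interior <- which(grid$x == 1 & grid$y == 1 & grid$z == 1)
  expect_equal(cn[interior], 6L)

  expect_error(coordination_numbers(
    data.frame(species = "Xx", x = 0, y = 0, z = 0), radii), "unknown")
})

test_that("surface-normal force equals the projection oracle", {
  one <- data.frame(x = 1, y = 0, z = 0, fx = 2, fy = 0, fz = 0)
  expect_equal(surface_normal_force(one), 2)

  tangential <- data.frame(x = 1, y = 0, z = 0, fx = 0, fy = 3, fz = -1)
  expect_equal(surface_normal_force(tangential), 0)

  set.seed(51)
  st <- data.frame(x = rnorm(100), y = rnorm(100), z = rnorm(100),
                   fx = rnorm(100), fy = rnorm(100), fz = rnorm(100))
  v <- surface_normal_force(st)
  oracle <- vapply(seq_len(100), function(i) {
    r <- c(st$x[i], st$y[i], st$z[i])
    f <- c(st$fx[i], st$fy[i], st$fz[i])
    sum(r * f) / sqrt(sum(r^2))
  }, 0)
  expect_equal(v, oracle, tolerance = 1e-12)

  at_centre <- data.frame(x = 0, y = 0, z = 0, fx = 1, fy = 0, fz = 0)
  expect_error(surface_normal_force(at_centre), "centre")
})

test_that("winsorized cube-root correlation follows its contracts", {
  expect_equal(cube_root(-8), -2)
  expect_equal(cube_root(27), 3)

  lfc <- matrix(c(1, 2, 3, 4, 5,
                  2, 1, 5, 3, 4), 2, 5, byrow = TRUE,
                dimnames = list(c("gA", "gB"), sprintf("e%d", 1:5)))
  desc <- matrix(c(1, 8, 27, 64, 125), 5, 1,
                 dimnames = list(sprintf("e%d", 1:5), "cube"))
  # cube root linearizes the descriptor, so gA correlates perfectly
  r <- winsorized_cube_correlation(lfc, desc, winsor_q = c(0, 1))
  expect_equal(unname(r["gA", "cube"]), 1, tolerance = 1e-12)

  # fewer complete pairs than min_pairs -> missing
  desc_na <- desc; desc_na[3:5, 1] <- NA
  r_na <- winsorized_cube_correlation(lfc, desc_na, winsor_q = c(0, 1))
  expect_true(all(is.na(r_na)))

  # zero-variance gene -> missing
  lfc0 <- rbind(lfc, gC = rep(2, 5))
  r0 <- winsorized_cube_correlation(lfc0, desc, winsor_q = c(0, 1))
  expect_true(is.na(r0["gC", "cube"]))

  # winsorized values stay inside the empirical quantiles
  set.seed(52)
  x <- rnorm(200)
  wx <- winsorize(x, c(0.05, 0.95))
  expect_gte(min(wx), quantile(x, 0.05, names = FALSE))
  expect_lte(max(wx), quantile(x, 0.95, names = FALSE))
})

test_that("descriptor set size matches the stated top fraction", {
  set.seed(53)
  genes <- sprintf("g%04d", 1:3670)
  cors <- matrix(runif(3670), ncol = 1,
                 dimnames = list(genes, "d1"))
  res <- descriptor_gsea(cors, genes, top_frac = 0.10, n_perm = 100,
                         seed = 1)
  expect_equal(res$set_size, 367)
})

test_that("linked descriptors are selected and unlinked ones are not", {
  cfg <- synth_config(n_genes = 400, n_contrasts = 48,
                      planted_signature = 80, n_enm_groups = 16, seed = 12)
  gen <- generate_de_collection(cfg)
  coll <- gen$collection
  enm <- unique(coll$meta$enm_group)
  linked <- list(linked = gen$truth$signature_genes[1:40],
                 null_a = character(), null_b = character(),
                 null_c = character())
  tab <- generate_descriptor_table(enm, linked, coll, noise_sd = 0.2,
                                   seed = 13)
  logfc_by_enm <- sapply(enm, function(e)
    rowMeans(coll$logfc[, coll$meta$enm_group == e, drop = FALSE]))
  cors <- winsorized_cube_correlation(logfc_by_enm, tab)
  cons <- run_meta_analysis(coll, n_perm = 200, seed = 14)
  res <- descriptor_gsea(cors, cons, n_perm = 500, seed = 15, alpha = 0.01)
  expect_true(res$selected[res$descriptor == "linked"])
  expect_false(any(res$selected[res$descriptor != "linked"]))
})

test_that("extended XYZ structures round-trip through the reader", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("2", "forces in columns 5-7",
               "Ti 0.0 0.0 0.0 0.1 0.2 0.3",
               "O  1.0 0.5 0.2 -0.1 0.0 0.4"), f)
  st <- read_xyz(f)
  expect_equal(st$species, c("Ti", "O"))
  expect_equal(st$fz, c(0.3, 0.4))
  expect_equal(st$x, c(0, 1))
})
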