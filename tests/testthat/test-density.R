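# Model maps, real-space correlation and quadrant classification.

test_that("model maps peak at atoms and are linear in occupancy", {
  one <- data.frame(chain = "A", resno = 1, resname = "DG", atom = "P",
                    element = "P", x = 5.13, y = 5.07, z = 4.96,
                    o = 1, b = 20, alt = "", hetero = FALSE)
  m <- model_map(one, grid_spacing = 0.5, padding = 4)
  peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  node <- m$origin + (peak - 1) * m$spacing
  # the maximum sits on the grid node nearest the atom
  expect_true(all(abs(node - c(5.13, 5.07, 4.96)) <= m$spacing / 2 + 1e-9))
  half <- one; half$o <- 0.5
  m2 <- model_map(half, grid_spacing = 0.5, padding = 4)
  expect_equal(m2$values * 2, m$values, tolerance = 1e-12)
  expect_error(model_map(one, grid_spacing = 0), "positive")
})

test_that("integrated density is proportional to electron count", {
  two <- data.frame(chain = "A", resno = c(1, 2), resname = "DG",
                    atom = c("P", "C1'"), element = c("P", "C"),
                    x = c(0, 10), y = 0, z = 0, o = 1, b = 15,
                    alt = "", hetero = FALSE)
  m <- model_map(two, grid_spacing = 0.4, padding = 5)
  sphere_sum <- function(ctr, r) {
    ax <- lapply(1:3, function(k) m$origin[k] + (seq_len(m$dim[k]) - 1) * m$spacing[k])
    w <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
    keep <- (w$x - ctr[1])^2 + (w$y - ctr[2])^2 + (w$z - ctr[3])^2 <= r^2
    sum(m$values[keep])
  }
  sP <- sphere_sum(c(0, 0, 0), 2)
  sC <- sphere_sum(c(10, 0, 0), 2)
  expect_equal(sP / sC, 15 / 6, tolerance = 0.05)
})

test_that("self-map RSCC is 1, negated map is -1, rescaling is neutral", {
  s <- fx_small_duplexA()
  m <- fx_small_map()
  steps <- dinucleotide_steps(s)
  st <- steps[steps$chain == "A" & steps$resno1 == 3, ]
  r <- rscc_step(m, s, st, map_calc = m)
  expect_equal(r$rscc, 1, tolerance = 1e-9)
  expect_gt(r$n_atoms, 10)
  neg <- m; neg$values <- -m$values
  expect_equal(rscc_step(neg, s, st, map_calc = m)$rscc, -1, tolerance = 1e-9)
  # Pearson is invariant under affine rescaling of the observed map
  aff <- m; aff$values <- 3.7 * m$values + 11
  expect_equal(rscc_step(aff, s, st, map_calc = m)$rscc, 1, tolerance = 1e-9)
  # a step outside the map errors
  far <- s$atoms
  far$x <- far$x + 500
  s2 <- ntc_structure(far, s$cell, s$spacegroup)
  expect_error(rscc_step(m, s2, st), "outside the map|no usable")
})

test_that("increasing map noise degrades the median step RSCC monotonically", {
  s <- fx_small_duplexA()
  calc <- fx_small_map()
  steps <- dinucleotide_steps(s)
  rms <- sqrt(mean(calc$values^2))
  med <- vapply(c(0.3, 1, 3) * rms, function(ns) {
    obs <- synthetic_map(s, grid_spacing = 0.8, noise_sigma = ns, seed = 7)
    median(vapply(seq_len(nrow(steps)), function(i)
      rscc_step(obs, s, steps[i, ], map_calc = calc)$rscc, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  # noise comparable to the map RMS still leaves clear signal in the masks
  expect_gt(med[2], 0.4)
  expect_lt(med[2], 1)
})

test_that("quadrant classification matches the published reading", {
  expect_equal(classify_quadrant(0.9, 0.5), "good")
  expect_equal(classify_quadrant(0.7, 0.5), "over_refined")
  expect_equal(classify_quadrant(0.9, 1.2), "unique")
  expect_equal(classify_quadrant(0.7, 1.2), "poor")
  # boundaries inclusive toward the favourable side
  expect_equal(classify_quadrant(0.8, 1.0), "good")
  expect_equal(classify_quadrant(0.8, 1.5), "unique")
  expect_equal(classify_quadrant(0.5, 1.0), "over_refined")
  # total function over a grid; vectorized
  g <- expand.grid(rscc = seq(-1, 1, by = 0.25), rmsd = seq(0, 3, by = 0.5))
  q <- classify_quadrant(g$rscc, g$rmsd)
  expect_true(all(q %in% c("good", "over_refined", "unique", "poor")))
})

test_that("scattergram table partitions steps and fractions sum to 1", {
  s <- fx_small_duplexA()
  m <- fx_small_map()
  tab <- scattergram_table(s, m, fx_lib())
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$quadrant == "good"))   # ideal fixture, self map
  expect_true(all(tab$assigned))
  fr <- attr(tab, "fractions")
  for (f in fr) expect_equal(sum(f), 1, tolerance = 1e-9)
  # truncated library: hide the A classes so steps go NANT but keep rmsd
  lib_b <- ntc_library(list(fx_lib()$classes$BB00), version = "trunc",
                       check = FALSE)
  tab2 <- scattergram_table(s, m, lib_b)
  expect_true(all(!tab2$assigned))          # constructed truth: all NANT
  # quadrants remain consistent with the classification rule
  expect_equal(tab2$quadrant, classify_quadrant(tab2$rscc, tab2$rmsd))
})

test_that("CCP4 maps round-trip", {
  m <- fx_small_map()
  tf <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(m, tf)
  m2 <- read_ccp4(tf)
  expect_equal(m2$dim, m$dim)
  expect_equal(m2$spacing, m$spacing, tolerance = 1e-5)
  expect_equal(m2$origin, m$origin, tolerance = 1e-4)
  expect_lt(max(abs(m2$values - m$values)) / max(abs(m$values)), 1e-6)
  expect_error(read_ccp4(tf2 <- withr::local_tempfile(fileext = ".ccp4",
                                                      lines = "not a map")),
               "")
})

test_that("synthetic maps are seed-stable and reduce to the model map", {
  s <- fx_small_duplexA()
  m0 <- synthetic_map(s, grid_spacing = 0.8, noise_sigma = 0)
  mm <- model_map(s, grid_spacing = 0.8)
  expect_equal(m0$values, mm$values, tolerance = 1e-12)
  m1 <- synthetic_map(s, grid_spacing = 0.8, noise_sigma = 0.5, seed = 13)
  m2 <- synthetic_map(s, grid_spacing = 0.8, noise_sigma = 0.5, seed = 13)
  expect_identical(m1$values, m2$values)
  m3 <- synthetic_map(s, grid_spacing = 0.8, noise_sigma = 0.5, seed = 14)
  expect_false(identical(m1$values, m3$values))
})
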