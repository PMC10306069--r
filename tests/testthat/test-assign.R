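# Conformer library handling, superposition, assignment and confal scoring.

test_that("the mini library loads, validates and round-trips through JSON", {
  lib <- fx_lib()
  expect_gte(length(lib$classes), 4)
  expect_true(all(c("AA00", "BB00") %in% names(lib$classes)))
  tf <- withr::local_tempfile(fileext = ".json")
  write_library(lib, tf)
  lib2 <- load_library(tf)
  expect_equal(names(lib2$classes), names(lib$classes))
  expect_equal(lib2$classes$AA00$targets, lib$classes$AA00$targets,
               tolerance = 1e-9)
  expect_equal(rownames(lib2$classes$AA00$ref_coords),
               rownames(lib$classes$AA00$ref_coords))
  expect_lt(max(abs(lib2$classes$AA00$ref_coords -
                      lib$classes$AA00$ref_coords)), 1e-9)
  # duplicate labels rejected
  expect_error(ntc_library(list(lib$classes$AA00, lib$classes$AA00)),
               "duplicate")
  # non-positive sigma rejected
  bad <- lib$classes$AA00
  expect_error(ntc_class(bad$label, bad$targets,
                         replace(bad$sigmas, 1, -1), bad$ref_coords),
               "positive")
  # coordinate/torsion mismatch rejected at load
  bad2 <- lib$classes$AA00
  bad2$targets[["delta1"]] <- bad2$targets[["delta1"]] + 10
  expect_error(ntc_library(list(bad2), check = TRUE), "disagree")
})

test_that("Kabsch superposition is exact on isometries and matches a grid oracle", {
  set.seed(7)
  ref <- matrix(rnorm(15, sd = 3), 5, 3)
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  rig <- random_rigid()
  mov <- t(rig$R %*% t(ref)) + matrix(rig$t, 5, 3, byrow = TRUE)
  expect_lt(superpose(ref, mov)$rmsd, 1e-9)
  fit <- superpose(ref, mov)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$fitted - ref)), 1e-9)
  # displaced-point toy set against the brute-force rotation grid
  mov2 <- ref
  mov2[2, ] <- mov2[2, ] + c(1, 0, 0)
  k <- superpose(ref, mov2)$rmsd
  g <- grid_superpose_rmsd(ref, mov2)
  expect_equal(k, g, tolerance = 1e-3)
  expect_error(superpose(ref[1:2, ], mov2[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate|collinear")
})

test_that("a step at a class's reference geometry assigns exactly", {
  lib <- fx_lib()
  for (lab in c("AA00", "BB00")) {
    coords <- lib$classes[[lab]]$ref_coords
    a <- assign_step(coords, lib = lib)
    expect_equal(a$ntc, lab)
    expect_lt(a$torsion_distance, 1e-6)
    expect_lt(a$cartesian_rmsd, 1e-6)
    expect_equal(a$confal, 100L)
    expect_true(a$restraint_eligible)
  }
})

test_that("assignment is invariant under rigid-body motion of the step", {
  lib <- fx_lib()
  set.seed(5)
  coords <- noisy_step(lib$classes$AA00, sigma_scale = 0.4)
  a0 <- assign_step(coords, lib = lib)
  for (k in 1:3) {
    rig <- random_rigid()
    a1 <- assign_step(apply_rigid_coords(coords, rig), lib = lib)
    expect_equal(a1$ntc, a0$ntc)
    expect_equal(a1$torsion_distance, a0$torsion_distance, tolerance = 1e-6)
    expect_equal(a1$cartesian_rmsd, a0$cartesian_rmsd, tolerance = 1e-6)
  }
})

test_that("moderate torsion noise is recovered; far decoys go NANT", {
  lib <- fx_lib()
  set.seed(42)
  # +-10 degree uniform noise on AA00, rebuilt in Cartesian space
  hits <- 0L
  for (i in 1:60) {
    tv <- lib$classes$AA00$targets
    ang <- ntckit:::TORSION_ANGLE_PARAMS
    tv[ang] <- wrap180(tv[ang] + stats::runif(length(ang), -10, 10))
    a <- assign_step(step_from_torsions(tv), lib = lib)
    hits <- hits + (a$ntc == "AA00")
  }
  expect_gte(hits / 60, 0.95)
  # backbone torsions 90 degrees off every class: gated to NANT
  for (lab in names(lib$classes)) {
    tv <- lib$classes[[lab]]$targets
    bb <- c("delta1", "epsilon1", "zeta1", "alpha2", "beta2", "gamma2",
            "delta2", "chi1", "chi2")
    tv[bb] <- wrap180(tv[bb] + 90)
    a <- assign_step(step_from_torsions(tv), lib = lib)
    expect_equal(a$ntc, "NANT")
    # nearest class still reported and rmsd still computed for NANT steps
    expect_true(is.finite(a$cartesian_rmsd))
  }
})

test_that("confal follows its closed form and is monotone", {
  lib <- fx_lib()
  cl <- lib$classes$AA00
  tv0 <- cl$targets
  expect_equal(confal_score(tv0, cl), 100L)
  # every parameter off by exactly one sigma: 100 * exp(-1/2) -> 61
  tv1 <- tv0
  tv1[ntckit:::TORSION_ANGLE_PARAMS] <-
    wrap180(tv1[ntckit:::TORSION_ANGLE_PARAMS] +
              cl$sigmas[ntckit:::TORSION_ANGLE_PARAMS])
  tv1[ntckit:::TORSION_DIST_PARAMS] <-
    tv1[ntckit:::TORSION_DIST_PARAMS] + cl$sigmas[ntckit:::TORSION_DIST_PARAMS]
  expect_equal(confal_score(tv1, cl), round(100 * exp(-0.5)))
  # increasing any single deviation never increases the score
  for (p in c("delta1", "nu2_2", "d_nn")) {
    scores <- vapply(c(0, 0.5, 1, 2, 4), function(k) {
      tv <- tv0
      tv[p] <- if (p %in% ntckit:::TORSION_DIST_PARAMS)
        tv[p] + k * cl$sigmas[p] else wrap180(tv[p] + k * cl$sigmas[p])
      confal_score(tv, cl)
    }, numeric(1))
    expect_true(all(diff(scores) <= 0))
  }
})

test_that("structure confal is the arithmetic mean of step scores", {
  a <- fx_assignA()
  expect_equal(structure_confal(a), mean(a$confal))
  expect_equal(structure_confal(data.frame(confal = c(40, 80))), 60)
  expect_error(structure_confal(data.frame(confal = numeric())), "no assignments")
})

test_that("idealize_step is a fixed point and reproduces class torsions", {
  lib <- fx_lib()
  cl <- lib$classes$AA00
  # already at the target: coordinates unchanged
  out0 <- idealize_step(cl$ref_coords, class = cl)
  expect_lt(max(abs(out0 - cl$ref_coords)), 1e-6)
  # arbitrary B-form step idealized to AA00
  set.seed(3)
  start <- noisy_step(lib$classes$BB00, sigma_scale = 0.3)
  out <- idealize_step(start, class = cl)
  tv <- step_torsions(out)
  expect_lt(max(abs(circ_diff(tv[ntckit:::TORSION_ANGLE_PARAMS],
                              cl$targets[ntckit:::TORSION_ANGLE_PARAMS]))), 1)
  # idealize then assign: the target class at rmsd ~ 0
  a <- assign_step(out, lib = lib)
  expect_equal(a$ntc, "AA00")
  expect_lt(a$cartesian_rmsd, 1e-6)
})

test_that("incomplete steps yield flagged NANT assignments", {
  s <- fx_small_duplexA()
  steps <- dinucleotide_steps(s)
  a <- s$atoms
  drop <- which(a$chain == "A" & a$resno == 2 & a$atom == "O4'")
  s2 <- ntc_structure(a[-drop, ], s$cell, s$spacegroup)
  asn <- assign_step(s2, steps[steps$chain == "A" & steps$resno1 == 2, ],
                     lib = fx_lib())
  expect_equal(asn$ntc, "NANT")
  expect_true(asn$incomplete)
  expect_true("O4'|1" %in% asn$missing)
})
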