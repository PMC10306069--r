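# Cross-strand distances, crystal contacts, base-pair parameters, ions.

make_two_atom_structure <- function(p1, p2, cell = c(50, 50, 50, 90, 90, 90),
                                    sg = "P 1") {
  atoms <- data.frame(
    chain = c("A", "B"), resno = c(1, 1), resname = "DG",
    atom = "C1'", element = "C",
    x = c(p1[1], p2[1]), y = c(p1[2], p2[2]), z = c(p1[3], p2[3]),
    o = 1, b = 20, alt = "", hetero = FALSE, stringsAsFactors = FALSE)
  ntc_structure(atoms, cell = cell, spacegroup = sg)
}

test_that("cross-strand C1' distances measure what was constructed", {
  s <- make_two_atom_structure(c(10, 10, 10), c(20, 10, 10))
  expect_equal(cross_strand_c1_distance(s, 1, 1), 10)
  # symmetric in the residue swap
  d1 <- cross_strand_c1_distance(fx_duplexA(), 9, 10)
  d2 <- cross_strand_c1_distance(fx_duplexA(), 10, 9)
  expect_equal(d1, d2, tolerance = 1e-9)
  # ideal B-form WC pair: canonical C1'-C1' separation
  sB <- fx_duplexB()
  dB <- cross_strand_c1_distance(sB, 9, 10)
  expect_gte(dB, 10.2); expect_lte(dB, 10.8)
  expect_error(cross_strand_c1_distance(s, 3, 1), "missing C1'")
})

test_that("symmetry-mate C1' distances pick the closest image", {
  # one strand in a P 21 cell; the mate comes from the screw operator
  s <- fx_small_duplexA()
  a <- s$atoms[s$atoms$chain == "A", ]
  s1 <- ntc_structure(a, cell = c(30, 30, 40, 90, 90, 90), spacegroup = "P 21")
  d_sym <- cross_strand_c1_distance(s1, 2, 3, mate = "symmetry")
  # oracle: explicit minimum over the expanded images
  i2 <- which(a$resno == 3 & a$atom == "C1'")
  p1 <- ntckit:::atom_xyz(s1, "A", 2, "C1'")
  best <- Inf
  for (k in 1:2) for (tx in -1:1) for (ty in -1:1) for (tz in -1:1) {
    if (k == 1 && tx == 0 && ty == 0 && tz == 0) next
    img <- apply_symmetry(s1, k, c(tx, ty, tz))
    best <- min(best, sqrt(sum((c(img$x[i2], img$y[i2], img$z[i2]) - p1)^2)))
  }
  expect_equal(d_sym, best, tolerance = 1e-9)
})

test_that("crystal contacts count unique symmetry neighbours", {
  # single atom in a huge P1 cell: nothing within 4 A of any image
  one <- make_two_atom_structure(c(25, 25, 25), c(25, 25, 25))[["atoms"]][1, ]
  s_one <- ntc_structure(one, cell = c(60, 60, 60, 90, 90, 90), spacegroup = "P 1")
  expect_equal(nrow(crystal_contacts(s_one)), 0)
  # an atom 3.0 A inside the cell edge touches its +x lattice image... place
  # two atoms 3.0 A apart across the lattice translation
  a <- data.frame(chain = "A", resno = 1, resname = "DG", atom = "C1'",
                  element = "C", x = 1.0, y = 10, z = 10, o = 1, b = 20,
                  alt = "", hetero = FALSE)
  b <- data.frame(chain = "A", resno = 2, resname = "DG", atom = "N9",
                  element = "N", x = 18.0, y = 10, z = 10, o = 1, b = 20,
                  alt = "", hetero = FALSE)
  s2 <- ntc_structure(rbind(a, b), cell = c(20, 20, 20, 90, 90, 90),
                      spacegroup = "P 1")
  ct <- crystal_contacts(s2, cutoff = 4.0)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 3.0, tolerance = 1e-9)
  # cutoffs below the separation exclude the pair; zero cutoff is empty
  expect_equal(nrow(crystal_contacts(s2, cutoff = 2.9)), 0)
  expect_equal(nrow(crystal_contacts(s2, cutoff = 0)), 0)
  counts <- vapply(c(2, 3.5, 4.5, 6), function(co)
    nrow(crystal_contacts(s2, cutoff = co)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("contacts in a packed P 43 21 2 fixture are canonical and symmetric", {
  s <- fx_small_duplexA()
  # shrink the cell until symmetry images touch
  s43 <- ntc_structure(s$atoms, cell = c(26, 26, 34, 90, 90, 90),
                       spacegroup = "P 43 21 2")
  ct <- crystal_contacts(s43, cutoff = 4.0)
  expect_gt(nrow(ct), 0)
  expect_true(all(ct$distance < 4.0))
  # uniqueness: no duplicated canonical pair
  key <- apply(ct, 1, function(r) {
    ids <- sort(c(paste(r["chain1"], trimws(r["resno1"]), r["atom1"]),
                  paste(r["chain2"], trimws(r["resno2"]), r["atom2"])))
    paste(ids[1], ids[2], sprintf("%.3f", as.numeric(r["distance"])))
  })
  expect_equal(anyDuplicated(key), 0)
})

test_that("base-pair parameters vanish for ideal pairs and track perturbations", {
  s <- fx_duplexA()
  bp <- base_pair_parameters(s, "A", 9, "B", 10)
  expect_lt(max(abs(bp[c("shear", "stretch", "stagger")])), 0.2)
  expect_lt(max(abs(bp[c("buckle", "propeller", "opening")])), 3)
  # translating base 2 by +1 A along the mid-frame x axis adds 1 to shear
  f1 <- ntckit:::base_frame(s, "A", 9)
  f2 <- ntckit:::base_frame(s, "B", 10)
  Rm <- f1$R %*% ntckit:::half_rotation(t(f1$R) %*% (f2$R %*% diag(c(1, -1, -1))))
  xm <- Rm[, 1]
  a <- s$atoms
  sel <- a$chain == "B" & a$resno == 10 &
    a$atom %in% rownames(ntckit:::base_template("DT"))
  a$x[sel] <- a$x[sel] + xm[1]; a$y[sel] <- a$y[sel] + xm[2]
  a$z[sel] <- a$z[sel] + xm[3]
  bp2 <- base_pair_parameters(ntc_structure(a, s$cell, s$spacegroup),
                              "A", 9, "B", 10)
  expect_equal(bp2[["shear"]] - bp[["shear"]], 1, tolerance = 0.05)
  # strand swap flips the signs of shear and buckle only
  a <- s$atoms
  sel <- a$chain == "B" & a$resno == 10
  f2o <- ntckit:::base_frame(s, "B", 10)$origin
  R <- ntckit:::rotation_about_axis(c(0.3, 0.5, 0.8), 8)
  xyz <- t(R %*% (t(as.matrix(a[sel, c("x", "y", "z")])) - f2o) + f2o) +
    matrix(c(0.4, -0.3, 0.2), sum(sel), 3, byrow = TRUE)
  a$x[sel] <- xyz[, 1]; a$y[sel] <- xyz[, 2]; a$z[sel] <- xyz[, 3]
  sp <- ntc_structure(a, s$cell, s$spacegroup)
  fwd <- base_pair_parameters(sp, "A", 9, "B", 10)
  swp <- base_pair_parameters(sp, "B", 10, "A", 9)
  expect_equal(swp[["shear"]], -fwd[["shear"]], tolerance = 1e-6)
  expect_equal(swp[["buckle"]], -fwd[["buckle"]], tolerance = 1e-6)
  expect_equal(swp[["stretch"]], fwd[["stretch"]], tolerance = 1e-6)
  expect_equal(swp[["stagger"]], fwd[["stagger"]], tolerance = 1e-6)
  expect_equal(swp[["propeller"]], fwd[["propeller"]], tolerance = 1e-6)
  expect_equal(swp[["opening"]], fwd[["opening"]], tolerance = 1e-6)
})

test_that("base-pair parameters are invariant under whole-pair rigid motion", {
  s <- fx_duplexA()
  bp <- base_pair_parameters(s, "A", 8, "B", 11)
  set.seed(21)
  rig <- random_rigid()
  s2 <- apply_rigid_structure(s, rig)
  bp2 <- base_pair_parameters(s2, "A", 8, "B", 11)
  expect_equal(bp2, bp, tolerance = 1e-6)
  # missing ring atoms are named (residue A9 is an adenine, so N7 exists)
  a <- s$atoms
  a <- a[!(a$chain == "A" & a$resno == 9 & a$atom == "N7"), ]
  expect_error(base_pair_parameters(ntc_structure(a, s$cell, s$spacegroup),
                                    "A", 9, "B", 10), "N7")
})

test_that("ion coordination lists DNA atoms within the cutoff", {
  s <- fx_small_duplexA()
  expect_equal(nrow(ion_coordination(s, "SR")), 0)
  # place a cation 2.6 A from a guanine O6
  o6 <- ntckit:::atom_xyz(s, "A", 1, "O6")
  ion <- data.frame(chain = "S", resno = 101, resname = "SR", atom = "SR",
                    element = "SR", x = o6[1] + 2.6, y = o6[2], z = o6[3],
                    o = 1, b = 30, alt = "", hetero = TRUE)
  s2 <- ntc_structure(rbind(s$atoms, ion), s$cell, s$spacegroup)
  ic <- ion_coordination(s2, "SR", cutoff = 3.2)
  expect_gte(nrow(ic), 1)
  expect_equal(ic$atom[1], "O6")
  expect_equal(ic$distance[1], 2.6, tolerance = 1e-9)
  expect_equal(nrow(ion_coordination(s2, "SR", cutoff = 2.0)), 0)
})
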