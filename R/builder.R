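# Internal-coordinate construction of nucleotide units.  The deoxyribose is
# built from its pseudorotation state, the base is attached at the canonical
# glycosidic anchor with a per-form chi, and the 5' tail (O5', P) is solved
# so that O3'(i)-P(i+1) connectivity under the helical step transform is a
# proper covalent bond.  These are documented generator constants, not
# measurements: they provide a self-consistent ground truth for the test
# fixtures and the built-in conformer library.

# Endocyclic torsions nu0..nu4 for phase P (deg) and amplitude tau_m (deg),
# Altona-Sundaralingam: nu_j = tau_m * cos(P + 144 (j - 2)).
pucker_nus <- function(P, tau_m) {
  j <- 0:4
  tau_m * cos((P + 144 * (j - 2)) / DEG)
}

# Standard bond lengths (A) and angles (deg) of the sugar-phosphate unit.
.bb <- list(
  b_o4c1 = 1.420, b_c1c2 = 1.528, b_c2c3 = 1.525, b_c3c4 = 1.528,
  b_c4o4 = 1.446, b_c4c5 = 1.511, b_c3o3 = 1.423, b_c1n = 1.461,
  b_c5o5 = 1.440, b_o5p = 1.600, b_o3p = 1.607, b_pop = 1.485,
  a_c3c4o4 = 105.6, a_c4o4c1 = 109.7,
  a_c4c5o5 = 110.2, a_c5o5p = 120.9, a_o5po3 = 104.0, a_c3o3p = 119.7
)

# Build one deoxyribose ring (O4', C1', C2', C3', C4') with the requested
# pseudorotation state, plus C5', O3' and the glycosidic direction point N.
# Ring closure: NeRF chain with the three free placement angles optimized
# against the closure bond, closure angles and the remaining two nu targets.
build_sugar <- function(P, tau_m) {
  build_sugar_nus(pucker_nus(P, tau_m))
}

# Same, from explicit nu0..nu4 targets.  Arbitrary nu combinations need not
# be realizable by a closed five-ring, so the targets are first projected
# onto the nearest consistent pseudorotation state (least squares in the
# (tau_m cos P, tau_m sin P) plane, closed form), which keeps the closure
# optimization well-conditioned for any input.
build_sugar_nus <- function(nus) {
  ph <- (144 * ((0:4) - 2)) / DEG
  a <- sum(nus * cos(ph)) / sum(cos(ph)^2)
  b <- -sum(nus * sin(ph)) / sum(sin(ph)^2)
  P <- atan2(b, a) * DEG
  tau_m <- sqrt(a^2 + b^2)
  nus <- pucker_nus(P %% 360, tau_m)
  ring <- function(ang) {
    o4 <- c(0, 0, 0)
    c1 <- c(.bb$b_o4c1, 0, 0)
    # place C2' in the xy-plane at angle ang[1] from O4'
    th <- ang[1L] / DEG
    c2 <- c1 + .bb$b_c1c2 * c(-cos(th), sin(th), 0)
    c3 <- place_atom(o4, c1, c2, .bb$b_c2c3, ang[2L], nus[2L])
    c4 <- place_atom(c1, c2, c3, .bb$b_c3c4, ang[3L], nus[3L])
    rbind("O4'" = o4, "C1'" = c1, "C2'" = c2, "C3'" = c3, "C4'" = c4)
  }
  obj <- function(ang) {
    r <- ring(ang)
    e_bond <- vnorm(r["C4'", ] - r["O4'", ]) - .bb$b_c4o4
    e_nu3 <- circ_diff(dihedral(r["C2'", ], r["C3'", ], r["C4'", ], r["O4'", ]), nus[4L])
    e_nu4 <- circ_diff(dihedral(r["C3'", ], r["C4'", ], r["O4'", ], r["C1'", ]), nus[5L])
    e_a1 <- angle3(r["C3'", ], r["C4'", ], r["O4'", ]) - .bb$a_c3c4o4
    e_a2 <- angle3(r["C4'", ], r["O4'", ], r["C1'", ]) - .bb$a_c4o4c1
    400 * e_bond^2 + 0.02 * (e_nu3^2 + e_nu4^2) + 0.01 * (e_a1^2 + e_a2^2)
  }
  fit <- stats::optim(c(106, 102, 103), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  r <- ring(fit$par)

  # beta face carries the base and C5'; alpha face carries O3'.  The face is
  # identified from the ring chirality so that delta falls in the physical
  # C3'-endo / C2'-endo regimes of a D-deoxyribose.
  dir_c5 <- tetrahedral_directions(r["C4'", ], r["O4'", ], r["C3'", ])
  dir_o3 <- tetrahedral_directions(r["C3'", ], r["C2'", ], r["C4'", ])
  dir_n  <- tetrahedral_directions(r["C1'", ], r["O4'", ], r["C2'", ])
  nrm <- unitv(cross3(r["C1'", ] - r["O4'", ], r["C4'", ] - r["O4'", ]))
  pick <- function(dirs, sign) {
    s <- c(sum(dirs[1L, ] * nrm), sum(dirs[2L, ] * nrm))
    dirs[if (sign > 0) which.max(s) else which.min(s), ]
  }
  c5 <- r["C4'", ] + .bb$b_c4c5 * pick(dir_c5, -1)
  n  <- r["C1'", ] + .bb$b_c1n  * pick(dir_n, -1)
  o3 <- r["C3'", ] + .bb$b_c3o3 * pick(dir_o3, +1)
  rbind(r, "C5'" = c5, "O3'" = o3, "N" = n)
}

# Rigid-place a sugar so that C1' sits on the canonical anchor, the
# glycosidic bond points at the N anchor, and the chi torsion (measured to
# the in-plane base reference direction) equals `chi`.  `chi_ref` is the
# position of the chi reference atom (C4 purine / C2 pyrimidine) in the
# target frame.
place_sugar <- function(sugar, chi, c1_anchor, n_anchor, chi_ref) {
  u_loc <- unitv(sugar["N", ] - sugar["C1'", ])
  u_tgt <- unitv(n_anchor - c1_anchor)
  ax <- cross3(u_loc, u_tgt)
  s <- vnorm(ax)
  cosang <- max(-1, min(1, sum(u_loc * u_tgt)))
  R <- if (s < 1e-12 && cosang > 0) diag(3L)
       else if (s < 1e-12) rotation_about_axis(unitv(cross3(u_loc, u_loc + c(0.1, 0.2, 0.3))), 180)
       else rotation_about_axis(ax / s, acos(cosang) * DEG)
  m <- t(R %*% t(sugar - matrix(sugar["C1'", ], nrow(sugar), 3L, byrow = TRUE)))
  m <- m + matrix(c1_anchor, nrow(m), 3L, byrow = TRUE)
  rownames(m) <- rownames(sugar)
  # rotate about the glycosidic axis until chi matches
  chi_now <- dihedral(m["O4'", ], m["C1'", ], n_anchor, chi_ref)
  Rchi <- rotation_about_axis(u_tgt, -circ_diff(chi, chi_now))
  m2 <- t(Rchi %*% t(m - matrix(c1_anchor, nrow(m), 3L, byrow = TRUE)))
  m2 <- m2 + matrix(c1_anchor, nrow(m2), 3L, byrow = TRUE)
  rownames(m2) <- rownames(sugar)
  chi_chk <- dihedral(m2["O4'", ], m2["C1'", ], n_anchor, chi_ref)
  if (abs(circ_diff(chi_chk, chi)) > 1e-6) {
    Rchi <- rotation_about_axis(u_tgt, +circ_diff(chi, chi_now))
    m2 <- t(Rchi %*% t(m - matrix(c1_anchor, nrow(m), 3L, byrow = TRUE)))
    m2 <- m2 + matrix(c1_anchor, nrow(m2), 3L, byrow = TRUE)
    rownames(m2) <- rownames(sugar)
  }
  m2
}

# Helical step transform in pair-frame coordinates: residue i -> i + 1.
step_transform <- function(twist, rise, xdisp) {
  coff <- c(xdisp, 0, 0)
  R <- rot_z(twist)
  list(
    fwd = function(p) drop(R %*% (p + coff)) + c(0, 0, rise) - coff,
    inv = function(p) drop(t(R) %*% (p + coff - c(0, 0, rise))) - coff
  )
}

# Solve O5' and P of the repeating unit so that the helical polymer is
# covalently continuous, then add the phosphate OP1/OP2 oxygens.
solve_backbone <- function(sugar, tr, targets) {
  c3 <- sugar["C3'", ]; c4 <- sugar["C4'", ]; c5 <- sugar["C5'", ]
  o3 <- sugar["O3'", ]
  init_o5 <- place_atom(c3, c4, c5, .bb$b_c5o5, .bb$a_c4c5o5, targets["gamma"])
  init_p <- place_atom(c4, c5, init_o5, .bb$b_o5p, .bb$a_c5o5p, targets["beta"])
  obj <- function(par) {
    o5 <- par[1:3]; p <- par[4:6]
    p_next <- tr$fwd(p)          # P of residue i+1
    o3_prev <- tr$inv(o3)        # O3' of residue i-1
    e <- 0
    e <- e + 400 * (vnorm(o5 - c5) - .bb$b_c5o5)^2
    e <- e + 400 * (vnorm(p - o5) - .bb$b_o5p)^2
    e <- e + 400 * (vnorm(p_next - o3) - .bb$b_o3p)^2
    e <- e + 0.02 * (angle3(c4, c5, o5) - .bb$a_c4c5o5)^2
    e <- e + 0.02 * (angle3(c5, o5, p) - .bb$a_c5o5p)^2
    e <- e + 0.02 * (angle3(o3_prev, p, o5) - .bb$a_o5po3)^2
    e <- e + 0.02 * (angle3(c3, o3, p_next) - .bb$a_c3o3p)^2
    tors <- c(
      alpha = dihedral(o3_prev, p, o5, c5),
      beta  = dihedral(p, o5, c5, c4),
      gamma = dihedral(o5, c5, c4, c3),
      eps   = dihedral(c4, c3, o3, p_next),
      zeta  = dihedral(c3, o3, p_next, tr$fwd(o5))
    )
    e + 5e-4 * sum(circ_diff(tors, targets[names(tors)])^2)
  }
  fit <- stats::optim(c(init_o5, init_p), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  o5 <- fit$par[1:3]; p <- fit$par[4:6]
  opd <- tetrahedral_directions(p, o5, tr$inv(o3))
  out <- rbind("O5'" = o5, "P" = p,
               "OP1" = p + .bb$b_pop * opd[1L, ],
               "OP2" = p + .bb$b_pop * opd[2L, ])
  attr(out, "objective") <- fit$value
  out
}

# Documented fiber-style generator constants per duplex form.
form_params <- function(form) {
  switch(form,
    A = list(twist = 32.7, rise = 2.56, xdisp = -2.5,
             P = 18, tau_m = 38, chi = -157,
             targets = c(alpha = -62, beta = 173, gamma = 52,
                         eps = -152, zeta = -74)),
    B = list(twist = 36.0, rise = 3.38, xdisp = -0.7,
             P = 162, tau_m = 36, chi = -102,
             targets = c(alpha = -63, beta = 171, gamma = 54,
                         eps = -171, zeta = -103)),
    stop("form must be 'A' or 'B'"))
}

.builder_cache <- new.env(parent = emptyenv())

# Full repeating unit for one form: sugar + backbone in pair-frame
# coordinates (base-independent thanks to the canonical glycosidic anchor),
# plus the chi reference position used during placement.
residue_unit <- function(form) {
  key <- paste0("unit_", form)
  if (!is.null(.builder_cache[[key]])) return(.builder_cache[[key]])
  fp <- form_params(form)
  sugar <- build_sugar(fp$P, fp$tau_m)
  # chi reference direction: in-plane point on the WC-edge side of the
  # glycosidic bond; any planar base gives the same torsion, so the DG
  # template's C4 serves for placement.
  tmpl <- base_template("DG")
  placed <- place_sugar(sugar, fp$chi, .c1_anchor, .n_anchor, tmpl["C4", ])
  tr <- step_transform(fp$twist, fp$rise, fp$xdisp)
  bb <- solve_backbone(placed, tr, fp$targets)
  unit <- list(sugar = placed[setdiff(rownames(placed), "N"), , drop = FALSE],
               backbone = bb, params = fp, tr = tr)
  .builder_cache[[key]] <- unit
  unit
}
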