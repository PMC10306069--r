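# Shared lazily-built fixtures; everything is generated in code so the test
# tree ships no data files.  Builders cache in this environment to keep the
# suite fast.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_lib <- function() fx_cache("lib", function() load_library("mini"))

fx_duplexA <- function() fx_cache("duplexA", function()
  build_duplex(fixture_spec()))

fx_duplexB <- function() fx_cache("duplexB", function()
  build_duplex(fixture_spec(form = "B")))

fx_small_duplexA <- function() fx_cache("smallA", function()
  build_duplex(fixture_spec(sequence = "GGTACC")))

fx_assignA <- function() fx_cache("assignA", function()
  assign_structure(fx_duplexA(), fx_lib()))

# A small map of the 6-mer duplex, reused across density tests.
fx_small_map <- function() fx_cache("smallmap", function()
  model_map(fx_small_duplexA(), grid_spacing = 0.8))

# random rigid-body transform (fixed-seed callers)
random_rigid <- function() {
  ax <- stats::rnorm(3)
  R <- ntckit:::rotation_about_axis(ax / sqrt(sum(ax^2)), stats::runif(1, 0, 360))
  t <- stats::rnorm(3, sd = 10)
  list(R = R, t = t)
}

apply_rigid_structure <- function(s, rig) {
  a <- s$atoms
  xyz <- t(rig$R %*% t(as.matrix(a[, c("x", "y", "z")]))) +
    matrix(rig$t, nrow(a), 3, byrow = TRUE)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  ntc_structure(a, s$cell, s$spacegroup)
}

apply_rigid_coords <- function(m, rig) {
  out <- t(rig$R %*% t(m)) + matrix(rig$t, nrow(m), 3, byrow = TRUE)
  rownames(out) <- rownames(m)
  attr(out, "missing") <- attr(m, "missing")
  out
}

# Brute-force rotation-grid superposition oracle: scan a coarse grid of
# Euler z-y-z rotations over pre-centred point sets, then polish the best
# coarse candidates with a derivative-free local search.  Independent of the
# SVD path it checks.
grid_superpose_rmsd <- function(ref, mov, step = 12, top = 10) {
  ref_c <- sweep(ref, 2, colMeans(ref))
  mov_c <- sweep(mov, 2, colMeans(mov))
  rmsd_at <- function(ang) {
    R <- ntckit:::rot_z(ang[1]) %*%
      ntckit:::rotation_about_axis(c(0, 1, 0), ang[2]) %*% ntckit:::rot_z(ang[3])
    sqrt(mean(rowSums((mov_c %*% t(R) - ref_c)^2)))
  }
  grid <- as.matrix(expand.grid(a1 = seq(0, 360 - step, by = step),
                                a2 = seq(0, 180, by = step),
                                a3 = seq(0, 360 - step, by = step)))
  vals <- apply(grid, 1, rmsd_at)
  cand <- grid[order(vals)[seq_len(top)], , drop = FALSE]
  best <- min(vals)
  for (i in seq_len(nrow(cand))) {
    fit <- stats::optim(cand[i, ], rmsd_at, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# Gaussian-noised copy of a class torsion vector, rebuilt in Cartesian space.
noisy_step <- function(class, sigma_scale = 0.5) {
  tv <- class$targets
  ang <- ntckit:::TORSION_ANGLE_PARAMS
  tv[ang] <- wrap180(tv[ang] + stats::rnorm(length(ang),
                                            0, class$sigmas[ang] * sigma_scale))
  step_from_torsions(tv)
}
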