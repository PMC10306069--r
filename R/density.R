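# Electron-density model maps, per-dinucleotide real-space correlation, and
# the RSCC vs r.m.s.d. quadrant classification.
#
# Model density is a sum of spherical atomic Gaussians: variance
# sigma^2 = B/(8 pi^2) + blur^2 (the blur emulating finite resolution),
# amplitude occ * Z / (2 pi sigma^2)^(3/2) so each atom integrates to its
# electron count.  Observed maps are consumed as grids (CCP4/MRC mode 2 or
# in-memory objects); map-coefficient synthesis from structure factors is
# out of scope, so validation examples run against model-generated and
# noise-perturbed synthetic maps.

#' Construct a density map object
#'
#' @param values 3-dimensional numeric array (x fastest axis).
#' @param spacing grid spacing per axis, Angstroms (length 1 or 3).
#' @param origin Cartesian position of grid node (1,1,1), Angstroms.
#' @return object of class `density_map`.
#' @export
density_map <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < 2L)) stop("map needs at least 2 nodes per axis")
  if (!all(is.finite(values))) stop("non-finite map values")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  structure(list(dim = dim(values), spacing = spacing,
                 origin = as.numeric(origin), values = values),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map %d x %d x %d, spacing %.2f A, origin (%.1f, %.1f, %.1f)\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing[1],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$dim, b$dim) && all(abs(a$spacing - b$spacing) < 1e-9) &&
    all(abs(a$origin - b$origin) < 1e-6)
}

#' Gaussian model density map
#'
#' @param s an `ntc_structure`, or an atoms data.frame with x, y, z,
#'   element, o, b columns.
#' @param grid_spacing grid spacing, Angstroms.
#' @param resolution_blur additional Gaussian width added to the B-factor
#'   term, Angstroms.
#' @param padding margin around the atom bounding box, Angstroms.
#' @param grid optional `density_map` whose grid should be reused (values
#'   ignored); overrides spacing/padding.
#' @return a `density_map`.
#' @export
model_map <- function(s, grid_spacing = 0.5, resolution_blur = 0.9,
                      padding = 3, grid = NULL) {
  atoms <- if (is_ntc_structure(s)) s$atoms else s
  if (!nrow(atoms)) stop("no atoms")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (is.null(grid)) {
    lo <- c(min(atoms$x), min(atoms$y), min(atoms$z)) - padding
    hi <- c(max(atoms$x), max(atoms$y), max(atoms$z)) + padding
    n <- pmax(2L, as.integer(ceiling((hi - lo) / grid_spacing)) + 1L)
    map <- density_map(array(0, n), grid_spacing, lo)
  } else {
    map <- density_map(array(0, grid$dim), grid$spacing, grid$origin)
  }
  ax <- lapply(1:3, function(k) map$origin[k] + (seq_len(map$dim[k]) - 1L) * map$spacing[k])
  vals <- map$values
  z_e <- electron_count(atoms$element)
  for (i in seq_len(nrow(atoms))) {
    s2 <- atoms$b[i] / (8 * pi^2) + resolution_blur^2
    amp <- atoms$o[i] * z_e[i] / (2 * pi * s2)^1.5
    cut <- 4 * sqrt(s2)
    p <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    rng <- lapply(1:3, function(k) which(abs(ax[[k]] - p[k]) <= cut))
    if (any(vapply(rng, length, integer(1L)) == 0L)) next
    dx2 <- (ax[[1L]][rng[[1L]]] - p[1L])^2
    dy2 <- (ax[[2L]][rng[[2L]]] - p[2L])^2
    dz2 <- (ax[[3L]][rng[[3L]]] - p[3L])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    vals[rng[[1L]], rng[[2L]], rng[[3L]]] <-
      vals[rng[[1L]], rng[[2L]], rng[[3L]]] + amp * exp(-r2 / (2 * s2))
  }
  map$values <- vals
  map
}

#' Synthetic observed map: model density plus seeded grid noise
#'
#' @param s an `ntc_structure`.
#' @param grid_spacing grid spacing, Angstroms.
#' @param noise_sigma Gaussian noise standard deviation (map units).
#' @param seed integer seed.
#' @param ... further arguments for [model_map()].
#' @return a `density_map`.
#' @export
synthetic_map <- function(s, grid_spacing = 0.5, noise_sigma = 0, seed = 1L, ...) {
  m <- model_map(s, grid_spacing = grid_spacing, ...)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    m$values <- m$values + array(stats::rnorm(prod(m$dim), 0, noise_sigma), m$dim)
  }
  m
}

# Linear indices of grid points within `radius` of position p.
.mask_indices <- function(map, p, radius) {
  ax <- lapply(1:3, function(k) map$origin[k] + (seq_len(map$dim[k]) - 1L) * map$spacing[k])
  rng <- lapply(1:3, function(k) which(abs(ax[[k]] - p[k]) <= radius))
  if (any(vapply(rng, length, integer(1L)) == 0L)) return(integer())
  dx2 <- (ax[[1L]][rng[[1L]]] - p[1L])^2
  dy2 <- (ax[[2L]][rng[[2L]]] - p[2L])^2
  dz2 <- (ax[[3L]][rng[[3L]]] - p[3L])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  keep <- which(r2 <= radius^2, arr.ind = TRUE)
  if (!nrow(keep)) return(integer())
  i <- rng[[1L]][keep[, 1L]]; j <- rng[[2L]][keep[, 2L]]; k <- rng[[3L]][keep[, 3L]]
  i + (j - 1L) * map$dim[1L] + (k - 1L) * map$dim[1L] * map$dim[2L]
}

#' Real-space correlation of one dinucleotide step
#'
#' Per atom, the Pearson correlation between observed and calculated density
#' over grid points within `mask_radius`; the step RSCC is the unweighted
#' mean over atoms with at least `min_points` mask points (atoms with fewer
#' are excluded and counted).
#'
#' @param map_obs observed `density_map`.
#' @param s the `ntc_structure`.
#' @param step step descriptor row from [dinucleotide_steps()].
#' @param map_calc calculated `density_map` on the same grid (defaults to a
#'   model map of the whole structure on the observed grid).
#' @param mask_radius per-atom mask radius, Angstroms.
#' @param min_points minimum mask points for an atom to contribute.
#' @return list: step_label, rscc, n_atoms (contributing), n_excluded.
#' @export
rscc_step <- function(map_obs, s, step, map_calc = NULL, mask_radius = 2.0,
                      min_points = 8L) {
  if (is.null(map_calc))
    map_calc <- model_map(s, grid = map_obs)
  if (!same_grid(map_obs, map_calc))
    stop("observed and calculated maps are on different grids")
  a <- s$atoms
  idx <- which(a$chain == step$chain & a$resno %in% c(step$resno1, step$resno2) &
                 !a$hetero)
  if (!length(idx)) stop("step atoms not found: ", step$label)
  cors <- numeric(); n_excl <- 0L
  for (i in idx) {
    p <- c(a$x[i], a$y[i], a$z[i])
    m <- .mask_indices(map_obs, p, mask_radius)
    if (length(m) < min_points) { n_excl <- n_excl + 1L; next }
    cc <- safe_cor(map_obs$values[m], map_calc$values[m])
    if (is.na(cc)) { n_excl <- n_excl + 1L; next }
    cors <- c(cors, cc)
  }
  if (!length(cors))
    stop("step entirely outside the map (or no usable atom masks): ", step$label)
  list(step_label = step$label, rscc = mean(cors),
       n_atoms = length(cors), n_excluded = n_excl)
}

#' Quadrant classification on the RSCC - r.m.s.d. plane
#'
#' Vertical cut at RSCC = 0.8, horizontal cut at r.m.s.d. = 1.0 A:
#' `good` (known geometry, good fit), `over_refined` (known geometry, poor
#' fit), `unique` (unknown geometry, good fit), `poor` (neither).
#' Boundaries are inclusive toward the favourable side.
#'
#' @param rscc real-space correlation in `[-1, 1]`.
#' @param rmsd Cartesian r.m.s.d. to the nearest conformer class, Angstroms.
#' @param rscc_cut,rmsd_cut the quadrant boundaries.
#' @return one of "good", "over_refined", "unique", "poor" (vectorized).
#' @export
classify_quadrant <- function(rscc, rmsd, rscc_cut = 0.8, rmsd_cut = 1.0) {
  stopifnot(all(rscc >= -1 & rscc <= 1), all(rmsd >= 0))
  ifelse(rmsd <= rmsd_cut,
         ifelse(rscc >= rscc_cut, "good", "over_refined"),
         ifelse(rscc >= rscc_cut, "unique", "poor"))
}

#' RSCC - r.m.s.d. scattergram table
#'
#' One record per dinucleotide step: conformer assignment, Cartesian
#' r.m.s.d. to the nearest class, step RSCC against the observed map, the
#' quadrant label, and whether the step is assigned (non-NANT).  Quadrant
#' fractions per partition (assigned / unassigned) are attached as
#' `attr(, "fractions")`.
#'
#' @param s an `ntc_structure`.
#' @param map_obs observed `density_map`.
#' @param lib an [ntc_library()].
#' @param map_calc optional calculated map on the observed grid.
#' @param ... assignment parameters passed to [assign_structure()].
#' @return data.frame (step_label, ntc, rmsd, rscc, quadrant, assigned).
#' @export
scattergram_table <- function(s, map_obs, lib, map_calc = NULL, ...) {
  asn <- assign_structure(s, lib, ...)
  steps <- attr(asn, "steps")
  if (is.null(map_calc)) map_calc <- model_map(s, grid = map_obs)
  rsccs <- vapply(seq_len(nrow(steps)), function(i)
    rscc_step(map_obs, s, steps[i, ], map_calc = map_calc)$rscc, numeric(1L))
  df <- data.frame(
    step_label = asn$step_label, ntc = asn$ntc,
    rmsd = asn$cartesian_rmsd, rscc = rsccs,
    quadrant = classify_quadrant(rsccs, asn$cartesian_rmsd),
    assigned = asn$ntc != "NANT", stringsAsFactors = FALSE)
  frac <- lapply(split(df$quadrant, df$assigned), function(q) {
    tab <- table(factor(q, levels = c("good", "over_refined", "unique", "poor")))
    as.numeric(tab) / length(q)
  })
  attr(df, "fractions") <- frac
  df
}

# ---- CCP4/MRC map i/o (mode 2, orthogonal cells) -------------------------

#' Write a density map as CCP4/MRC (mode 2)
#'
#' @param map a `density_map`.
#' @param path output file.
#' @export
write_ccp4 <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- map$dim
  cell <- c(n * map$spacing, 90, 90, 90)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(n)                      # NX NY NZ
  wi(2L)                     # MODE 2 = float32
  wi(c(0L, 0L, 0L))          # NXSTART..
  wi(n)                      # MX MY MZ
  wf(cell)                   # CELLA, CELLB
  wi(c(1L, 2L, 3L))          # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(1L, 0L))              # ISPG, NSYMBT
  wi(rep(0L, 25L))           # EXTRA (words 26-50 start); includes EXTTYP slot
  wf(map$origin)             # ORIGIN (MRC2014, words 50-52)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(map$values)))
  wi(0L)                     # NLABL
  writeBin(raw(800L), con)   # labels
  wf(as.numeric(map$values))
  invisible(path)
}

#' Read a CCP4/MRC density map (mode 2)
#'
#' @param path file path.
#' @return a `density_map`.
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4L, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4L, endian = "little")
  n <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("unsupported MRC mode: ", mode)
  ri(3L)                     # NXSTART
  m <- ri(3L)
  cell <- rf(6L)
  axes <- ri(3L)
  if (!identical(axes, c(1L, 2L, 3L))) stop("unsupported MRC axis order")
  rf(3L); ri(2L)             # stats, ISPG/NSYMBT
  ri(25L)
  origin <- rf(3L)
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "MAP ")) stop("not a CCP4/MRC map file: ", path)
  readBin(con, "raw", 4L); rf(1L); ri(1L)
  readBin(con, "raw", 800L)
  vals <- rf(prod(n))
  density_map(array(vals, n), spacing = cell[1:3] / m, origin = origin)
}
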