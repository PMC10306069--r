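# Assignment of dinucleotide steps to conformer classes.
#
# Class membership is decided in torsion space: the nearest class under a
# circular-Euclidean metric over the 22 parameters, with pseudo-distances
# mapped onto the angular scale by K degrees per Angstrom.  A step is NANT
# ("not assigned") when the nearest class is farther than `t_assign` or any
# single angular deviation exceeds `single_gate`.  Restraint eligibility is
# decided separately, in Cartesian space: the r.m.s.d. to the nearest
# class's reference coordinates after least-squares superposition must be
# within 0.5 A (boundary inclusive).

#' Torsion-space distance between a step and a class
#'
#' @param tv named torsion vector of the step.
#' @param targets named torsion vector of the class.
#' @param K pseudo-distance scaling, degrees per Angstrom.
#' @param weights optional named per-parameter weights (default 1).
#' @return list with `distance` (degrees) and `max_angle_dev` (degrees).
#' @export
torsion_distance <- function(tv, targets, K = 20, weights = NULL) {
  w <- stats::setNames(rep(1, length(TORSION_PARAMS)), TORSION_PARAMS)
  if (!is.null(weights)) w[names(weights)] <- weights
  da <- circ_diff(tv[TORSION_ANGLE_PARAMS], targets[TORSION_ANGLE_PARAMS])
  dd <- (tv[TORSION_DIST_PARAMS] - targets[TORSION_DIST_PARAMS]) * K
  list(distance = sqrt(sum(w[TORSION_ANGLE_PARAMS] * da^2) +
                         sum(w[TORSION_DIST_PARAMS] * dd^2)),
       max_angle_dev = max(abs(da)))
}

#' Confal-style agreement score
#'
#' Per-parameter score s_k = exp(-d_k^2 / (2 sigma_k^2)) with circular
#' differences for angles; the step score is 100 times the geometric mean
#' over the 22 parameters, rounded to an integer.  Monotone non-increasing
#' in every |d_k|.
#'
#' @param tv step torsion vector.
#' @param class an [ntc_class()] (typically the nearest class).
#' @return integer in 0..100.
#' @export
confal_score <- function(tv, class) {
  da <- circ_diff(tv[TORSION_ANGLE_PARAMS], class$targets[TORSION_ANGLE_PARAMS])
  dd <- tv[TORSION_DIST_PARAMS] - class$targets[TORSION_DIST_PARAMS]
  d <- c(da, dd)
  sig <- class$sigmas[TORSION_PARAMS]
  log_s <- -d^2 / (2 * sig^2)
  as.integer(round(100 * exp(mean(log_s))))
}

# Cartesian r.m.s.d. of a step against a class's reference coordinates over
# their common step atoms.
step_class_rmsd <- function(coords, class) {
  common <- intersect(rownames(class$ref_coords), rownames(coords))
  if (length(common) < 3L) stop("too few common step atoms for superposition")
  superpose(class$ref_coords[common, , drop = FALSE],
            coords[common, , drop = FALSE])$rmsd
}

#' Assign one dinucleotide step
#'
#' @param s an `ntc_structure`, or a step-atom coordinate matrix.
#' @param step step descriptor row from [dinucleotide_steps()] (ignored when
#'   `s` is already a coordinate matrix).
#' @param lib an [ntc_library()].
#' @param t_assign torsion-distance threshold for assignment, degrees.
#' @param single_gate maximum tolerated single-angle deviation, degrees.
#' @param K pseudo-distance scaling, degrees per Angstrom.
#' @param rmsd_eligible Cartesian r.m.s.d. eligibility gate, Angstroms.
#' @return object of class `ntc_assignment`: step_label, ntc (class label or
#'   "NANT"), torsion_distance, cartesian_rmsd, confal, restraint_eligible,
#'   nearest (nearest class label regardless of gating).
#' @export
assign_step <- function(s, step = NULL, lib, t_assign = 100, single_gate = 72,
                        K = 20, rmsd_eligible = 0.5) {
  label <- if (is_ntc_structure(s)) step$label else
    attr(s, "label") %||% "step"
  coords <- if (is_ntc_structure(s)) step_atom_coords(s, step) else s
  miss <- attr(coords, "missing")
  if (length(miss)) {
    return(structure(list(step_label = label, ntc = "NANT",
                          torsion_distance = NA_real_,
                          cartesian_rmsd = NA_real_, confal = NA_integer_,
                          restraint_eligible = FALSE, nearest = NA_character_,
                          incomplete = TRUE, missing = miss),
                     class = "ntc_assignment"))
  }
  tv <- step_torsions(coords)
  dists <- lapply(lib$classes, function(cl) torsion_distance(tv, cl$targets, K = K))
  dvals <- vapply(dists, `[[`, numeric(1L), "distance")
  nearest <- names(which.min(dvals))
  nd <- dists[[nearest]]
  cl <- lib$classes[[nearest]]
  ntc <- if (nd$distance <= t_assign && nd$max_angle_dev <= single_gate)
    nearest else "NANT"
  rmsd <- step_class_rmsd(coords, cl)
  structure(list(step_label = label, ntc = ntc,
                 torsion_distance = unname(nd$distance),
                 cartesian_rmsd = rmsd,
                 confal = confal_score(tv, cl),
                 restraint_eligible = ntc != "NANT" && rmsd <= rmsd_eligible,
                 nearest = nearest, incomplete = FALSE,
                 missing = character()),
            class = "ntc_assignment")
}

#' @export
print.ntc_assignment <- function(x, ...) {
  cat(sprintf("%s  %s  dist %.1f deg  rmsd %.3f A  confal %d  %s\n",
              x$step_label, x$ntc,
              x$torsion_distance %||% NA, x$cartesian_rmsd %||% NA,
              x$confal %||% NA,
              if (isTRUE(x$restraint_eligible)) "eligible" else "ineligible"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign every step of a structure
#'
#' @inheritParams assign_step
#' @param s an `ntc_structure`.
#' @return data.frame with one row per step (step_label, ntc,
#'   torsion_distance, cartesian_rmsd, confal, eligible, nearest); the full
#'   assignment objects are attached as `attr(, "assignments")`.
#' @export
assign_structure <- function(s, lib, t_assign = 100, single_gate = 72,
                             K = 20, rmsd_eligible = 0.5) {
  steps <- dinucleotide_steps(s)
  asn <- lapply(seq_len(nrow(steps)), function(i)
    assign_step(s, steps[i, ], lib, t_assign = t_assign,
                single_gate = single_gate, K = K,
                rmsd_eligible = rmsd_eligible))
  df <- data.frame(
    step_label = vapply(asn, `[[`, character(1L), "step_label"),
    ntc = vapply(asn, `[[`, character(1L), "ntc"),
    torsion_distance = vapply(asn, function(a) a$torsion_distance %||% NA_real_, numeric(1L)),
    cartesian_rmsd = vapply(asn, function(a) a$cartesian_rmsd %||% NA_real_, numeric(1L)),
    confal = vapply(asn, function(a) as.integer(a$confal %||% NA_integer_), integer(1L)),
    eligible = vapply(asn, `[[`, logical(1L), "restraint_eligible"),
    nearest = vapply(asn, function(a) a$nearest %||% NA_character_, character(1L)),
    stringsAsFactors = FALSE)
  attr(df, "assignments") <- asn
  attr(df, "steps") <- steps
  df
}

#' Mean confal score of a structure
#'
#' @param assignments result of [assign_structure()] (or any data.frame with
#'   a `confal` column).
#' @return arithmetic mean of the per-step confal scores (NA steps dropped).
#' @export
structure_confal <- function(assignments) {
  v <- assignments$confal
  if (!length(v)) stop("no assignments")
  mean(v, na.rm = TRUE)
}

#' Idealized replacement coordinates for a step
#'
#' Superposes the target class's reference coordinates onto the step's
#' current step atoms (least squares over common atoms) and returns the
#' transformed reference coordinates: a step whose geometry is exactly the
#' class geometry, placed in the model's frame.
#'
#' @param s an `ntc_structure` or step-atom coordinate matrix.
#' @param step step descriptor (when `s` is a structure).
#' @param class target [ntc_class()].
#' @return coordinate matrix (step-atom rows) of the idealized step.
#' @export
idealize_step <- function(s, step = NULL, class) {
  coords <- if (is_ntc_structure(s)) step_atom_coords(s, step) else s
  common <- intersect(rownames(class$ref_coords), rownames(coords))
  if (length(common) < 3L) stop("too few common step atoms")
  fit <- superpose(coords[common, , drop = FALSE],
                   class$ref_coords[common, , drop = FALSE])
  out <- sweep(class$ref_coords %*% t(fit$rotation), 2L, fit$translation, `+`)
  rownames(out) <- rownames(class$ref_coords)
  attr(out, "missing") <- character()
  out
}
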