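# Reference conformer (NtC) classes and libraries.
#
# A class stores the 22 torsion/pseudo-bond targets, their per-parameter
# spreads (sigmas), and reference Cartesian coordinates of the step-atom
# subset.  The built-in "mini" library is derived from the package's ideal
# fiber-style duplex generator (A-form, B-form and two hybrid bridge
# classes); it is NOT the curated golden set behind the published NtC
# classes, but a drop-in compatible stand-in, and a user-supplied library in
# the same JSON schema replaces it transparently.

#' Construct a reference conformer class
#'
#' @param label 4-character class label (e.g. "AA00").
#' @param targets named numeric vector of parameter targets; must contain
#'   all 22 metric parameters.
#' @param sigmas named numeric vector of per-parameter spreads (degrees for
#'   angles, Angstroms for distances), all positive.
#' @param ref_coords numeric matrix of reference step-atom coordinates with
#'   step-atom row names.
#' @return an object of class `ntc_class`.
#' @export
ntc_class <- function(label, targets, sigmas, ref_coords) {
  if (nchar(label) != 4L) stop("class label must have 4 characters: ", label)
  miss <- setdiff(TORSION_PARAMS, names(targets))
  if (length(miss)) stop("targets missing parameters: ", paste(miss, collapse = ", "))
  miss <- setdiff(TORSION_PARAMS, names(sigmas))
  if (length(miss)) stop("sigmas missing parameters: ", paste(miss, collapse = ", "))
  if (any(sigmas[TORSION_PARAMS] <= 0)) stop("sigmas must be positive")
  if (is.null(rownames(ref_coords)) || ncol(ref_coords) != 3L)
    stop("ref_coords must be a 3-column matrix with step-atom row names")
  structure(list(label = label, targets = targets, sigmas = sigmas,
                 ref_coords = ref_coords),
            class = "ntc_class")
}

#' Construct a conformer library
#'
#' @param classes list of [ntc_class()] objects with unique labels.
#' @param version free-form version string recorded in restraint headers.
#' @param check verify that each class's reference coordinates reproduce its
#'   torsion targets to 1 degree (self-consistency).
#' @return an object of class `ntc_library`.
#' @export
ntc_library <- function(classes, version = "custom", check = TRUE) {
  if (!length(classes)) stop("library must contain at least one class")
  labels <- vapply(classes, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    stop("duplicate class label: ", labels[duplicated(labels)][1L])
  names(classes) <- labels
  lib <- structure(list(classes = classes, version = version),
                   class = "ntc_library")
  if (check) validate_library(lib)
  lib
}

#' @export
print.ntc_library <- function(x, ...) {
  cat("ntc_library", x$version, "with", length(x$classes), "classes:",
      paste(names(x$classes), collapse = ", "), "\n")
  invisible(x)
}

# Self-consistency: torsions recomputed from each class's reference
# coordinates must reproduce the stored targets.
validate_library <- function(lib, tol = 1) {
  for (cl in lib$classes) {
    tv <- step_torsions(cl$ref_coords)
    ang <- TORSION_ANGLE_PARAMS
    dev_a <- abs(circ_diff(tv[ang], cl$targets[ang]))
    dev_d <- abs(tv[TORSION_DIST_PARAMS] - cl$targets[TORSION_DIST_PARAMS])
    if (max(dev_a) > tol || max(dev_d) > 0.05)
      stop(sprintf(
        "class %s: reference coordinates disagree with torsion targets (%s off by %.2f)",
        cl$label, names(which.max(c(dev_a, dev_d))), max(dev_a)))
  }
  invisible(lib)
}

#' Load a conformer library
#'
#' @param source `"mini"` for the built-in generator-derived library, or the
#'   path of a library JSON file in the documented schema.
#' @return an [ntc_library()].
#' @export
load_library <- function(source = "mini") {
  if (identical(source, "mini")) return(mini_library())
  if (!file.exists(source)) stop("library file not found: ", source)
  j <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (is.null(j$classes) || !length(j$classes))
    stop("library file has no classes: ", source)
  classes <- lapply(j$classes, function(cj) {
    coords <- do.call(rbind, lapply(cj$ref_coords, unlist))
    rownames(coords) <- unlist(cj$ref_atoms)
    ntc_class(cj$label, unlist(cj$targets), unlist(cj$sigmas), coords)
  })
  ntc_library(classes, version = if (!is.null(j$version)) j$version else "file")
}

#' Write a conformer library to JSON
#'
#' @param lib an [ntc_library()].
#' @param path output file path.
#' @export
write_library <- function(lib, path) {
  j <- list(
    version = lib$version,
    classes = lapply(unname(lib$classes), function(cl) {
      list(label = cl$label,
           targets = as.list(cl$targets),
           sigmas = as.list(cl$sigmas),
           ref_atoms = rownames(cl$ref_coords),
           ref_coords = lapply(seq_len(nrow(cl$ref_coords)),
                               function(i) unname(cl$ref_coords[i, ])))
    }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.library_cache <- new.env(parent = emptyenv())

# Built-in mini library; constructed once per session from the duplex
# generator (see build_mini_library) and cached.
mini_library <- function() {
  if (is.null(.library_cache$mini))
    .library_cache$mini <- build_mini_library()
  .library_cache$mini
}
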