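# Crystal-geometry measurements: cross-strand C1'-C1' distances,
# symmetry-expanded crystal contacts, intra-base-pair parameters, and
# cation coordination distances.

#' Cross-strand C1'-C1' distance
#'
#' Distance between the C1' atoms of two residues on paired strands -- for
#' example between nucleotide 9 and its symmetry-related base-paired
#' nucleotide 10 in a duplex with one strand per asymmetric unit.
#'
#' @param s an `ntc_structure`.
#' @param seq_a,seq_b author residue numbers.
#' @param mate `"second_chain"`: residue `seq_a` on the first chain against
#'   `seq_b` on the second chain; `"symmetry"`: both residues on the first
#'   chain, `seq_b` taken from the symmetry image (over all operators and
#'   neighbouring lattice translations) minimizing the distance.
#' @param chains optional length-2 character giving the chains to use.
#' @return distance in Angstroms.
#' @export
cross_strand_c1_distance <- function(s, seq_a, seq_b,
                                     mate = c("second_chain", "symmetry"),
                                     chains = NULL) {
  mate <- match.arg(mate)
  chs <- if (!is.null(chains)) chains else unique(s$atoms$chain[!s$atoms$hetero])
  p1 <- atom_xyz(s, chs[1L], seq_a, "C1'")
  if (is.null(p1)) stop("missing C1' for residue ", seq_a, " chain ", chs[1L])
  if (mate == "second_chain") {
    if (length(chs) < 2L) stop("structure has no second chain")
    p2 <- atom_xyz(s, chs[2L], seq_b, "C1'")
    if (is.null(p2)) stop("missing C1' for residue ", seq_b, " chain ", chs[2L])
    return(vnorm(p1 - p2))
  }
  # symmetry mate: minimize over operators x translations
  a <- s$atoms
  i2 <- which(a$chain == chs[1L] & a$resno == seq_b & a$atom == "C1'")
  if (!length(i2)) stop("missing C1' for residue ", seq_b, " chain ", chs[1L])
  ops <- sg_operators(s$spacegroup)
  best <- Inf
  tr <- expand.grid(tx = -1:1, ty = -1:1, tz = -1:1)
  for (k in seq_along(ops)) {
    for (j in seq_len(nrow(tr))) {
      if (k == 1L && all(tr[j, ] == 0)) next  # skip the identity copy
      img <- apply_symmetry(s, k, as.integer(tr[j, ]))
      p2 <- c(img$x[i2[1L]], img$y[i2[1L]], img$z[i2[1L]])
      best <- min(best, vnorm(p1 - p2))
    }
  }
  best
}

#' Symmetry-expanded DNA-DNA crystal contacts
#'
#' All unique atom pairs with the first atom in the asymmetric unit and the
#' second in a non-identity symmetry/lattice image, closer than `cutoff`
#' (strict).  A pair is counted once: images are canonicalized by the
#' (operator, translation) tag and the lexicographically smaller atom id,
#' identifying an operator with its inverse image.
#'
#' @param s an `ntc_structure` with cell and space group.
#' @param cutoff contact distance cutoff, Angstroms (strict `<`).
#' @param dna_only restrict both partners to DNA atoms.
#' @return data.frame: chain1, resno1, atom1, chain2, resno2, atom2,
#'   op_index, tx, ty, tz, distance.
#' @export
crystal_contacts <- function(s, cutoff = 4.0, dna_only = TRUE) {
  if (is.null(s$cell) || is.na(s$spacegroup))
    stop("symmetry unavailable: structure has no cell or space group")
  if (cutoff <= 0)
    return(data.frame(chain1 = character(), resno1 = integer(),
                      atom1 = character(), chain2 = character(),
                      resno2 = integer(), atom2 = character(),
                      op_index = integer(), tx = integer(), ty = integer(),
                      tz = integer(), distance = numeric(),
                      stringsAsFactors = FALSE))
  a <- s$atoms
  keep <- if (dna_only) which(!a$hetero) else seq_len(nrow(a))
  asu <- as.matrix(a[keep, c("x", "y", "z")])
  ids <- paste(a$chain[keep], a$resno[keep], a$atom[keep], sep = ":")
  ops <- sg_operators(s$spacegroup)
  tr <- expand.grid(tx = -1:1, ty = -1:1, tz = -1:1)
  seen <- character()
  out <- list()
  for (k in seq_along(ops)) {
    for (j in seq_len(nrow(tr))) {
      tv <- as.integer(tr[j, ])
      if (k == 1L && all(tv == 0L)) next
      img <- apply_symmetry(s, k, tv)
      im <- as.matrix(img[keep, c("x", "y", "z")])
      # bounding-box prefilter
      if (min(im[, 1L]) > max(asu[, 1L]) + cutoff ||
          max(im[, 1L]) < min(asu[, 1L]) - cutoff ||
          min(im[, 2L]) > max(asu[, 2L]) + cutoff ||
          max(im[, 2L]) < min(asu[, 2L]) - cutoff ||
          min(im[, 3L]) > max(asu[, 3L]) + cutoff ||
          max(im[, 3L]) < min(asu[, 3L]) - cutoff) next
      for (ii in seq_len(nrow(asu))) {
        d2 <- (im[, 1L] - asu[ii, 1L])^2 + (im[, 2L] - asu[ii, 2L])^2 +
          (im[, 3L] - asu[ii, 3L])^2
        hits <- which(d2 < cutoff^2)
        for (h in hits) {
          # canonical tag: unordered atom-id pair (operator identified with
          # its inverse image by using only the id pair + distance key)
          dkey <- sprintf("%.4f", sqrt(d2[h]))
          pair <- sort(c(ids[ii], ids[h]))
          tag <- paste(pair[1L], pair[2L], dkey, sep = "|")
          if (tag %in% seen) next
          seen <- c(seen, tag)
          f1 <- strsplit(ids[ii], ":", fixed = TRUE)[[1L]]
          f2 <- strsplit(ids[h], ":", fixed = TRUE)[[1L]]
          out[[length(out) + 1L]] <- data.frame(
            chain1 = f1[1L], resno1 = as.integer(f1[2L]), atom1 = f1[3L],
            chain2 = f2[1L], resno2 = as.integer(f2[2L]), atom2 = f2[3L],
            op_index = k, tx = tv[1L], ty = tv[2L], tz = tv[3L],
            distance = sqrt(d2[h]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(chain1 = character(), resno1 = integer(),
                      atom1 = character(), chain2 = character(),
                      resno2 = integer(), atom2 = character(),
                      op_index = integer(), tx = integer(), ty = integer(),
                      tz = integer(), distance = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$distance), , drop = FALSE]
}

# Fit the standard reference frame to one base: returns rotation (columns =
# base axes in global coordinates) and origin.
base_frame <- function(s, chain, resno, base = NULL) {
  if (is.null(base)) {
    nts <- nucleotides(s)
    base <- nts$resname[nts$chain == chain & nts$resno == resno][1L]
  }
  ring <- base_ring_atoms(base)
  tmpl <- base_template(base)[ring, , drop = FALSE]
  obs <- do.call(rbind, lapply(ring, function(nm) {
    p <- atom_xyz(s, chain, resno, nm)
    if (is.null(p)) stop("missing base ring atom ", nm, " in ",
                         chain, resno, " (", base, ")")
    p
  }))
  fit <- superpose(obs, tmpl)   # tmpl -> obs
  list(R = fit$rotation,
       origin = drop(fit$translation),
       rmsd = fit$rmsd, base = base)
}

# Half-rotation matrix (rotate by half the angle of R).
half_rotation <- function(R) {
  tr <- (sum(diag(R)) - 1) / 2
  ang <- acos(max(-1, min(1, tr)))
  if (ang < 1e-12) return(diag(3L))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  rotation_about_axis(ax, ang / 2 * DEG)
}

#' Intra-base-pair parameters
#'
#' Fits the embedded standard-frame base templates to the two bases, flips
#' the second base's frame for antiparallel pairing, and reports the six
#' standard parameters from the mid-frame: translations (shear, stretch,
#' stagger, Angstroms) and rotations (buckle, propeller, opening, degrees,
#' rotation-vector decomposition in the mid-frame).
#'
#' @param s an `ntc_structure`.
#' @param chain1,resno1 first base (reference strand).
#' @param chain2,resno2 second (paired) base.
#' @return named numeric: shear, stretch, stagger, buckle, propeller,
#'   opening.
#' @export
base_pair_parameters <- function(s, chain1, resno1, chain2, resno2) {
  f1 <- base_frame(s, chain1, resno1)
  f2 <- base_frame(s, chain2, resno2)
  flip <- diag(c(1, -1, -1))          # antiparallel: flip y and z
  R2 <- f2$R %*% flip
  Rrel <- t(f1$R) %*% R2
  Rm <- f1$R %*% half_rotation(Rrel)
  tvec <- drop(t(Rm) %*% (f2$origin - f1$origin))
  # rotation vector of Rrel, expressed in the mid-frame
  tr <- (sum(diag(Rrel)) - 1) / 2
  ang <- acos(max(-1, min(1, tr))) * DEG
  if (ang < 1e-9) {
    rvec <- c(0, 0, 0)
  } else {
    ax <- c(Rrel[3, 2] - Rrel[2, 3], Rrel[1, 3] - Rrel[3, 1],
            Rrel[2, 1] - Rrel[1, 2])
    ax <- unitv(ax)
    # ax lives in frame-1 coordinates; express in the mid-frame
    ax_m <- drop(t(Rm) %*% (f1$R %*% ax))
    rvec <- ang * ax_m
  }
  c(shear = tvec[1L], stretch = tvec[2L], stagger = tvec[3L],
    buckle = rvec[1L], propeller = rvec[2L], opening = rvec[3L])
}

#' Cation coordination distances
#'
#' DNA atoms within `cutoff` of each hetero atom named `ion_name`, sorted by
#' distance.
#'
#' @param s an `ntc_structure`.
#' @param ion_name residue or atom name of the ion (e.g. "SR").
#' @param cutoff maximum distance, Angstroms.
#' @return data.frame: ion_resno, chain, resno, atom, distance.
#' @export
ion_coordination <- function(s, ion_name, cutoff = 3.2) {
  a <- s$atoms
  ions <- which(a$hetero & (toupper(a$resname) == toupper(ion_name) |
                              toupper(a$atom) == toupper(ion_name)))
  dna <- which(!a$hetero)
  out <- list()
  for (i in ions) {
    p <- c(a$x[i], a$y[i], a$z[i])
    d <- sqrt((a$x[dna] - p[1L])^2 + (a$y[dna] - p[2L])^2 + (a$z[dna] - p[3L])^2)
    hits <- which(d <= cutoff)
    for (h in hits) {
      k <- dna[h]
      out[[length(out) + 1L]] <- data.frame(
        ion_resno = a$resno[i], chain = a$chain[k], resno = a$resno[k],
        atom = a$atom[k], distance = d[h], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ion_resno = integer(), chain = character(),
                      resno = integer(), atom = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$distance), , drop = FALSE]
}
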