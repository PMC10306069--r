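# Synthetic DNA fixtures: ideal and perturbed duplexes, rebuilt dinucleotide
# steps, the built-in mini conformer library, and (in density.R) synthetic
# maps.  The fiber-style constants in builder.R are the ground truth that
# every other module is tested against; they are generator constants of this
# package, not measurements of any deposited structure.

#' Specification for a synthetic duplex fixture
#'
#' @param sequence strand-1 sequence, 5'->3', over A/C/G/T.  The default is
#'   an 18-mer of the GGTGGGGC-XZ-GCCCCACC family studied in CG-rich
#'   REP-element duplexes.
#' @param form duplex form: "A" (rise 2.56 A, twist 32.7 deg, C3'-endo) or
#'   "B" (rise 3.38 A, twist 36.0 deg, C2'-endo).
#' @param torsion_noise_sigma Gaussian backbone torsion jitter, degrees.
#' @param coordinate_noise_sigma Gaussian per-coordinate jitter, Angstroms.
#' @param seed integer seed; the only source of randomness.
#' @param cell_padding padding added around the bounding box to form the P1
#'   cell, Angstroms.
#' @param spacegroup space-group symbol written to the fixture.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(sequence = "GGTGGGGCATGCCCCACC", form = "A",
                         torsion_noise_sigma = 0, coordinate_noise_sigma = 0,
                         seed = 1L, cell_padding = 12, spacegroup = "P 1") {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2L) stop("sequence must have at least 2 nucleotides")
  if (grepl("[^ACGT]", sequence)) stop("invalid sequence characters in: ", sequence)
  if (torsion_noise_sigma < 0 || coordinate_noise_sigma < 0)
    stop("noise sigmas must be >= 0")
  structure(list(sequence = sequence, form = match.arg(form, c("A", "B")),
                 torsion_noise_sigma = torsion_noise_sigma,
                 coordinate_noise_sigma = coordinate_noise_sigma,
                 seed = as.integer(seed), cell_padding = cell_padding,
                 spacegroup = spacegroup),
            class = "fixture_spec")
}

# Atom table of one residue in pair-frame coordinates: backbone + sugar +
# base.  `five_prime` drops the phosphate group.
.residue_atoms <- function(unit, base, five_prime = FALSE) {
  sugar <- unit$sugar
  bb <- unit$backbone
  tmpl <- base_template(base)
  tmpl <- tmpl[setdiff(rownames(tmpl), "C1'"), , drop = FALSE]
  m <- rbind(bb[c("P", "OP1", "OP2", "O5'"), , drop = FALSE],
             sugar[c("C5'", "C4'", "O4'", "C1'"), , drop = FALSE],
             tmpl,
             sugar[c("C2'", "C3'", "O3'"), , drop = FALSE])
  if (five_prime) m <- m[setdiff(rownames(m), c("P", "OP1", "OP2")), , drop = FALSE]
  m
}

#' Build an ideal (optionally perturbed) DNA duplex
#'
#' Constructs an antiparallel Watson-Crick duplex from rigid fiber-style
#' repeating units: chain A carries `sequence` 5'->3', chain B the
#' complement, with chain B's residue j pairing chain A's residue n+1-j.
#' Residues are stacked by the form's helical twist/rise; the two strands
#' are related by a dyad perpendicular to the helical axis.  The unit cell
#' is the padded bounding box.
#'
#' @param spec a [fixture_spec()].
#' @return an `ntc_structure`; perturbation truth metadata (when noise was
#'   requested) is attached as `attr(, "perturbation")`.
#' @export
build_duplex <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  unit <- residue_unit(spec$form)
  fp <- unit$params
  n <- nchar(spec$sequence)
  bases_a <- vapply(strsplit(spec$sequence, "")[[1L]], base_letter_to_resname,
                    character(1L), USE.NAMES = FALSE)
  coff <- c(fp$xdisp, 0, 0)
  Dy <- diag(c(1, -1, -1))
  rows <- list()
  for (slot in seq_len(n)) {
    R <- rot_z(fp$twist * (slot - 1))
    shift <- c(0, 0, fp$rise * (slot - 1))
    place <- function(m, flip) {
      mm <- if (flip) m %*% t(Dy) else m
      t(R %*% (t(mm) + coff)) + matrix(shift, nrow(m), 3L, byrow = TRUE)
    }
    # chain A residue `slot`
    ma <- .residue_atoms(unit, bases_a[slot], five_prime = slot == 1L)
    ga <- place(ma, FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = slot, resname = bases_a[slot],
      atom = rownames(ma), x = ga[, 1L], y = ga[, 2L], z = ga[, 3L],
      stringsAsFactors = FALSE)
    # chain B residue n+1-slot (5' end of B sits at slot n)
    resb <- n + 1L - slot
    baseb <- wc_complement(bases_a[slot])
    mb <- .residue_atoms(unit, baseb, five_prime = resb == 1L)
    gb <- place(mb, TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "B", resno = resb, resname = baseb,
      atom = rownames(mb), x = gb[, 1L], y = gb[, 2L], z = gb[, 3L],
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  atoms$element <- element_from_name(atoms$atom)
  atoms$o <- 1; atoms$b <- 20; atoms$alt <- ""; atoms$hetero <- FALSE
  # move into the positive octant and wrap in a padded P1 cell
  pad <- spec$cell_padding
  for (ax in c("x", "y", "z")) atoms[[ax]] <- atoms[[ax]] - min(atoms[[ax]]) + pad / 2
  cell <- c(max(atoms$x) + pad / 2, max(atoms$y) + pad / 2,
            max(atoms$z) + pad / 2, 90, 90, 90)
  s <- ntc_structure(atoms, cell = cell, spacegroup = spec$spacegroup)
  if (spec$torsion_noise_sigma > 0 || spec$coordinate_noise_sigma > 0)
    s <- perturb(s, spec)
  s
}

# Backbone bonds about which torsion jitter is applied, with the atoms of
# the owning residue that stay fixed (everything 3'-ward moves).
.jitter_bonds <- list(
  list(name = "alpha", a = "P", b = "O5'", hold = c("P", "OP1", "OP2")),
  list(name = "beta", a = "O5'", b = "C5'", hold = c("P", "OP1", "OP2", "O5'")),
  list(name = "gamma", a = "C5'", b = "C4'", hold = c("P", "OP1", "OP2", "O5'", "C5'")),
  list(name = "epsilon", a = "C3'", b = "O3'", hold = NA)  # only O3' + downstream move
)

#' Apply seeded noise to a structure
#'
#' Coordinate noise adds i.i.d. Gaussian jitter to every atom.  Torsion
#' noise rotates about backbone bonds (alpha, beta, gamma, epsilon of each
#' residue) by Gaussian angles, propagating the rotation to all atoms
#' 3'-ward along the same chain, which emulates correlated backbone
#' deformation without breaking bond geometry.
#'
#' @param s an `ntc_structure`.
#' @param spec a [fixture_spec()] carrying the noise sigmas and seed.
#' @return the perturbed structure with truth metadata in
#'   `attr(, "perturbation")` (data.frame: chain, resno, bond, delta_deg).
#' @export
perturb <- function(s, spec) {
  set.seed(spec$seed)
  atoms <- s$atoms
  truth <- list()
  if (spec$torsion_noise_sigma > 0) {
    nts <- nucleotides(s)
    for (r in seq_len(nrow(nts))) {
      ch <- nts$chain[r]; res <- nts$resno[r]
      chain_idx <- which(atoms$chain == ch & !atoms$hetero)
      for (bond in .jitter_bonds) {
        ia <- which(atoms$chain == ch & atoms$resno == res & atoms$atom == bond$a)
        ib <- which(atoms$chain == ch & atoms$resno == res & atoms$atom == bond$b)
        if (!length(ia) || !length(ib)) next
        delta <- stats::rnorm(1L, 0, spec$torsion_noise_sigma)
        if (identical(bond$hold, NA)) {
          move <- chain_idx[atoms$resno[chain_idx] > res |
                              (atoms$resno[chain_idx] == res &
                                 atoms$atom[chain_idx] == "O3'")]
        } else {
          move <- chain_idx[atoms$resno[chain_idx] > res |
                              (atoms$resno[chain_idx] == res &
                                 !(atoms$atom[chain_idx] %in% c(bond$hold, bond$b)))]
        }
        if (!length(move)) next
        p0 <- c(atoms$x[ia], atoms$y[ia], atoms$z[ia])
        p1 <- c(atoms$x[ib], atoms$y[ib], atoms$z[ib])
        R <- rotation_about_axis(p1 - p0, delta)
        xyz <- t(R %*% (t(as.matrix(atoms[move, c("x", "y", "z")])) - p0) + p0)
        atoms$x[move] <- xyz[, 1L]; atoms$y[move] <- xyz[, 2L]; atoms$z[move] <- xyz[, 3L]
        truth[[length(truth) + 1L]] <- data.frame(
          chain = ch, resno = res, bond = bond$name, delta_deg = delta,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (spec$coordinate_noise_sigma > 0) {
    nat <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(nat, 0, spec$coordinate_noise_sigma)
    atoms$y <- atoms$y + stats::rnorm(nat, 0, spec$coordinate_noise_sigma)
    atoms$z <- atoms$z + stats::rnorm(nat, 0, spec$coordinate_noise_sigma)
  }
  out <- ntc_structure(atoms, cell = s$cell, spacegroup = s$spacegroup)
  attr(out, "perturbation") <- if (length(truth)) do.call(rbind, truth) else NULL
  out
}

# Attach a base template to a placed sugar: match the glycosidic bond, then
# roll about it until chi is met.
attach_base <- function(base, c1, n_pos, o4, chi) {
  tmpl <- base_template(base)
  nglyc <- glycosidic_n(base)
  u_loc <- unitv(tmpl[nglyc, ] - tmpl["C1'", ])
  u_tgt <- unitv(n_pos - c1)
  ax <- cross3(u_loc, u_tgt); sv <- vnorm(ax)
  cosang <- max(-1, min(1, sum(u_loc * u_tgt)))
  R <- if (sv < 1e-12 && cosang > 0) diag(3L)
       else if (sv < 1e-12) rotation_about_axis(unitv(cross3(u_loc, u_loc + c(0.1, 0.2, 0.3))), 180)
       else rotation_about_axis(ax / sv, acos(cosang) * DEG)
  m <- t(R %*% (t(tmpl) - tmpl["C1'", ])) + matrix(c1, nrow(tmpl), 3L, byrow = TRUE)
  rownames(m) <- rownames(tmpl)
  cref <- chi_ref_atom(base)
  chi_now <- dihedral(o4, c1, n_pos, m[cref, ])
  for (sgn in c(-1, 1)) {
    Rchi <- rotation_about_axis(u_tgt, sgn * circ_diff(chi, chi_now))
    m2 <- t(Rchi %*% (t(m) - c1)) + matrix(c1, nrow(m), 3L, byrow = TRUE)
    rownames(m2) <- rownames(m)
    if (abs(circ_diff(dihedral(o4, c1, n_pos, m2[cref, ]), chi)) < 1e-6) break
  }
  m2[nglyc, ] <- n_pos
  m2
}

#' Rebuild a dinucleotide step from a torsion vector
#'
#' Inverse of [step_torsions()] up to the parameters a single step does not
#' determine (the absolute placement, and nt1's 5' tail, which is omitted).
#' Sugar rings are rebuilt from their nu targets, the inter-sugar backbone
#' by natural-extension placement from epsilon1, zeta1, alpha2 and beta2,
#' the second sugar is rolled to gamma2, and bases are attached at chi1 and
#' chi2.
#'
#' @param tv named torsion vector (the 22 metric parameters; P/tau_m entries
#'   are ignored).
#' @param base1,base2 residue names of the two nucleotides.
#' @return step-atom coordinate matrix in the layout of the internal step
#'   extractor (no "O5'|1" row).
#' @export
step_from_torsions <- function(tv, base1 = "DG", base2 = "DG") {
  s1 <- build_sugar_nus(unname(tv[paste0("nu", 0:4, "_1")]))
  # replace the tetrahedral O3' with the delta1-honouring placement
  o3_1 <- place_atom(s1["C5'", ], s1["C4'", ], s1["C3'", ], .bb$b_c3o3,
                     110.7, tv[["delta1"]])
  p2 <- place_atom(s1["C4'", ], s1["C3'", ], o3_1, .bb$b_o3p,
                   .bb$a_c3o3p, tv[["epsilon1"]])
  o5_2 <- place_atom(s1["C3'", ], o3_1, p2, .bb$b_o5p,
                     .bb$a_o5po3, tv[["zeta1"]])
  c5_2 <- place_atom(o3_1, p2, o5_2, .bb$b_c5o5,
                     .bb$a_c5o5p, tv[["alpha2"]])
  c4_2 <- place_atom(p2, o5_2, c5_2, .bb$b_c4c5,
                     .bb$a_c4c5o5, tv[["beta2"]])
  # second sugar: anchor C4', align its C4'->C5' bond, roll to gamma2
  s2 <- build_sugar_nus(unname(tv[paste0("nu", 0:4, "_2")]))
  u_loc <- unitv(s2["C5'", ] - s2["C4'", ])
  u_tgt <- unitv(c5_2 - c4_2)
  ax <- cross3(u_loc, u_tgt); sv <- vnorm(ax)
  cosang <- max(-1, min(1, sum(u_loc * u_tgt)))
  R <- if (sv < 1e-12 && cosang > 0) diag(3L)
       else if (sv < 1e-12) rotation_about_axis(unitv(cross3(u_loc, u_loc + c(0.1, 0.2, 0.3))), 180)
       else rotation_about_axis(ax / sv, acos(cosang) * DEG)
  m2 <- t(R %*% (t(s2) - s2["C4'", ])) + matrix(c4_2, nrow(s2), 3L, byrow = TRUE)
  rownames(m2) <- rownames(s2)
  g_now <- dihedral(o5_2, c5_2, c4_2, m2["C3'", ])
  for (sgn in c(-1, 1)) {
    Rg <- rotation_about_axis(u_tgt, sgn * circ_diff(tv[["gamma2"]], g_now))
    m2b <- t(Rg %*% (t(m2) - c4_2)) + matrix(c4_2, nrow(m2), 3L, byrow = TRUE)
    rownames(m2b) <- rownames(m2)
    if (abs(circ_diff(dihedral(o5_2, c5_2, c4_2, m2b["C3'", ]), tv[["gamma2"]])) < 1e-6) break
  }
  m2 <- m2b
  o3_2 <- place_atom(c5_2, c4_2, m2["C3'", ], .bb$b_c3o3, 110.7, tv[["delta2"]])
  b1 <- attach_base(base1, s1["C1'", ], s1["N", ], s1["O4'", ], tv[["chi1"]])
  b2 <- attach_base(base2, m2["C1'", ], m2["N", ], m2["O4'", ], tv[["chi2"]])
  coords <- rbind(
    "C5'|1" = s1["C5'", ], "C4'|1" = s1["C4'", ], "C3'|1" = s1["C3'", ],
    "O3'|1" = o3_1, "O4'|1" = s1["O4'", ], "C1'|1" = s1["C1'", ],
    "C2'|1" = s1["C2'", ], "N|1" = s1["N", ],
    "CREF|1" = b1[chi_ref_atom(base1), ],
    "P|2" = p2, "O5'|2" = o5_2, "C5'|2" = c5_2, "C4'|2" = c4_2,
    "C3'|2" = m2["C3'", ], "O3'|2" = o3_2, "O4'|2" = m2["O4'", ],
    "C1'|2" = m2["C1'", ], "C2'|2" = m2["C2'", ], "N|2" = m2["N", ],
    "CREF|2" = b2[chi_ref_atom(base2), ])
  attr(coords, "missing") <- character()
  attr(coords, "bases") <- c(base1, base2)
  coords
}

#' Build the built-in mini conformer library
#'
#' Four classes derived from the package's own fiber-style generator: AA00
#' (ideal A-form step), BB00 (ideal B-form step), AB01 (A-like first
#' nucleotide bridging to a B-like second) and BA05 (the reverse bridge).
#' Torsion sigmas default to 12 degrees and distance sigmas to 0.15 A.
#'
#' @param torsion_sigma,distance_sigma class spreads applied to every class.
#' @return an [ntc_library()] of version "ntckit-mini-1".
#' @export
build_mini_library <- function(torsion_sigma = 12, distance_sigma = 0.15) {
  sig <- c(stats::setNames(rep(torsion_sigma, length(TORSION_ANGLE_PARAMS)),
                           TORSION_ANGLE_PARAMS),
           stats::setNames(rep(distance_sigma, length(TORSION_DIST_PARAMS)),
                           TORSION_DIST_PARAMS))
  pure_step <- function(form) {
    s <- build_duplex(fixture_spec(sequence = "GGGG", form = form,
                                   cell_padding = 8))
    steps <- dinucleotide_steps(s)
    mid <- steps[steps$chain == "A" & steps$resno1 == 2L, ]
    step_atom_coords(s, mid)
  }
  cA <- pure_step("A"); cB <- pure_step("B")
  tvA <- step_torsions(cA); tvB <- step_torsions(cB)
  mix <- function(first, second) {
    tv <- first
    take2 <- c("alpha2", "beta2", "gamma2", "delta2", "chi2",
               paste0("nu", 0:4, "_2"))
    tv[take2] <- second[take2]
    rebuilt <- step_from_torsions(tv)
    # measured torsions of the rebuilt coordinates are the class targets,
    # which keeps every class exactly self-consistent
    list(coords = rebuilt, tv = step_torsions(rebuilt))
  }
  ab <- mix(tvA, tvB)
  ba <- mix(tvB, tvA)
  ntc_library(list(
    ntc_class("AA00", tvA, sig, cA),
    ntc_class("BB00", tvB, sig, cB),
    ntc_class("AB01", ab$tv, sig, ab$coords),
    ntc_class("BA05", ba$tv, sig, ba$coords)),
    version = "ntckit-mini-1", check = TRUE)
}
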