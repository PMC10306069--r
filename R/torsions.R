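# Torsional and pseudo-bond parameters of dinucleotide steps.
#
# A step i -> i+1 contributes 22 parameters: the backbone torsions delta,
# epsilon, zeta of the first nucleotide and alpha, beta, gamma, delta of the
# second; the glycosidic chi of both; the five endocyclic sugar torsions
# nu0..nu4 of both sugars; the glycosidic pseudo-torsion N1-C1'1-C1'2-N2
# (nccn); and the two cross-step pseudo-distances d_nn and d_cc.  The sugar
# pseudorotation phase P and amplitude tau_m are carried alongside as derived
# summaries and are not part of the 22-parameter metric.

# canonical parameter order used by the metric, confal and restraint code
TORSION_ANGLE_PARAMS <- c(
  "delta1", "epsilon1", "zeta1", "alpha2", "beta2", "gamma2", "delta2",
  "chi1", "chi2",
  "nu0_1", "nu1_1", "nu2_1", "nu3_1", "nu4_1",
  "nu0_2", "nu1_2", "nu2_2", "nu3_2", "nu4_2",
  "nccn")
TORSION_DIST_PARAMS <- c("d_nn", "d_cc")
TORSION_PARAMS <- c(TORSION_ANGLE_PARAMS, TORSION_DIST_PARAMS)

# Ordered step-atom subset used for torsion extraction and Cartesian
# comparison against reference conformers.  nt1 O5' is optional (absent on
# rebuilt steps and 5'-terminal residues without a phosphate tail).
STEP_ATOMS_NT1 <- c("O5'", "C5'", "C4'", "C3'", "O3'", "O4'", "C1'", "C2'", "N", "CREF")
STEP_ATOMS_NT2 <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "O4'", "C1'", "C2'", "N", "CREF")

#' Sugar pseudorotation phase and amplitude
#'
#' Altona-Sundaralingam summary of the five endocyclic torsions:
#' tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72)),
#' tau_m = nu2 / cos P, with P mapped into [0, 360).
#'
#' @param nus numeric(5): nu0..nu4 in degrees.
#' @return list with elements `P` (degrees, [0, 360)) and `tau_m` (degrees).
#' @export
pseudorotation <- function(nus) {
  stopifnot(length(nus) == 5L)
  num <- (nus[5L] + nus[2L]) - (nus[4L] + nus[1L])
  den <- 2 * nus[3L] * (sin(36 / DEG) + sin(72 / DEG))
  if (abs(num) < 1e-9 && abs(den) < 1e-9)
    stop("undefined sugar pucker: all endocyclic torsions are ~0")
  P <- atan2(num, den) * DEG
  P <- P %% 360
  tau_m <- nus[3L] / cos(P / DEG)
  list(P = P, tau_m = tau_m)
}

# Locate the dinucleotide steps of a structure: consecutive author numbering
# within a chain AND a covalent O3'(i)-P(i+1) linkage closer than 2.5 A.
#' Enumerate dinucleotide steps
#'
#' @param s an `ntc_structure`.
#' @param linkage_cutoff maximum O3'(i)-P(i+1) distance in Angstroms for two
#'   consecutive residues to form a step.
#' @return data.frame with one row per step: chain, resno1, resno2, base1,
#'   base2 and the step label `chain.base1resno1_base2resno2`.
#' @export
dinucleotide_steps <- function(s, linkage_cutoff = 2.5) {
  nts <- nucleotides(s)
  out <- list()
  for (ch in unique(nts$chain)) {
    sub <- nts[nts$chain == ch, , drop = FALSE]
    for (k in seq_len(nrow(sub) - 1L)) {
      if (sub$resno[k + 1L] != sub$resno[k] + 1L) next
      o3 <- atom_xyz(s, ch, sub$resno[k], "O3'")
      p <- atom_xyz(s, ch, sub$resno[k + 1L], "P")
      if (is.null(o3) || is.null(p) || vnorm(p - o3) >= linkage_cutoff) next
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, resno1 = sub$resno[k], resno2 = sub$resno[k + 1L],
        base1 = sub$resname[k], base2 = sub$resname[k + 1L],
        label = sprintf("%s.%s%d_%s%d", ch, sub$resname[k], sub$resno[k],
                        sub$resname[k + 1L], sub$resno[k + 1L]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), resno1 = integer(),
                      resno2 = integer(), base1 = character(),
                      base2 = character(), label = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Ordered coordinate matrix of the step-atom subset for one step (row names
# use nt-qualified atom names like "C5'|1").  Missing atoms are reported in
# attr(, "missing"); nt1 O5' is allowed to be absent.
step_atom_coords <- function(s, step) {
  get_res <- function(resno, base, names, tag) {
    rows <- lapply(names, function(nm) {
      real <- switch(nm, N = glycosidic_n(base), CREF = chi_ref_atom(base), nm)
      xyz <- atom_xyz(s, step$chain, resno, real)
      list(key = paste0(nm, "|", tag), xyz = xyz)
    })
    rows
  }
  rows <- c(get_res(step$resno1, step$base1, STEP_ATOMS_NT1, "1"),
            get_res(step$resno2, step$base2, STEP_ATOMS_NT2, "2"))
  keys <- vapply(rows, `[[`, character(1L), "key")
  have <- !vapply(rows, function(r) is.null(r$xyz), logical(1L))
  m <- do.call(rbind, lapply(rows[have], `[[`, "xyz"))
  rownames(m) <- keys[have]
  missing <- setdiff(keys[!have], "O5'|1")  # nt1 O5' is optional
  attr(m, "missing") <- missing
  m
}

#' Torsional and pseudo-bond parameters of a dinucleotide step
#'
#' @param coords step-atom coordinate matrix from an internal step lookup, or
#'   an `ntc_structure` together with `step` (a row of
#'   [dinucleotide_steps()]).
#' @param step when `coords` is a structure, the step descriptor row.
#' @return named numeric vector with the 22 metric parameters (backbone and
#'   glycosidic torsions, sugar nu torsions, nccn pseudo-torsion, d_nn and
#'   d_cc pseudo-distances) plus the derived P1, tau_m1, P2, tau_m2.
#' @export
step_torsions <- function(coords, step = NULL) {
  if (is_ntc_structure(coords)) {
    stopifnot(!is.null(step))
    coords <- step_atom_coords(coords, step)
  }
  miss <- attr(coords, "missing")
  if (length(miss))
    stop("incomplete step: missing atoms ", paste(miss, collapse = ", "))
  g <- function(nm) coords[nm, ]
  tv <- c(
    delta1   = dihedral(g("C5'|1"), g("C4'|1"), g("C3'|1"), g("O3'|1")),
    epsilon1 = dihedral(g("C4'|1"), g("C3'|1"), g("O3'|1"), g("P|2")),
    zeta1    = dihedral(g("C3'|1"), g("O3'|1"), g("P|2"), g("O5'|2")),
    alpha2   = dihedral(g("O3'|1"), g("P|2"), g("O5'|2"), g("C5'|2")),
    beta2    = dihedral(g("P|2"), g("O5'|2"), g("C5'|2"), g("C4'|2")),
    gamma2   = dihedral(g("O5'|2"), g("C5'|2"), g("C4'|2"), g("C3'|2")),
    delta2   = dihedral(g("C5'|2"), g("C4'|2"), g("C3'|2"), g("O3'|2")),
    chi1     = dihedral(g("O4'|1"), g("C1'|1"), g("N|1"), g("CREF|1")),
    chi2     = dihedral(g("O4'|2"), g("C1'|2"), g("N|2"), g("CREF|2")))
  for (i in 1:2) {
    o4 <- g(paste0("O4'|", i)); c1 <- g(paste0("C1'|", i))
    c2 <- g(paste0("C2'|", i)); c3 <- g(paste0("C3'|", i))
    c4 <- g(paste0("C4'|", i))
    nus <- c(dihedral(c4, o4, c1, c2), dihedral(o4, c1, c2, c3),
             dihedral(c1, c2, c3, c4), dihedral(c2, c3, c4, o4),
             dihedral(c3, c4, o4, c1))
    names(nus) <- paste0("nu", 0:4, "_", i)
    tv <- c(tv, nus)
  }
  tv <- c(tv,
          nccn = dihedral(g("N|1"), g("C1'|1"), g("C1'|2"), g("N|2")),
          d_nn = vnorm(g("N|1") - g("N|2")),
          d_cc = vnorm(g("C1'|1") - g("C1'|2")))
  for (i in 1:2) {
    ps <- pseudorotation(tv[paste0("nu", 0:4, "_", i)])
    tv[paste0("P", i)] <- ps$P
    tv[paste0("tau_m", i)] <- ps$tau_m
  }
  tv
}

#' Export a torsion table for all steps of a structure
#'
#' @param s an `ntc_structure`.
#' @return data.frame with one row per step (label first, then the torsion
#'   columns in canonical order).
#' @export
torsion_table <- function(s) {
  steps <- dinucleotide_steps(s)
  rows <- lapply(seq_len(nrow(steps)), function(i) {
    tv <- tryCatch(step_torsions(s, steps[i, ]), error = function(e) NULL)
    if (is.null(tv)) return(NULL)
    cbind(data.frame(label = steps$label[i], stringsAsFactors = FALSE),
          as.data.frame(as.list(tv)))
  })
  do.call(rbind, rows)
}
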