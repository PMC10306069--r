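# The typed coordinate model used throughout the package.
#
# An `ntc_structure` is a list with:
#   atoms      data.frame: chain, resno, resname, atom, element,
#              x, y, z, o, b, alt, hetero
#   cell       numeric(6): a, b, c (Angstrom), alpha, beta, gamma (deg); or NULL
#   spacegroup Hermann-Mauguin symbol, or NA
#
# Coordinates are orthogonal Angstroms everywhere; fractional coordinates
# exist only transiently inside the symmetry and map code.  Hydrogens are
# dropped on input and atom-name primes are normalized to the ASCII
# apostrophe form (O3').

DNA_BASES <- c("DA", "DC", "DG", "DT")

#' Construct a structure object
#'
#' @param atoms data.frame with columns chain, resno, resname, atom, element,
#'   x, y, z and optionally o (occupancy), b (B-factor), alt (alternate
#'   location id), hetero (logical; non-nucleic atoms).
#' @param cell numeric(6) lattice parameters (a, b, c, alpha, beta, gamma) or
#'   NULL when unknown.
#' @param spacegroup Hermann-Mauguin space-group symbol or NA.
#' @return an object of class `ntc_structure`.
#' @export
ntc_structure <- function(atoms, cell = NULL, spacegroup = NA_character_) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 20
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$hetero)) atoms$hetero <- !(atoms$resname %in% DNA_BASES)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atoms")
  if (any(atoms$o < 0 | atoms$o > 1)) stop("occupancy outside [0, 1]")
  if (any(atoms$b < 0)) stop("negative B-factor")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6L || any(cell[1:3] <= 0) ||
        any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
      stop("invalid unit cell")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, spacegroup = spacegroup),
            class = "ntc_structure")
}

#' @export
print.ntc_structure <- function(x, ...) {
  a <- x$atoms
  na <- a[!a$hetero, , drop = FALSE]
  nres <- nrow(unique(na[, c("chain", "resno")]))
  cat("ntc_structure:", nres, "nucleotides in",
      length(unique(na$chain)), "chain(s),",
      sum(a$hetero), "hetero atoms\n")
  if (!is.null(x$cell))
    cat(sprintf("  cell %.2f %.2f %.2f  %.1f %.1f %.1f   %s\n",
                x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6],
                ifelse(is.na(x$spacegroup), "?", x$spacegroup)))
  invisible(x)
}

is_ntc_structure <- function(x) inherits(x, "ntc_structure")

#' Nucleotide residue table of a structure
#'
#' @param s an `ntc_structure`.
#' @return data.frame with one row per DNA residue: chain, resno, resname.
#' @export
nucleotides <- function(s) {
  a <- s$atoms[!s$atoms$hetero & s$atoms$resname %in% DNA_BASES, , drop = FALSE]
  u <- unique(a[, c("chain", "resno", "resname")])
  u <- u[order(u$chain, u$resno), , drop = FALSE]
  rownames(u) <- NULL
  u
}

# Coordinate lookup: named 3-vector for one atom, or NULL when absent.
atom_xyz <- function(s, chain, resno, atom) {
  a <- s$atoms
  i <- which(a$chain == chain & a$resno == resno & a$atom == atom)
  if (!length(i)) return(NULL)
  c(a$x[i[1L]], a$y[i[1L]], a$z[i[1L]])
}

# All coordinates of a residue as a named matrix (rows = atom names).
residue_xyz <- function(s, chain, resno) {
  a <- s$atoms
  i <- which(a$chain == chain & a$resno == resno)
  m <- as.matrix(a[i, c("x", "y", "z")])
  rownames(m) <- a$atom[i]
  m
}

coords_matrix <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- list(atoms$atom, NULL)
  m
}

# Normalize atom names: unicode prime to apostrophe, trim, uppercase, and
# map legacy O1P/O2P style names.
normalize_atom_name <- function(name) {
  nm <- gsub("′", "'", trimws(name))
  nm <- toupper(nm)
  nm <- sub("\\*$", "'", nm)             # old-style C1* names
  nm[nm == "O1P"] <- "OP1"
  nm[nm == "O2P"] <- "OP2"
  nm
}

# Keep the highest-occupancy alt-loc (ties: alphabetically first id) and
# drop hydrogens.
select_altloc <- function(atoms) {
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(atoms) || all(atoms$alt %in% "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    if (length(i) == 1L) return(i)
    o <- atoms$o[i]
    best <- i[o == max(o)]
    if (length(best) > 1L) best <- best[order(atoms$alt[best])][1L]
    best
  }), use.names = FALSE)
  out <- atoms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
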