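# Space-group symmetry: operator tables, fractional/orthogonal conversion,
# and symmetry expansion of atom sets.
#
# Operator triplets for the groups this package needs are embedded directly
# (verified by the group-closure property tests); arbitrary user-supplied
# triplets in the same x,y,z notation are also accepted.

.spacegroup_ops <- list(
  "P 1" = c("x,y,z"),
  "P 2" = c("x,y,z", "-x,y,-z"),
  "P 21" = c("x,y,z", "-x,y+1/2,-z"),
  "C 2" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z",
                   "-x,y+1/2,-z+1/2"),
  "P 41 21 2" = c("x,y,z", "-y+1/2,x+1/2,z+1/4", "-x,-y,z+1/2",
                  "y+1/2,-x+1/2,z+3/4", "x+1/2,-y+1/2,-z+3/4",
                  "-y,-x,-z+1/2", "-x+1/2,y+1/2,-z+1/4", "y,x,-z"),
  "P 43 21 2" = c("x,y,z", "-y+1/2,x+1/2,z+3/4", "-x,-y,z+1/2",
                  "y+1/2,-x+1/2,z+1/4", "x+1/2,-y+1/2,-z+1/4",
                  "-y,-x,-z+1/2", "-x+1/2,y+1/2,-z+3/4", "y,x,-z")
)

# Normalize a Hermann-Mauguin symbol: strip spaces/underscores, upper-case,
# so "P43212", "P 43 21 2" and "p_43_21_2" all match.
normalize_sg_symbol <- function(symbol) {
  toupper(gsub("[ _]", "", symbol))
}

#' Symmetry operators of a space group
#'
#' @param symbol Hermann-Mauguin symbol (spacing-insensitive), e.g.
#'   "P 43 21 2" or "P43212".
#' @return list of operators, each a list with `R` (3 x 3 rotation part,
#'   fractional) and `t` (translation part, fractional).
#' @export
sg_operators <- function(symbol) {
  key <- normalize_sg_symbol(symbol)
  hit <- which(vapply(names(.spacegroup_ops), normalize_sg_symbol,
                      character(1L)) == key)
  if (!length(hit))
    stop("space group not in the built-in table: ", symbol,
         " (available: ", paste(names(.spacegroup_ops), collapse = ", "), ")")
  lapply(.spacegroup_ops[[hit[1L]]], parse_symop)
}

#' Parse an x,y,z symmetry-operator triplet
#'
#' @param triplet e.g. `"-y+1/2,x+1/2,z+3/4"`.
#' @return list with fractional rotation matrix `R` and translation `t`.
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) stop("malformed symmetry triplet: ", triplet)
  R <- matrix(0, 3L, 3L); t <- numeric(3L)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1L]]
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        f <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1L]])
        t[i] <- t[i] + sgn * f[1L] / f[2L]
      } else if (grepl("^[0-9.]+$", body)) {
        t[i] <- t[i] + sgn * as.numeric(body)
      } else stop("malformed symmetry term '", tok, "' in: ", triplet)
    }
  }
  list(R = R, t = t)
}

# Orthogonalization matrix (PDB convention: a along x, b in the xy plane).
orth_matrix <- function(cell) {
  a <- cell[1L]; b <- cell[2L]; cc <- cell[3L]
  al <- cell[4L] / DEG; be <- cell[5L] / DEG; ga <- cell[6L] / DEG
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)),
         3L, 3L, byrow = TRUE)
}

frac_coords <- function(xyz, cell) t(solve(orth_matrix(cell)) %*% t(xyz))
orth_coords <- function(frac, cell) t(orth_matrix(cell) %*% t(frac))

#' Apply a symmetry operator (plus lattice translation) to a structure
#'
#' @param s an `ntc_structure` with cell and space group.
#' @param op_index 1-based operator index (1 = identity).
#' @param translations integer lattice translation (length 3).
#' @return the atoms data.frame of `s` with transformed coordinates, in
#'   orthogonal Angstroms.
#' @export
apply_symmetry <- function(s, op_index = 1L, translations = c(0L, 0L, 0L)) {
  if (is.null(s$cell) || is.na(s$spacegroup))
    stop("symmetry unavailable: structure has no cell or space group")
  ops <- sg_operators(s$spacegroup)
  if (op_index < 1L || op_index > length(ops))
    stop("operator index out of range: ", op_index, " (group has ",
         length(ops), " operators)")
  op <- ops[[op_index]]
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  fr <- frac_coords(xyz, s$cell)
  fr2 <- t(op$R %*% t(fr)) +
    matrix(op$t + translations, nrow(fr), 3L, byrow = TRUE)
  out <- s$atoms
  o2 <- orth_coords(fr2, s$cell)
  out$x <- o2[, 1L]; out$y <- o2[, 2L]; out$z <- o2[, 3L]
  out
}
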