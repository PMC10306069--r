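# Idealized planar base templates, expressed in the base-pair reference
# frame: z = 0 base plane, x-axis along the pair pseudo-dyad pointing toward
# the major groove, y-axis toward the strand-1 backbone.  A Watson-Crick
# partner is the template of the complementary base with y and z negated.
# The templates are shifted 0.125 A toward the dyad relative to textbook
# standard-frame tables so that an ideal pair has a C1'-C1' separation of
# ~10.5 A; the same tables serve the duplex generator and the base-pair
# parameter code, which keeps the two exactly consistent.

.base_templates_raw <- list(
  DA = matrix(c(
    -1.291, 4.498, 0,   #  N9
     0.024, 4.897, 0,   #  C8
     0.877, 3.902, 0,   #  N7
     0.071, 2.771, 0,   #  C5
     0.369, 1.398, 0,   #  C6
     1.611, 0.909, 0,   #  N6
    -0.668, 0.532, 0,   #  N1
    -1.912, 1.023, 0,   #  C2
    -2.320, 2.290, 0,   #  N3
    -1.267, 3.124, 0,   #  C4
    -2.479, 5.346, 0    #  C1'
  ), ncol = 3L, byrow = TRUE,
     dimnames = list(c("N9","C8","N7","C5","C6","N6","N1","C2","N3","C4","C1'"), NULL)),
  DG = matrix(c(
    -1.289, 4.551, 0,   #  N9
     0.023, 4.962, 0,   #  C8
     0.870, 3.969, 0,   #  N7
     0.071, 2.833, 0,   #  C5
     0.424, 1.460, 0,   #  C6
     1.554, 0.955, 0,   #  O6
    -0.700, 0.641, 0,   #  N1
    -1.999, 1.087, 0,   #  C2
    -2.949, 0.139, 0,   #  N2
    -2.342, 2.364, 0,   #  N3
    -1.265, 3.177, 0,   #  C4
    -2.477, 5.399, 0    #  C1'
  ), ncol = 3L, byrow = TRUE,
     dimnames = list(c("N9","C8","N7","C5","C6","O6","N1","C2","N2","N3","C4","C1'"), NULL)),
  DC = matrix(c(
    -1.285, 4.542, 0,   #  N1
    -1.472, 3.158, 0,   #  C2
    -2.628, 2.709, 0,   #  O2
    -0.391, 2.344, 0,   #  N3
     0.837, 2.868, 0,   #  C4
     1.875, 2.027, 0,   #  N4
     1.056, 4.275, 0,   #  C5
    -0.023, 5.068, 0,   #  C6
    -2.477, 5.402, 0    #  C1'
  ), ncol = 3L, byrow = TRUE,
     dimnames = list(c("N1","C2","O2","N3","C4","N4","C5","C6","C1'"), NULL)),
  DT = matrix(c(
    -1.284, 4.500, 0,   #  N1
    -1.462, 3.135, 0,   #  C2
    -2.562, 2.608, 0,   #  O2
    -0.298, 2.407, 0,   #  N3
     0.994, 2.897, 0,   #  C4
     1.944, 2.119, 0,   #  O4
     1.106, 4.338, 0,   #  C5
     2.466, 4.961, 0,   #  C7
    -0.024, 5.057, 0,   #  C6
    -2.481, 5.354, 0    #  C1'
  ), ncol = 3L, byrow = TRUE,
     dimnames = list(c("N1","C2","O2","N3","C4","O4","C5","C7","C6","C1'"), NULL))
)

# Canonical glycosidic anchor shared by all four bases.  Each raw template is
# rigidly rotated/translated in the base plane so its C1' and glycosidic N
# land exactly on these points; the small (<0.01 A) residual on N is snapped.
# This makes the sugar-phosphate geometry of the duplex generator exactly
# sequence-independent and gives an ideal pair a C1'-C1' separation of 10.5 A.
.c1_anchor <- c(-2.478, 5.250, 0)
.n_anchor  <- c(-1.287, 4.400, 0)

base_template <- function(base) {
  m <- .base_templates_raw[[base]]
  if (is.null(m)) stop("unknown base: ", base)
  nglyc <- if (base %in% c("DA", "DG")) "N9" else "N1"
  c1 <- m["C1'", ]; n <- m[nglyc, ]
  th <- atan2(.n_anchor[2] - .c1_anchor[2], .n_anchor[1] - .c1_anchor[1]) -
        atan2(n[2] - c1[2], n[1] - c1[1])
  R <- rot_z(th * DEG)
  m <- t(R %*% (t(m) - c1) + .c1_anchor)
  dimnames(m) <- dimnames(.base_templates_raw[[base]])
  m[nglyc, ] <- .n_anchor
  m
}

# Ring atoms used to fit the base reference frame (no exocyclic substituents).
base_ring_atoms <- function(base) {
  switch(base,
    DA = , DG = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
    DC = , DT = c("N1", "C2", "N3", "C4", "C5", "C6"),
    stop("unknown base: ", base))
}

glycosidic_n <- function(base) if (base %in% c("DA", "DG")) "N9" else "N1"

# Fourth atom of the chi torsion O4'-C1'-N-X.
chi_ref_atom <- function(base) if (base %in% c("DA", "DG")) "C4" else "C2"

wc_complement <- function(base) {
  switch(base, DA = "DT", DT = "DA", DG = "DC", DC = "DG",
         stop("unknown base: ", base))
}

base_letter_to_resname <- function(ch) {
  switch(toupper(ch), A = "DA", C = "DC", G = "DG", T = "DT",
         stop("invalid sequence character: ", ch))
}

# Electron counts for the density model.
.electron_counts <- c(H = 1, C = 6, N = 7, O = 8, P = 15,
                      MG = 12, NA. = 11, K = 19, CL = 17, SR = 38, CA = 20)

electron_count <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  z <- .electron_counts[key]
  z[is.na(z)] <- 7  # conservative default for unknown elements
  unname(z)
}

# Infer element from a (normalized) atom name.
element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm2 <- toupper(gsub("[^A-Za-z].*$", "", nm))
    if (nm2 %in% c("SR", "MG", "CL", "CA", "NA", "K")) return(nm2)
    substr(nm2, 1L, 1L)
  }, character(1L), USE.NAMES = FALSE)
}
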