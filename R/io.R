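# Reading and writing DNA coordinate models.  PDB files go through bio3d;
# mmCIF (PDBx atom_site) is parsed and written by a small dedicated reader
# since no installed package writes mmCIF.  On input, hydrogens are dropped,
# atom-name primes are normalized, and by default the highest-occupancy
# alternate conformer is kept (ties break to the alphabetically first
# alt-loc id).

#' Read a DNA structure from a PDB or mmCIF file
#'
#' @param path file path.
#' @param format `"auto"` (sniff by content), `"pdb"` or `"mmcif"`.
#' @param keep_altlocs keep all alternate conformers instead of the default
#'   highest-occupancy selection.
#' @return an `ntc_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_altlocs = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- sniff_format(path)
  s <- if (format == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
  atoms <- s$atoms
  atoms$atom <- normalize_atom_name(atoms$atom)
  if (!keep_altlocs) atoms <- select_altloc(atoms)
  else atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (!any(atoms$resname %in% DNA_BASES))
    stop("empty model: no nucleic-acid residues found in ", path)
  ntc_structure(atoms, cell = s$cell, spacegroup = s$spacegroup)
}

sniff_format <- function(path) {
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_", head_lines)) || any(grepl("_atom_site\\.", head_lines)))
    return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1)", head_lines)))
    return("pdb")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  stop("cannot determine format of ", path,
       ": no recognizable PDB or mmCIF records")
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  element <- if (!is.null(a$elesy) && any(nzchar(trimws(a$elesy))))
    toupper(trimws(a$elesy)) else element_from_name(normalize_atom_name(a$elety))
  element[!nzchar(element)] <-
    element_from_name(normalize_atom_name(a$elety))[!nzchar(element)]
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain),
    resno = a$resno, resname = trimws(a$resid),
    atom = trimws(a$elety), element = element,
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt), "", a$alt),
    hetero = a$type == "HETATM" | !(trimws(a$resid) %in% DNA_BASES),
    stringsAsFactors = FALSE)
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  cell <- NULL; sg <- NA_character_
  if (length(cr)) {
    ln <- cr[1L]
    cell <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                         substr(ln, 25, 33), substr(ln, 34, 40),
                         substr(ln, 41, 47), substr(ln, 48, 54)))
    sg <- trimws(substr(ln, 56, 66))
    if (!nzchar(sg)) sg <- NA_character_
    if (any(is.na(cell))) cell <- NULL
  }
  list(atoms = atoms, cell = cell, spacegroup = sg)
}

# Minimal PDBx/mmCIF atom_site reader (loop_ layout, whitespace-separated
# with quoted tokens).
read_structure_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  li <- grep("^\\s*loop_\\s*$", lines)
  start <- NA_integer_; headers <- character()
  for (l in li) {
    j <- l + 1L
    hdr <- character()
    while (j <= length(lines) && grepl("^\\s*_atom_site\\.", lines[j])) {
      hdr <- c(hdr, sub("^\\s*_atom_site\\.([^ ]+)\\s*$", "\\1", lines[j]))
      j <- j + 1L
    }
    if (length(hdr)) { start <- j; headers <- hdr; break }
  }
  if (is.na(start))
    stop("unparseable mmCIF file ", path, ": no _atom_site loop found")
  rows <- list()
  j <- start
  while (j <= length(lines)) {
    ln <- lines[j]
    if (grepl("^\\s*(#|loop_|_[a-zA-Z]|data_)", ln) || !nzchar(trimws(ln))) break
    toks <- cif_tokens(ln)
    if (length(toks) != length(headers))
      stop("unparseable mmCIF file ", path, ": atom_site row at line ", j,
           " has ", length(toks), " fields, expected ", length(headers))
    rows[[length(rows) + 1L]] <- toks
    j <- j + 1L
  }
  if (!length(rows)) stop("empty model: mmCIF file ", path, " has no atom rows")
  m <- do.call(rbind, rows)
  colnames(m) <- headers
  gv <- function(nm, default = NA_character_) {
    if (nm %in% headers) m[, nm] else rep(default, nrow(m))
  }
  alt <- gv("label_alt_id")
  alt[is.na(alt) | alt %in% c(".", "?")] <- ""
  chain <- gv("auth_asym_id"); lab_chain <- gv("label_asym_id")
  chain[is.na(chain)] <- lab_chain[is.na(chain)]
  resno <- gv("auth_seq_id"); lab_resno <- gv("label_seq_id")
  resno[is.na(resno)] <- lab_resno[is.na(resno)]
  elem <- toupper(gv("type_symbol"))
  nm <- gv("label_atom_id")
  elem[is.na(elem) | elem %in% c(".", "?")] <-
    element_from_name(normalize_atom_name(nm))[is.na(elem) | elem %in% c(".", "?")]
  grp <- gv("group_PDB", "ATOM")
  resname <- gv("label_comp_id")
  occ <- suppressWarnings(as.numeric(gv("occupancy", "1")))
  bf <- suppressWarnings(as.numeric(gv("B_iso_or_equiv", "0")))
  atoms <- data.frame(
    chain = chain, resno = suppressWarnings(as.integer(resno)),
    resname = resname, atom = nm, element = elem,
    x = as.numeric(m[, "Cartn_x"]), y = as.numeric(m[, "Cartn_y"]),
    z = as.numeric(m[, "Cartn_z"]),
    o = ifelse(is.na(occ), 1, occ), b = ifelse(is.na(bf), 0, bf),
    alt = alt,
    hetero = grp == "HETATM" | !(resname %in% DNA_BASES),
    stringsAsFactors = FALSE)
  cell <- NULL; sg <- NA_character_
  cv <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(ln[1L]), "\\s+")[[1L]][2L]))
  }
  cl <- c(cv("_cell\\.length_a"), cv("_cell\\.length_b"), cv("_cell\\.length_c"),
          cv("_cell\\.angle_alpha"), cv("_cell\\.angle_beta"), cv("_cell\\.angle_gamma"))
  if (!any(is.na(cl))) cell <- cl
  sgl <- grep("^\\s*_symmetry\\.space_group_name_H-M\\s", lines, value = TRUE)
  if (length(sgl)) {
    sg <- trimws(sub("^\\s*_symmetry\\.space_group_name_H-M\\s+", "", sgl[1L]))
    sg <- gsub("^['\"]|['\"]$", "", sg)
  }
  list(atoms = atoms, cell = cell, spacegroup = sg)
}

# whitespace tokenizer honouring single/double quotes
cif_tokens <- function(line) {
  toks <- character(); i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      toks <- c(toks, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("\\s", substr(line, j, j))) j <- j + 1L
      toks <- c(toks, substr(line, i, j - 1L))
      i <- j
    }
  }
  toks
}

#' Write a structure to PDB or mmCIF
#'
#' The emitted file re-reads to an equal model (coordinates to 1e-3 A,
#' names exact).
#'
#' @param s an `ntc_structure`.
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension; defaults to
#'   mmCIF).
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "mmcif"
  }
  if (format == "pdb") write_structure_pdb(s, path) else write_structure_mmcif(s, path)
  invisible(path)
}

write_structure_pdb <- function(s, path) {
  a <- s$atoms
  lines <- character()
  if (!is.null(s$cell)) {
    sg <- if (is.na(s$spacegroup)) "P 1" else s$spacegroup
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      s$cell[1], s$cell[2], s$cell[3], s$cell[4], s$cell[5], s$cell[6], sg, 1L))
  }
  for (i in seq_len(nrow(a))) {
    nm <- a$atom[i]
    # PDB name field: element right-justified in columns 13-14
    namefield <- if (nchar(nm) >= 4L) substr(nm, 1L, 4L) else
      sprintf(" %-3s", nm)
    lines <- c(lines, sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (a$hetero[i]) "HETATM" else "ATOM", i %% 100000L, namefield,
      substr(paste0(a$alt[i], " "), 1L, 1L), a$resname[i],
      substr(a$chain[i], 1L, 1L), a$resno[i],
      a$x[i], a$y[i], a$z[i], a$o[i], a$b[i],
      substr(a$element[i], 1L, 2L)))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
}

write_structure_mmcif <- function(s, path) {
  a <- s$atoms
  lines <- c("data_ntckit", "#")
  if (!is.null(s$cell)) {
    lines <- c(lines,
               sprintf("_cell.length_a    %.4f", s$cell[1]),
               sprintf("_cell.length_b    %.4f", s$cell[2]),
               sprintf("_cell.length_c    %.4f", s$cell[3]),
               sprintf("_cell.angle_alpha %.4f", s$cell[4]),
               sprintf("_cell.angle_beta  %.4f", s$cell[5]),
               sprintf("_cell.angle_gamma %.4f", s$cell[6]), "#")
  }
  if (!is.na(s$spacegroup))
    lines <- c(lines,
               sprintf("_symmetry.space_group_name_H-M '%s'", s$spacegroup), "#")
  lines <- c(lines, "loop_",
             "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
             "_atom_site.label_atom_id", "_atom_site.label_alt_id",
             "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
             "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
             "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv")
  qn <- function(nm) ifelse(grepl("'", nm), nm, sprintf('"%s"', nm))
  for (i in seq_len(nrow(a))) {
    nm <- a$atom[i]
    nm_out <- if (grepl("'", nm)) sprintf('"%s"', nm) else nm
    alt <- if (nzchar(a$alt[i])) a$alt[i] else "."
    lines <- c(lines, sprintf(
      "%-6s %d %s %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f",
      if (a$hetero[i]) "HETATM" else "ATOM", i, a$element[i], nm_out, alt,
      a$resname[i], a$chain[i], a$resno[i], a$x[i], a$y[i], a$z[i],
      a$o[i], a$b[i]))
  }
  lines <- c(lines, "#")
  writeLines(lines, path)
}
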