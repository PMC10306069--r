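# Generation, rendering and parsing of per-step torsion/pseudo-bond
# restraints.  Restraint targets are always the assigned class's targets,
# never the model's current torsions: the restraints pull the model toward
# the known conformer, which is the point of conformation-based refinement.
# Only steps whose Cartesian r.m.s.d. to the nearest class is within 0.5 A
# are restrained.
#
# Two output dialects are provided.  The phenix-style dialect expresses the
# published ntc_delete / ntc_change action model: for every parameter the
# refinement program's auto-generated torsion restraint on those atoms is
# deleted, then the class-derived target is assigned.  The refmac-style
# dialect writes external torsion/distance restraint lines.  The exact file
# grammar of either refinement program fork is not reproduced; both dialects
# are documented, self-consistent and mutually convertible.

# atom quadruples/pairs per parameter: list of c(nt_index, atom_name) with
# "N"/"CREF" resolved per base at build time
.param_atoms <- list(
  delta1   = list(c(1, "C5'"), c(1, "C4'"), c(1, "C3'"), c(1, "O3'")),
  epsilon1 = list(c(1, "C4'"), c(1, "C3'"), c(1, "O3'"), c(2, "P")),
  zeta1    = list(c(1, "C3'"), c(1, "O3'"), c(2, "P"), c(2, "O5'")),
  alpha2   = list(c(1, "O3'"), c(2, "P"), c(2, "O5'"), c(2, "C5'")),
  beta2    = list(c(2, "P"), c(2, "O5'"), c(2, "C5'"), c(2, "C4'")),
  gamma2   = list(c(2, "O5'"), c(2, "C5'"), c(2, "C4'"), c(2, "C3'")),
  delta2   = list(c(2, "C5'"), c(2, "C4'"), c(2, "C3'"), c(2, "O3'")),
  chi1     = list(c(1, "O4'"), c(1, "C1'"), c(1, "N"), c(1, "CREF")),
  chi2     = list(c(2, "O4'"), c(2, "C1'"), c(2, "N"), c(2, "CREF")),
  nu0_1 = list(c(1, "C4'"), c(1, "O4'"), c(1, "C1'"), c(1, "C2'")),
  nu1_1 = list(c(1, "O4'"), c(1, "C1'"), c(1, "C2'"), c(1, "C3'")),
  nu2_1 = list(c(1, "C1'"), c(1, "C2'"), c(1, "C3'"), c(1, "C4'")),
  nu3_1 = list(c(1, "C2'"), c(1, "C3'"), c(1, "C4'"), c(1, "O4'")),
  nu4_1 = list(c(1, "C3'"), c(1, "C4'"), c(1, "O4'"), c(1, "C1'")),
  nu0_2 = list(c(2, "C4'"), c(2, "O4'"), c(2, "C1'"), c(2, "C2'")),
  nu1_2 = list(c(2, "O4'"), c(2, "C1'"), c(2, "C2'"), c(2, "C3'")),
  nu2_2 = list(c(2, "C1'"), c(2, "C2'"), c(2, "C3'"), c(2, "C4'")),
  nu3_2 = list(c(2, "C2'"), c(2, "C3'"), c(2, "C4'"), c(2, "O4'")),
  nu4_2 = list(c(2, "C3'"), c(2, "C4'"), c(2, "O4'"), c(2, "C1'")),
  nccn  = list(c(1, "N"), c(1, "C1'"), c(2, "C1'"), c(2, "N")),
  d_nn  = list(c(1, "N"), c(2, "N")),
  d_cc  = list(c(1, "C1'"), c(2, "C1'"))
)

is_distance_param <- function(p) p %in% TORSION_DIST_PARAMS

#' Parse a residue-range step selection
#'
#' Accepts selections like `"1-7,12-18"` (1-based, inclusive).  A step is
#' selected when both of its residues fall inside the selection.
#'
#' @param text selection string, or NULL for "all".
#' @return integer vector of residue numbers, or NULL.
#' @export
parse_step_selection <- function(text) {
  if (is.null(text) || !nzchar(text)) return(NULL)
  parts <- strsplit(text, ",", fixed = TRUE)[[1L]]
  out <- integer()
  for (p in parts) {
    p <- trimws(p)
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else if (grepl("^[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else stop("cannot parse step selection fragment: '", p, "'")
  }
  sort(unique(out))
}

#' Build a restraint set from assignments
#'
#' One record per parameter (22 per restrained step).  Sigmas come from the
#' assigned class, clamped to `sigma_clamp_tor` degrees (torsions) or
#' `sigma_clamp_dist` Angstroms (pseudo-distances) and divided by the
#' effective weight (global x per-step): larger weights mean tighter
#' restraints.
#'
#' @param assignments result of [assign_structure()].
#' @param lib the [ntc_library()] used for assignment.
#' @param model the `ntc_structure` the assignments refer to.
#' @param global_weight positive overall weight.
#' @param per_step_weights optional named numeric (step_label -> weight).
#' @param include_residues optional integer residue set (see
#'   [parse_step_selection()]); a step is restrained only when both its
#'   residues are in the set.
#' @param tighter use the 0.5x tighter-sigma preset.
#' @param sigma_clamp_tor,sigma_clamp_dist clamp intervals for class sigmas.
#' @return object of class `ntc_restraint_set`.
#' @export
build_restraints <- function(assignments, lib, model, global_weight = 1.0,
                             per_step_weights = NULL, include_residues = NULL,
                             tighter = FALSE,
                             sigma_clamp_tor = c(8, 25),
                             sigma_clamp_dist = c(0.05, 0.3)) {
  if (global_weight <= 0) stop("global_weight must be positive")
  if (!is.null(per_step_weights) && any(per_step_weights <= 0))
    stop("per-step weights must be positive")
  steps <- attr(assignments, "steps")
  if (is.null(steps)) stop("assignments must come from assign_structure()")
  nts <- nucleotides(model)
  recs <- list()
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    if (!isTRUE(a$eligible) || a$ntc == "NANT") next
    st <- steps[steps$label == a$step_label, ]
    if (!nrow(st)) stop("assignment refers to a step absent from the model: ",
                        a$step_label)
    if (!is.null(include_residues) &&
        !(st$resno1 %in% include_residues && st$resno2 %in% include_residues))
      next
    cl <- lib$classes[[a$ntc]]
    w <- global_weight
    if (!is.null(per_step_weights) && a$step_label %in% names(per_step_weights))
      w <- w * per_step_weights[[a$step_label]]
    bases <- c(st$base1, st$base2)
    resnos <- c(st$resno1, st$resno2)
    for (p in TORSION_PARAMS) {
      sg <- cl$sigmas[[p]]
      clamp <- if (is_distance_param(p)) sigma_clamp_dist else sigma_clamp_tor
      sg <- min(max(sg, clamp[1L]), clamp[2L])
      if (tighter) sg <- sg * 0.5
      sg <- sg / w
      atoms <- vapply(.param_atoms[[p]], function(ref) {
        k <- as.integer(ref[1L])
        nm <- switch(ref[2L], N = glycosidic_n(bases[k]),
                     CREF = chi_ref_atom(bases[k]), ref[2L])
        if (is.null(atom_xyz(model, st$chain, resnos[k], nm)))
          stop("restraint atom missing from model: ",
               st$chain, resnos[k], " ", nm)
        paste(st$chain, resnos[k], nm, sep = ":")
      }, character(1L))
      recs[[length(recs) + 1L]] <- data.frame(
        step_label = a$step_label, chain = st$chain,
        resno1 = st$resno1, resno2 = st$resno2, parameter = p,
        target = unname(cl$targets[[p]]), sigma = sg,
        period = if (is_distance_param(p)) NA_integer_ else 1L,
        atoms = paste(atoms, collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(step_label = character(), chain = character(),
               resno1 = integer(), resno2 = integer(), parameter = character(),
               target = numeric(), sigma = numeric(), period = integer(),
               atoms = character(), stringsAsFactors = FALSE)
  if (nrow(records)) {
    ord <- order(records$chain, records$resno1,
                 match(records$parameter, TORSION_PARAMS))
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records, global_weight = global_weight,
                 per_step_weights = per_step_weights,
                 library_version = lib$version, tighter = tighter),
            class = "ntc_restraint_set")
}

#' @export
print.ntc_restraint_set <- function(x, ...) {
  cat("ntc_restraint_set:", nrow(x$records), "records for",
      length(unique(x$records$step_label)), "steps (library",
      x$library_version, ")\n")
  invisible(x)
}

.render_header <- function(rs) {
  sprintf("# NtC restraints | library %s | global_weight %g%s",
          rs$library_version, rs$global_weight,
          if (isTRUE(rs$tighter)) " | tighter_sigmas" else "")
}

#' Render a restraint set to text
#'
#' @param rs an `ntc_restraint_set`.
#' @param dialect `"phenix_style"` (ntc_delete/ntc_change blocks) or
#'   `"refmac_style"` (external restraint lines).
#' @return character scalar; deterministic for a given set.
#' @export
render_restraints <- function(rs, dialect = c("phenix_style", "refmac_style")) {
  dialect <- match.arg(dialect)
  out <- .render_header(rs)
  r <- rs$records
  if (dialect == "phenix_style") {
    for (i in seq_len(nrow(r))) {
      rec <- r[i, ]
      out <- c(out,
               "ntc_delete {",
               paste0("  atoms = ", rec$atoms),
               "}",
               "ntc_change {",
               paste0("  step = ", rec$step_label),
               paste0("  parameter = ", rec$parameter),
               paste0("  atoms = ", rec$atoms),
               sprintf("  target = %.6f", rec$target),
               sprintf("  sigma = %.6f", rec$sigma),
               if (!is.na(rec$period)) sprintf("  period = %d", rec$period),
               "}")
    }
  } else {
    for (i in seq_len(nrow(r))) {
      rec <- r[i, ]
      refs <- strsplit(rec$atoms, " ", fixed = TRUE)[[1L]]
      key <- c("first", "next", "next", "next")
      if (is.na(rec$period)) key <- c("first", "second")
      sel <- paste(vapply(seq_along(refs), function(k) {
        f <- strsplit(refs[k], ":", fixed = TRUE)[[1L]]
        sprintf("%s chain %s resi %s atom %s", key[k], f[1L], f[2L], f[3L])
      }, character(1L)), collapse = " ")
      kind <- if (is.na(rec$period)) "exte dist" else "exte tors"
      tail <- if (is.na(rec$period))
        sprintf("value %.6f sigma %.6f", rec$target, rec$sigma)
      else
        sprintf("value %.6f sigma %.6f period %d", rec$target, rec$sigma, rec$period)
      out <- c(out, sprintf("%s %s %s ! step %s param %s",
                            kind, sel, tail, rec$step_label, rec$parameter))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Parse a rendered restraint file
#'
#' Inverse of [render_restraints()] on the supported subset; lines that are
#' not restraint directives are preserved in `attr(, "passthrough")`.
#'
#' @param text character scalar or vector of lines.
#' @param dialect dialect the text is written in.
#' @return an `ntc_restraint_set` (weights folded into sigmas).
#' @export
parse_restraints <- function(text, dialect = c("phenix_style", "refmac_style")) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  recs <- list()
  passthrough <- character()
  version <- "unknown"; gw <- 1
  hdr <- grep("^# NtC restraints \\| library ", lines)
  if (length(hdr)) {
    h <- lines[hdr[1L]]
    version <- sub("^.*library ([^ ]+) \\|.*$", "\\1", h)
    gw <- as.numeric(sub("^.*global_weight ([0-9.eE+-]+).*$", "\\1", h))
  }
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("line %d: malformed %s '%s'", ln, what, s))
    v
  }
  split_ref <- function(a) strsplit(a, ":", fixed = TRUE)[[1L]]
  if (dialect == "phenix_style") {
    i <- 1L
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "ntc_delete {") {
        while (i <= length(lines) && trimws(lines[i]) != "}") i <- i + 1L
        i <- i + 1L
      } else if (ln == "ntc_change {") {
        fields <- list(); j <- i + 1L
        while (j <= length(lines) && trimws(lines[j]) != "}") {
          kv <- trimws(lines[j])
          eq <- regexpr("=", kv, fixed = TRUE)
          if (eq < 0) stop(sprintf("line %d: malformed directive '%s'", j, kv))
          fields[[trimws(substr(kv, 1L, eq - 1L))]] <-
            trimws(substr(kv, eq + 1L, nchar(kv)))
          j <- j + 1L
        }
        refs <- strsplit(fields$atoms, " ", fixed = TRUE)[[1L]]
        f1 <- split_ref(refs[1L]); f2 <- split_ref(refs[length(refs)])
        recs[[length(recs) + 1L]] <- data.frame(
          step_label = fields$step %||% "", chain = f1[1L],
          resno1 = as.integer(f1[2L]), resno2 = as.integer(f2[2L]),
          parameter = fields$parameter,
          target = num(fields$target, "target", j),
          sigma = num(fields$sigma, "sigma", j),
          period = if (is.null(fields$period)) NA_integer_ else
            as.integer(fields$period),
          atoms = fields$atoms, stringsAsFactors = FALSE)
        i <- j + 1L
      } else {
        if (nzchar(ln) && !grepl("^# NtC restraints", ln))
          passthrough <- c(passthrough, lines[i])
        i <- i + 1L
      }
    }
  } else {
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (grepl("^exte (tors|dist) ", ln)) {
        toks <- strsplit(ln, "\\s+")[[1L]]
        grab <- function(key) {
          k <- which(toks == key)
          if (!length(k)) return(NULL)
          toks[k + 1L]
        }
        is_dist <- toks[2L] == "dist"
        kidx <- which(toks %in% c("first", "next", "second"))
        refs <- vapply(kidx, function(k)
          paste(toks[k + 2L], toks[k + 4L], toks[k + 6L], sep = ":"),
          character(1L))
        step <- grab("step") %||% ""
        recs[[length(recs) + 1L]] <- data.frame(
          step_label = step,
          chain = strsplit(refs[1L], ":", fixed = TRUE)[[1L]][1L],
          resno1 = as.integer(strsplit(refs[1L], ":", fixed = TRUE)[[1L]][2L]),
          resno2 = as.integer(strsplit(refs[length(refs)], ":", fixed = TRUE)[[1L]][2L]),
          parameter = grab("param") %||% NA_character_,
          target = num(grab("value"), "value", i),
          sigma = num(grab("sigma"), "sigma", i),
          period = if (is_dist) NA_integer_ else as.integer(grab("period")),
          atoms = paste(refs, collapse = " "), stringsAsFactors = FALSE)
      } else if (nzchar(ln) && !grepl("^# NtC restraints", ln)) {
        passthrough <- c(passthrough, lines[i])
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(step_label = character(), chain = character(),
               resno1 = integer(), resno2 = integer(), parameter = character(),
               target = numeric(), sigma = numeric(), period = integer(),
               atoms = character(), stringsAsFactors = FALSE)
  out <- structure(list(records = records, global_weight = gw,
                        per_step_weights = NULL, library_version = version,
                        tighter = FALSE),
                   class = "ntc_restraint_set")
  attr(out, "passthrough") <- passthrough
  out
}
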