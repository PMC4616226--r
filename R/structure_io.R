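# Column layout of PDB v3.3 ATOM/HETATM records (1-based, inclusive).
.pdb_cols <- list(
  record = c(1L, 6L), serial = c(7L, 11L), name = c(13L, 16L),
  altloc = c(17L, 17L), resname = c(18L, 21L), chain = c(22L, 22L),
  resid = c(23L, 26L), inscode = c(27L, 27L), x = c(31L, 38L),
  y = c(39L, 46L), z = c(47L, 54L), occupancy = c(55L, 60L),
  bfactor = c(61L, 66L), element = c(77L, 78L)
)

.substr_trim <- function(lines, span) {
  trimws(substr(lines, span[1], span[2]))
}

.missing_atom_error <- function(what, where) {
  stop(errorCondition(
    sprintf("missing atom %s in %s", what, where),
    class = c("lhc_missing_atom", "error")
  ))
}

#' Construct a structure model
#'
#' A `StructureModel` is an ordered table of atoms (one row per atom) with
#' chain/residue/atom identity and Cartesian coordinates in Angstrom. Atom
#' order is stable across all package operations.
#'
#' @param atoms data.frame with columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resid`, `inscode`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`.
#' @param model_id integer model number (frame index for multi-model files).
#' @param source provenance string (file name or generator tag).
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, model_id = 1L, source = "") {
  needed <- c("record", "serial", "name", "altloc", "resname", "chain",
              "resid", "inscode", "x", "y", "z", "occupancy", "bfactor",
              "element")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) {
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("a StructureModel must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 source = source),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<StructureModel> %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resid, a$inscode))),
              paste(sort(unique(a$chain)), collapse = " ")))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Coordinates of a structure model
#'
#' @param model a `StructureModel`.
#' @return numeric n x 3 matrix of positions (Angstrom), rows in atom order.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure model
#'
#' @param model a `StructureModel`.
#' @param xyz n x 3 matrix matching the model's atom count.
#' @return the updated `StructureModel`.
#' @export
set_coords <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(model$atoms) || ncol(xyz) != 3L) {
    stop("coordinate matrix must be n_atoms x 3")
  }
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

.parse_num <- function(txt, lineno, field) {
  out <- suppressWarnings(as.numeric(txt))
  bad <- is.na(out) & nzchar(txt)
  bad <- bad | !nzchar(txt)
  if (any(bad)) {
    stop(sprintf("malformed PDB record at line %d: unreadable %s field '%s'",
                 lineno[bad][1], field, txt[bad][1]))
  }
  out
}

# Keep the highest-occupancy alternate location per (chain, resid, inscode,
# resname, name); ties resolved in favour of the first record encountered.
.resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resid, atoms$inscode, atoms$resname,
               atoms$name, sep = "\r")
  occ <- ifelse(is.na(atoms$occupancy), 1, atoms$occupancy)
  ord <- seq_len(nrow(atoms))
  # order by key, then -occupancy, then original order: first row per key wins
  sel <- ord[order(key, -occ, ord)]
  keep <- sel[!duplicated(key[sel])]
  atoms[sort(keep), , drop = FALSE]
}

#' Parse a PDB-format structure
#'
#' Reads fixed-width ATOM/HETATM records (PDB v3.3). For multi-model files
#' `model_index` selects the model by position (1 = first MODEL block or the
#' whole file when no MODEL records are present). Alternate locations are
#' resolved to the highest-occupancy conformer (ties: first encountered).
#'
#' @param text PDB content: a single string or a character vector of lines.
#' @param model_index 1-based model number to extract.
#' @param source provenance label stored on the result.
#' @return a [structure_model()].
#' @export
parse_structure <- function(text, model_index = 1L, source = "") {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    trimws(rec) %in% c("ATOM", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  model_no <- cumsum(is_model)
  model_no[model_no == 0L] <- 1L
  pick <- is_atom & model_no == model_index
  if (!any(pick)) {
    stop(sprintf("no ATOM/HETATM records found for model %d", model_index))
  }
  ln <- which(pick)
  sel <- lines[pick]
  # pad short lines so substr is safe
  sel <- formatC(sel, width = -80)
  g <- function(f) .substr_trim(sel, .pdb_cols[[f]])
  occ <- suppressWarnings(as.numeric(g("occupancy")))
  bfac <- suppressWarnings(as.numeric(g("bfactor")))
  atoms <- data.frame(
    record = trimws(g("record")),
    serial = suppressWarnings(as.integer(g("serial"))),
    name = g("name"),
    altloc = g("altloc"),
    resname = g("resname"),
    chain = g("chain"),
    resid = suppressWarnings(as.integer(g("resid"))),
    inscode = g("inscode"),
    x = .parse_num(g("x"), ln, "x"),
    y = .parse_num(g("y"), ln, "y"),
    z = .parse_num(g("z"), ln, "z"),
    occupancy = ifelse(is.na(occ), 1, occ),
    bfactor = ifelse(is.na(bfac), 0, bfac),
    element = g("element"),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resid)) {
    stop(sprintf("malformed PDB record at line %d: unreadable residue number",
                 ln[which(is.na(atoms$resid))[1]]))
  }
  atoms <- .resolve_altloc(atoms)
  dup <- duplicated(paste(atoms$chain, atoms$resid, atoms$inscode,
                          atoms$name, sep = "\r"))
  if (any(dup)) {
    stop("duplicate atom identity after altloc resolution: ",
         paste(atoms$chain[dup][1], atoms$resid[dup][1], atoms$name[dup][1]))
  }
  structure_model(atoms, model_id = model_index, source = source)
}

#' Read a PDB file from disk
#'
#' @param path file path.
#' @param model_index model to extract (see [parse_structure()]).
#' @return a `StructureModel`.
#' @export
read_structure <- function(path, model_index = 1L) {
  parse_structure(readLines(path, warn = FALSE), model_index,
                  source = basename(path))
}

.fmt_atom_name <- function(name, element) {
  # Standard PDB alignment: element symbol in columns 13-14 for 1-2 char
  # elements; 4-char names fill the field.
  ifelse(nchar(name) >= 4L, substr(name, 1, 4),
         formatC(paste0(" ", name), width = -4))
}

#' Write a structure model as PDB-format text
#'
#' @param model a `StructureModel`.
#' @param path optional file path; when given, text is also written there.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
write_structure <- function(model, path = NULL) {
  a <- model$atoms
  if (any(abs(a$x) >= 10000 | abs(a$y) >= 10000 | abs(a$z) >= 10000)) {
    stop("coordinates exceed the PDB fixed field width (|v| < 10000 required)")
  }
  lines <- sprintf(
    "%-6s%5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, a$serial %% 100000L, .fmt_atom_name(a$name, a$element),
    a$altloc, a$resname, a$chain, a$resid %% 10000L, a$inscode,
    a$x, a$y, a$z, a$occupancy, a$bfactor, a$element
  )
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Construct a trajectory
#'
#' A `Trajectory` couples a topology (`StructureModel` carrying atom
#' identities) with an ordered list of coordinate snapshots and their times.
#'
#' @param topology a `StructureModel`.
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param times numeric vector of frame times in ns, strictly increasing;
#'   defaults to 0, 1, 2, ...
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "StructureModel"), length(frames) >= 1L)
  n <- nrow(topology$atoms)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3L) {
      stop("every frame must have the topology's atom count x 3 coordinates")
    }
    unname(f)
  })
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) {
    stop("times length must equal number of frames")
  }
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms, t = %g..%g ns\n",
              length(x$frames), nrow(x$topology$atoms),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a structure model
#'
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return a `StructureModel` with the frame's coordinates.
#' @export
frame_model <- function(traj, i) {
  m <- set_coords(traj$topology, traj$frames[[i]])
  m$model_id <- as.integer(i)
  m
}

#' Parse a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; atom identities are taken from
#' the first model and every model must contain the same atom count.
#'
#' @param text PDB content (string or lines) or, with `read_trajectory`, a path.
#' @param times optional frame times (ns); default 0, 1, 2, ...
#' @return a `Trajectory`.
#' @export
parse_trajectory <- function(text, times = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  nm <- max(1L, sum(startsWith(lines, "MODEL")))
  models <- lapply(seq_len(nm), function(i) parse_structure(lines, i))
  topo <- models[[1]]
  frames <- lapply(models, function(m) {
    if (nrow(m$atoms) != nrow(topo$atoms)) {
      stop("all models must contain the same atom count")
    }
    coords(m)
  })
  trajectory(topo, frames, times)
}

#' @rdname parse_trajectory
#' @param path file path of a multi-model PDB.
#' @export
read_trajectory <- function(path, times = NULL) {
  tr <- parse_trajectory(readLines(path, warn = FALSE), times)
  tr$topology$source <- basename(path)
  tr
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `Trajectory`.
#' @param path optional output path.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
write_trajectory <- function(traj, path = NULL) {
  out <- unlist(lapply(seq_along(traj$frames), function(i) {
    body <- write_structure(set_coords(traj$topology, traj$frames[[i]]))
    c(sprintf("MODEL     %4d", i), body[body != "END"], "ENDMDL")
  }))
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Atom selections
#'
#' Filters are AND-combined; `NULL` filters match everything. Residue ranges
#' are inclusive `(start, end)` pairs.
#'
#' @param chain character vector of chain ids, or NULL.
#' @param resid_ranges list of length-2 integer vectors, or NULL.
#' @param resname character vector of residue codes, or NULL.
#' @param name character vector of atom names, or NULL.
#' @return object of class `AtomSelection`.
#' @export
atom_selection <- function(chain = NULL, resid_ranges = NULL, resname = NULL,
                           name = NULL) {
  if (!is.null(resid_ranges)) {
    if (!is.list(resid_ranges)) resid_ranges <- list(resid_ranges)
    lapply(resid_ranges, function(r) stopifnot(length(r) == 2L, r[1] <= r[2]))
  }
  structure(list(chain = chain, resid_ranges = resid_ranges,
                 resname = resname, name = name),
            class = "AtomSelection")
}

#' Resolve a selection against a structure model
#'
#' @param model a `StructureModel`.
#' @param sel an [atom_selection()].
#' @return integer vector of atom indices in model order (possibly empty).
#' @export
resolve_selection <- function(model, sel) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resname)) keep <- keep & a$resname %in% sel$resname
  if (!is.null(sel$name)) keep <- keep & a$name %in% sel$name
  if (!is.null(sel$resid_ranges)) {
    inr <- rep(FALSE, nrow(a))
    for (r in sel$resid_ranges) inr <- inr | (a$resid >= r[1] & a$resid <= r[2])
    keep <- keep & inr
  }
  which(keep)
}

#' Domain definition
#'
#' Named residue-range set used for per-domain RMSD. Ranges must not overlap
#' within one domain.
#'
#' @param name domain label (e.g. "N-terminus").
#' @param residue_ranges list of inclusive `(start, end)` pairs.
#' @param chain optional chain restriction.
#' @return object of class `DomainDefinition`.
#' @export
domain_definition <- function(name, residue_ranges, chain = NULL) {
  if (!is.list(residue_ranges)) residue_ranges <- list(residue_ranges)
  m <- do.call(rbind, residue_ranges)
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2])) {
    stop("residue ranges overlap within domain '", name, "'")
  }
  structure(list(name = name, residue_ranges = residue_ranges, chain = chain),
            class = "DomainDefinition")
}

#' Rigid-body superposition (Kabsch)
#'
#' Finds the least-squares optimal proper rotation + translation mapping the
#' mobile fit atoms onto the reference fit atoms (no reflection), applies it
#' to all mobile atoms, and reports the post-fit RMSD over the fit atoms.
#'
#' @param mobile n x 3 coordinate matrix (or `StructureModel`).
#' @param reference n x 3 coordinate matrix (or `StructureModel`) with the
#'   same atom count.
#' @param fit_indices indices of atoms used to compute the transform
#'   (default: all atoms). At least 3 non-collinear atoms are required.
#' @return list with `coords` (all mobile atoms transformed) and `rmsd_fit`
#'   (Angstrom, over the fit atoms).
#' @export
superpose <- function(mobile, reference, fit_indices = NULL) {
  if (inherits(mobile, "StructureModel")) mobile <- coords(mobile)
  if (inherits(reference, "StructureModel")) reference <- coords(reference)
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference must have the same atom count")
  }
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3L) stop("need at least 3 fit atoms")
  for (m in list(reference[fit_indices, , drop = FALSE],
                 mobile[fit_indices, , drop = FALSE])) {
    sv <- svd(scale(m, center = TRUE, scale = FALSE))$d
    if (sv[2] <= 1e-8 * max(sv[1], 1)) {
      stop("fit atoms are collinear; superposition is degenerate")
    }
  }
  xyz_ind <- as.vector(t(cbind((fit_indices - 1) * 3 + 1,
                               (fit_indices - 1) * 3 + 2,
                               (fit_indices - 1) * 3 + 3)))
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(reference)),
                           mobile = as.vector(t(mobile)),
                           fixed.inds = xyz_ind, mobile.inds = xyz_ind)
  out <- matrix(fitted, ncol = 3, byrow = TRUE)
  d <- out[fit_indices, , drop = FALSE] - reference[fit_indices, , drop = FALSE]
  list(coords = out, rmsd_fit = sqrt(mean(rowSums(d^2))))
}
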