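#' Transition dipole constructor
#'
#' @param center 3-vector, Angstrom.
#' @param direction 3-vector; normalised internally, must be non-zero.
#' @param magnitude_debye dipole magnitude in Debye (>= 0).
#' @return object of class `TransitionDipole`.
#' @export
transition_dipole <- function(center, direction, magnitude_debye) {
  center <- as.numeric(center); direction <- as.numeric(direction)
  stopifnot(length(center) == 3L, length(direction) == 3L,
            all(is.finite(center)), all(is.finite(direction)),
            magnitude_debye >= 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("dipole direction vector has zero length")
  structure(list(center = center, direction = direction / nrm,
                 magnitude_debye = as.numeric(magnitude_debye)),
            class = "TransitionDipole")
}

#' @export
print.TransitionDipole <- function(x, ...) {
  cat(sprintf(
    "<TransitionDipole> %.2f D along (%.3f, %.3f, %.3f) at (%.2f, %.2f, %.2f) A\n",
    x$magnitude_debye, x$direction[1], x$direction[2], x$direction[3],
    x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Chlorophyll Qy transition dipole
#'
#' The Qy axis is taken along the vector from the axis-tail to the axis-head
#' nitrogen (default NB -> ND in PDB chlorophyll nomenclature), centered on
#' the Mg atom by default; both are configurable per registry entry or via
#' the arguments. The magnitude comes from the registry (dipole magnitudes
#' and geometry are independent).
#'
#' @param p a `PigmentInstance` of class chl_a or chl_b.
#' @param axis_atoms optional override of the (tail, head) atom pair.
#' @param center_atom optional override of the center atom; `"midpoint"`
#'   uses the midpoint of the axis atoms.
#' @return a [transition_dipole()].
#' @export
chl_qy_dipole <- function(p, axis_atoms = NULL, center_atom = NULL) {
  if (!p$registry$pigment_class %in% c("chl_a", "chl_b")) {
    stop("chl_qy_dipole requires a chlorophyll pigment")
  }
  axis_atoms <- axis_atoms %||% p$registry$axis_atoms
  center_atom <- center_atom %||% p$registry$center_atom
  where <- sprintf("%s %s/%s", p$pigment_id$resname, p$pigment_id$chain,
                   p$pigment_id$resid)
  for (nm in axis_atoms) {
    if (!nm %in% rownames(p$atom_map)) .missing_atom_error(nm, where)
  }
  tail_pos <- p$atom_map[axis_atoms[1], ]
  head_pos <- p$atom_map[axis_atoms[2], ]
  center <- if (identical(center_atom, "midpoint")) {
    (tail_pos + head_pos) / 2
  } else {
    if (!center_atom %in% rownames(p$atom_map)) {
      .missing_atom_error(center_atom, where)
    }
    p$atom_map[center_atom, ]
  }
  transition_dipole(center, head_pos - tail_pos, p$registry$magnitude_debye)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Carotenoid S2 transition dipole
#'
#' The S2 <- S0 dipole lies along the conjugated polyene backbone. The
#' direction is the dominant principal axis (largest-variance eigenvector of
#' the position covariance) of the central portion of the registry's ordered
#' chain-atom list, signed from the first toward the last listed atom; the
#' center is the centroid of those central atoms. Using only the central
#' portion makes the axis insensitive to bending of the chain ends.
#'
#' @param p a `PigmentInstance` of class carotenoid.
#' @param central_fraction fraction of the chain-atom list, centered on its
#'   middle, used for the axis (default 0.5).
#' @return a [transition_dipole()].
#' @export
car_s2_dipole <- function(p, central_fraction = 0.5) {
  if (p$registry$pigment_class != "carotenoid") {
    stop("car_s2_dipole requires a carotenoid pigment")
  }
  stopifnot(central_fraction > 0, central_fraction <= 1)
  chain <- p$registry$chain_atoms
  n <- length(chain)
  keep <- max(2L, round(n * central_fraction))
  lo <- floor((n - keep) / 2) + 1L
  atoms <- chain[lo:(lo + keep - 1L)]
  where <- sprintf("%s %s/%s", p$pigment_id$resname, p$pigment_id$chain,
                   p$pigment_id$resid)
  absent <- setdiff(atoms, rownames(p$atom_map))
  if (length(absent)) .missing_atom_error(paste(absent, collapse = ", "), where)
  xyz <- p$atom_map[atoms, , drop = FALSE]
  if (nrow(xyz) < 2L) stop("need at least 2 central-chain atoms")
  centered <- scale(xyz, center = TRUE, scale = FALSE)
  if (max(abs(centered)) < 1e-9) stop("central-chain atoms are coincident")
  ev <- eigen(crossprod(centered) / nrow(xyz), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  # sign: along the listed atom order, first -> last
  span <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  transition_dipole(colMeans(xyz), dir, p$registry$magnitude_debye)
}

#' Transition dipole of any registered chromophore
#'
#' Dispatches to [chl_qy_dipole()] or [car_s2_dipole()] by pigment class.
#'
#' @param p a `PigmentInstance`.
#' @param ... passed to the class-specific function.
#' @return a [transition_dipole()].
#' @export
pigment_dipole <- function(p, ...) {
  switch(p$registry$pigment_class,
         chl_a = chl_qy_dipole(p, ...),
         chl_b = chl_qy_dipole(p, ...),
         carotenoid = car_s2_dipole(p, ...),
         stop("pigment class '", p$registry$pigment_class,
              "' has no transition dipole"))
}
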