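#' Protein reference axis
#'
#' The membrane-normal reference against which carotenoid tilt angles are
#' measured; in a light-harvesting complex this is the protein's
#' pseudo-two-fold symmetry axis.
#'
#' @param direction 3-vector, normalised internally.
#' @param definition how the axis was obtained.
#' @return object of class `ProteinAxis`.
#' @export
protein_axis_vector <- function(direction,
                                definition = c("inertia_principal",
                                               "lab_z_after_alignment")) {
  definition <- match.arg(definition)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("axis direction has zero length")
  structure(list(direction = direction / nrm, definition = definition),
            class = "ProteinAxis")
}

#' Estimate the protein axis from a structure
#'
#' `inertia_principal` mode takes the smallest-inertia principal axis (the
#' long axis, i.e. the largest-variance eigenvector) of the selected
#' backbone atoms - for a transmembrane helix bundle this is the membrane
#' normal. The sign is chosen so the axis points from the atom centroid
#' toward `orient_point` when given (e.g. a stromal-side residue), otherwise
#' toward +z. `lab_z_after_alignment` mode simply returns (0, 0, 1) for use
#' after frames have been superposed onto an axis-aligned reference.
#'
#' @param model a `StructureModel`.
#' @param selection an [atom_selection()] of backbone atoms (>= 3, not
#'   collinear in a degenerate way); default: all CA atoms.
#' @param mode axis definition.
#' @param orient_point optional 3-vector fixing the axis sign.
#' @return a `ProteinAxis`.
#' @export
protein_axis <- function(model,
                         selection = atom_selection(name = "CA"),
                         mode = c("inertia_principal",
                                  "lab_z_after_alignment"),
                         orient_point = NULL) {
  mode <- match.arg(mode)
  if (mode == "lab_z_after_alignment") {
    return(protein_axis_vector(c(0, 0, 1), "lab_z_after_alignment"))
  }
  idx <- resolve_selection(model, selection)
  if (length(idx) < 3L) stop("need at least 3 selected atoms for the axis")
  xyz <- coords(model)[idx, , drop = FALSE]
  centered <- scale(xyz, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(centered) / nrow(xyz), symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) <= 1e-6 * max(ev$values[1], 1e-12)) {
    stop("degenerate inertia tensor: leading principal axes are not separated")
  }
  dir <- ev$vectors[, 1]
  ref <- if (is.null(orient_point)) {
    c(0, 0, 1)
  } else {
    as.numeric(orient_point) - colMeans(xyz)
  }
  if (sum(dir * ref) < 0) dir <- -dir
  protein_axis_vector(dir, "inertia_principal")
}

#' Tilt angle of a transition dipole against the protein axis
#'
#' theta = arccos(|d_hat . axis_hat|), folded to [0, 90] degrees because the
#' transition-dipole sign is unphysical.
#'
#' @param d a [transition_dipole()].
#' @param axis a `ProteinAxis`.
#' @return angle in degrees in [0, 90].
#' @export
tilt_angle <- function(d, axis) {
  ct <- abs(sum(d$direction * axis$direction))
  acos(min(1, ct)) * 180 / pi
}

#' Per-frame carotenoid (or chlorophyll) tilt-angle series
#'
#' @param traj a `Trajectory`.
#' @param pigment pigment id ("A/620" form) or list(chain, resid).
#' @param axis a fixed `ProteinAxis`, or NULL to recompute per frame from
#'   `axis_selection`.
#' @param registry pigment registry.
#' @param axis_selection backbone selection for per-frame axis recomputation.
#' @param ... passed to the dipole function (e.g. `central_fraction`).
#' @return data.frame with columns `frame`, `time_ns`, `angle_deg`.
#' @export
tilt_angle_series <- function(traj, pigment, axis = NULL,
                              registry = default_registry(),
                              axis_selection = atom_selection(name = "CA"),
                              ...) {
  id <- .parse_pair_id(pigment)
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ns = traj$times,
                    angle_deg = NA_real_)
  for (f in seq_len(n_frames(traj))) {
    model <- frame_model(traj, f)
    ax <- if (is.null(axis)) protein_axis(model, axis_selection) else axis
    p <- pigment_instance(model, id$chain, id$resid, registry)
    out$angle_deg[f] <- tilt_angle(pigment_dipole(p, ...), ax)
  }
  out
}

#' Per-atom B-factors from a trajectory
#'
#' Frames are superposed over `fit_selection` (first onto frame 1, then the
#' mean structure is computed and all frames are refit onto it - one
#' refinement pass), after which
#' B_i = (8 pi^2 / 3) <|r_i - <r_i>|^2> in Angstrom^2. The superposition
#' removes global rigid-body motion so B reports internal fluctuation only.
#'
#' @param traj a `Trajectory` with >= 2 frames.
#' @param selection atoms to report (default: all).
#' @param fit_selection atoms used for the superposition (default:
#'   `selection`).
#' @return data.frame with columns `index` (atom index in the topology) and
#'   `bfactor` (Angstrom^2).
#' @export
per_atom_bfactor <- function(traj, selection = NULL, fit_selection = NULL) {
  if (n_frames(traj) < 2L) stop("B-factors need at least 2 frames")
  all_idx <- seq_len(nrow(traj$topology$atoms))
  sel <- if (is.null(selection)) all_idx
         else resolve_selection(traj$topology, selection)
  fit <- if (is.null(fit_selection)) sel
         else resolve_selection(traj$topology, fit_selection)
  fitted <- lapply(traj$frames, function(fr) {
    superpose(fr, traj$frames[[1]], fit)$coords
  })
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  refit <- lapply(traj$frames, function(fr) {
    superpose(fr, mean_xyz, fit)$coords
  })
  mean_xyz <- Reduce(`+`, refit) / length(refit)
  msd <- Reduce(`+`, lapply(refit, function(fr) {
    rowSums((fr - mean_xyz)^2)
  })) / length(refit)
  data.frame(index = sel, bfactor = (8 * pi^2 / 3) * msd[sel])
}

.backbone_names <- c("N", "CA", "C", "O")

.domain_indices <- function(model, domain, atom_names = .backbone_names) {
  sel <- atom_selection(chain = domain$chain,
                        resid_ranges = domain$residue_ranges,
                        name = atom_names)
  idx <- resolve_selection(model, sel)
  if (!length(idx)) {
    .missing_atom_error(paste(atom_names, collapse = "/"),
                        paste("domain", domain$name))
  }
  idx
}

#' Per-domain RMSD time series
#'
#' Each frame is superposed onto the reference over `fit_selection` (by
#' default the caller should pass the transmembrane-helix backbone, so that
#' peripheral-domain RMSD reports genuine displacement rather than fitting
#' artefact), then the RMSD is computed over the domain's backbone atoms
#' without refitting on the domain.
#'
#' @param traj a `Trajectory`.
#' @param reference a `StructureModel` with the same atom set.
#' @param domain a [domain_definition()].
#' @param fit_selection an [atom_selection()] for the superposition;
#'   default: all CA atoms.
#' @param atom_names atom names constituting the domain's backbone.
#' @return data.frame with columns `frame`, `time_ns`, `rmsd_A`.
#' @export
domain_rmsd_series <- function(traj, reference, domain,
                               fit_selection = atom_selection(name = "CA"),
                               atom_names = .backbone_names) {
  fit <- resolve_selection(reference, fit_selection)
  if (length(fit) < 3L) stop("need at least 3 fit atoms")
  dom <- .domain_indices(reference, domain, atom_names)
  ref_xyz <- coords(reference)
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ns = traj$times,
                    rmsd_A = NA_real_)
  for (f in seq_len(n_frames(traj))) {
    fitted <- superpose(traj$frames[[f]], ref_xyz, fit)$coords
    d <- fitted[dom, , drop = FALSE] - ref_xyz[dom, , drop = FALSE]
    out$rmsd_A[f] <- sqrt(mean(rowSums(d^2)))
  }
  out
}

# Rough atomic masses for mass-weighted centroids.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, MG = 24.305, FE = 55.845)

.centroid <- function(xyz, elements, mass_weighting) {
  if (!mass_weighting) return(colMeans(xyz))
  m <- .atomic_masses[toupper(elements)]
  m[is.na(m)] <- 12.011
  colSums(xyz * m) / sum(m)
}

#' Centroid-centroid distance time series
#'
#' Per-frame Euclidean distance between the (optionally mass-weighted)
#' centroids of two selections, e.g. the N-terminus backbone and a lipid
#' ligand.
#'
#' @param traj a `Trajectory`.
#' @param selA,selB non-empty [atom_selection()]s.
#' @param mass_weighting use atomic masses (default FALSE: geometric).
#' @return data.frame with columns `frame`, `time_ns`, `distance_A`.
#' @export
com_distance_series <- function(traj, selA, selB, mass_weighting = FALSE) {
  ia <- resolve_selection(traj$topology, selA)
  ib <- resolve_selection(traj$topology, selB)
  if (!length(ia) || !length(ib)) stop("empty selection for centroid distance")
  ea <- traj$topology$atoms$element[ia]
  eb <- traj$topology$atoms$element[ib]
  d <- vapply(traj$frames, function(fr) {
    ca <- .centroid(fr[ia, , drop = FALSE], ea, mass_weighting)
    cb <- .centroid(fr[ib, , drop = FALSE], eb, mass_weighting)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_ns = traj$times,
             distance_A = d)
}

#' Hydrogen-bond specification
#'
#' Geometric criterion: donor-acceptor distance <= `d_cut` and, when a
#' hydrogen atom is given, the hydrogen-donor-acceptor angle (at the donor,
#' between donor->H and donor->acceptor) <= `angle_cut`.
#'
#' @param donor,acceptor atom ids: "chain/resid/name" strings or
#'   list(chain, resid, name).
#' @param hydrogen optional hydrogen atom id.
#' @param d_cut distance cutoff in Angstrom (default 3.5).
#' @param angle_cut angle cutoff in degrees, in (0, 90] (default 30).
#' @return object of class `HBondSpec`.
#' @export
hbond_spec <- function(donor, acceptor, hydrogen = NULL,
                       d_cut = 3.5, angle_cut = 30) {
  stopifnot(d_cut > 0, angle_cut > 0, angle_cut <= 90)
  structure(list(donor = .parse_atom_id(donor),
                 acceptor = .parse_atom_id(acceptor),
                 hydrogen = if (is.null(hydrogen)) NULL
                            else .parse_atom_id(hydrogen),
                 d_cut = d_cut, angle_cut = angle_cut),
            class = "HBondSpec")
}

.parse_atom_id <- function(id) {
  if (is.character(id)) {
    parts <- strsplit(id, "/", fixed = TRUE)[[1]]
    if (length(parts) != 3L) stop("atom id must look like 'A/131/OE1'")
    list(chain = parts[1], resid = as.integer(parts[2]), name = parts[3])
  } else {
    id
  }
}

.atom_index <- function(model, id) {
  a <- model$atoms
  i <- which(a$chain == id$chain & a$resid == id$resid & a$name == id$name)
  if (!length(i)) {
    .missing_atom_error(sprintf("%s/%s/%s", id$chain, id$resid, id$name),
                        "hydrogen-bond specification")
  }
  i[1]
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' @param traj a `Trajectory`.
#' @param spec an [hbond_spec()].
#' @return list with `occupancy` (fraction of frames in [0, 1]) and
#'   `present` (per-frame logical vector).
#' @export
hbond_occupancy <- function(traj, spec) {
  topo <- traj$topology
  id <- .atom_index(topo, spec$donor)
  ia <- .atom_index(topo, spec$acceptor)
  ih <- if (is.null(spec$hydrogen)) NA_integer_
        else .atom_index(topo, spec$hydrogen)
  present <- vapply(traj$frames, function(fr) {
    dvec <- fr[ia, ] - fr[id, ]
    dist_ok <- sqrt(sum(dvec^2)) <= spec$d_cut
    if (!dist_ok || is.na(ih)) return(dist_ok)
    hvec <- fr[ih, ] - fr[id, ]
    ct <- sum(hvec * dvec) / sqrt(sum(hvec^2) * sum(dvec^2))
    ang <- acos(max(-1, min(1, ct))) * 180 / pi
    ang <= spec$angle_cut
  }, logical(1))
  list(occupancy = mean(present), present = present)
}
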