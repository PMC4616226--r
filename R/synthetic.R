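# Idealized template geometry: Mg-N 2.05 A, polyene C-C 1.35 A defaults.
# Ground truth must stay analytic, so templates are built from these
# constants, never from crystallographic coordinates.

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- as.numeric(axis); u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

.check_rotation <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8) {
    stop("orientation must be a 3x3 orthogonal matrix")
  }
  if (det(R) < 0) stop("orientation is an improper rotation (det = -1)")
  R
}

.instance_from_template <- function(template, position, orientation,
                                    entry, chain, resid, resname) {
  R <- .check_rotation(orientation)
  xyz <- t(R %*% t(template)) +
    matrix(as.numeric(position), nrow(template), 3, byrow = TRUE)
  rownames(xyz) <- rownames(template)
  structure(list(pigment_id = list(chain = chain, resid = as.integer(resid),
                                   resname = resname),
                 atom_map = xyz, registry = entry),
            class = "PigmentInstance")
}

#' Synthetic chlorin ring
#'
#' Idealized planar chlorophyll head group: Mg at the given position and the
#' four pyrrole nitrogens at +/- 2.05 A on the in-plane template axes, with
#' the Qy axis (NB -> ND) along template x. The chl_b variant adds the
#' formyl oxygen at a fixed template site; chl_a has none.
#'
#' @param position Mg position (3-vector, Angstrom).
#' @param orientation 3 x 3 proper rotation applied to the template
#'   (improper rotations are rejected).
#' @param variant "chl_a" or "chl_b".
#' @param chain,resid identity given to the pigment.
#' @param mg_n Mg-N distance in Angstrom (default 2.05).
#' @param registry registry supplying the matching entry (default
#'   [default_registry()]).
#' @return a `PigmentInstance`.
#' @export
make_chlorin <- function(position = c(0, 0, 0), orientation = diag(3),
                         variant = c("chl_a", "chl_b"),
                         chain = "X", resid = 1L, mg_n = 2.05,
                         registry = default_registry()) {
  variant <- match.arg(variant)
  template <- rbind(
    MG = c(0, 0, 0),
    `NA` = c(0, mg_n, 0),
    NB = c(-mg_n, 0, 0),
    NC = c(0, -mg_n, 0),
    ND = c(mg_n, 0, 0)
  )
  if (variant == "chl_b") {
    template <- rbind(template, OBD = c(0, 3.2, 0))
  }
  entry <- registry[[variant]]
  .instance_from_template(template, position, orientation, entry,
                          chain, resid, entry$resnames[1])
}

#' Synthetic polyene chain
#'
#' Planar zigzag carbon chain (atoms C1..Cn) with its long axis along
#' template x, emulating a carotenoid conjugated backbone. An optional kink
#' bends the part of the chain after `kink_at` by `kink_deg` in the chain
#' plane, emulating distortion of the chain portion protruding from the
#' protein.
#'
#' @param position centroid position of the chain (3-vector, Angstrom).
#' @param orientation 3 x 3 proper rotation applied to the template.
#' @param n_atoms number of chain carbons (>= 4).
#' @param bond_length C-C bond length in Angstrom (default 1.35).
#' @param bond_angle zigzag bond angle in degrees (default 120).
#' @param kink_deg in-plane bend applied after `kink_at` (default 0).
#' @param kink_at atom index at which the bend starts (default: midpoint).
#' @param chain,resid,resname identity given to the pigment.
#' @param magnitude_debye S2 dipole magnitude for the registry entry.
#' @return a `PigmentInstance` whose registry entry lists C1..Cn as the
#'   conjugated chain.
#' @export
make_polyene <- function(position = c(0, 0, 0), orientation = diag(3),
                         n_atoms = 20L, bond_length = 1.35,
                         bond_angle = 120, kink_deg = 0, kink_at = NULL,
                         chain = "X", resid = 1L, resname = "NEX",
                         magnitude_debye = 13.0) {
  if (n_atoms < 4L) stop("a polyene needs at least 4 chain atoms")
  if (bond_length <= 0 || bond_angle <= 0 || bond_angle >= 180) {
    stop("invalid polyene geometry parameters")
  }
  half <- (bond_angle / 2) * pi / 180
  dx <- bond_length * sin(half)
  dy <- bond_length * cos(half)
  i <- seq_len(n_atoms) - 1L
  xyz <- cbind(i * dx, rep(c(0, dy), length.out = n_atoms), 0)
  if (kink_deg != 0) {
    if (is.null(kink_at)) kink_at <- floor(n_atoms / 2)
    if (kink_at < 2L || kink_at >= n_atoms) stop("kink_at out of range")
    pivot <- xyz[kink_at, ]
    Rk <- rotation_matrix(c(0, 0, 1), kink_deg)
    after <- (kink_at + 1L):n_atoms
    xyz[after, ] <- t(Rk %*% (t(xyz[after, , drop = FALSE]) - pivot)) +
      matrix(pivot, length(after), 3, byrow = TRUE)
  }
  xyz <- scale(xyz, center = TRUE, scale = FALSE)  # centroid at origin
  rownames(xyz) <- paste0("C", seq_len(n_atoms))
  entry <- registry_entry(resname, "carotenoid",
                          chain_atoms = paste0("C", seq_len(n_atoms)),
                          magnitude_debye = magnitude_debye)
  .instance_from_template(xyz, position, orientation, entry,
                          chain, resid, resname)
}

.element_from_name <- function(name) {
  e <- toupper(substr(name, 1, 2))
  ifelse(e %in% c("MG", "FE", "CL"), e, substr(gsub("[0-9']", "", name), 1, 1))
}

.atoms_df <- function(record, name, resname, chain, resid, xyz,
                      element = .element_from_name(name)) {
  data.frame(record = record, serial = NA_integer_, name = name,
             altloc = "", resname = resname, chain = chain,
             resid = as.integer(resid), inscode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bfactor = 0, element = element,
             stringsAsFactors = FALSE)
}

.pigment_atoms <- function(p) {
  .atoms_df("HETATM", rownames(p$atom_map), p$pigment_id$resname,
            p$pigment_id$chain, p$pigment_id$resid, p$atom_map)
}

#' Synthetic transmembrane helix bundle
#'
#' CA-only alpha-helical scaffold: `n_helices` ideal helices running along
#' the template z axis, arranged on a circle of radius `bundle_radius`.
#' Residues are numbered consecutively from `start_resid`.
#'
#' @param n_helices number of helices (default 3).
#' @param res_per_helix residues per helix (default 30).
#' @param start_resid first residue number (default 14, matching
#'   author-style numbering that does not start at 1).
#' @param chain chain id.
#' @param rise helical rise per residue, Angstrom (default 1.5).
#' @param twist_deg helical twist per residue, degrees (default 100).
#' @param helix_radius CA helix radius, Angstrom (default 2.3).
#' @param bundle_radius distance of each helix axis from the bundle center.
#' @param orientation 3 x 3 proper rotation applied to the whole bundle.
#' @param position bundle centroid translation.
#' @return data.frame of ATOM rows (internal atom-table format).
#' @export
make_helix_bundle <- function(n_helices = 3L, res_per_helix = 30L,
                              start_resid = 14L, chain = "A", rise = 1.5,
                              twist_deg = 100, helix_radius = 2.3,
                              bundle_radius = 8, orientation = diag(3),
                              position = c(0, 0, 0)) {
  R <- .check_rotation(orientation)
  rows <- list()
  resid <- start_resid
  for (h in seq_len(n_helices)) {
    phi <- 2 * pi * (h - 1) / n_helices
    center <- c(bundle_radius * cos(phi), bundle_radius * sin(phi), 0)
    i <- seq_len(res_per_helix) - 1L
    th <- i * twist_deg * pi / 180
    xyz <- cbind(center[1] + helix_radius * cos(th),
                 center[2] + helix_radius * sin(th),
                 center[3] + i * rise - (res_per_helix - 1) * rise / 2)
    rows[[h]] <- .atoms_df("ATOM", rep("CA", res_per_helix), "ALA", chain,
                           resid + i, xyz, element = "C")
    resid <- resid + res_per_helix
  }
  atoms <- do.call(rbind, rows)
  xyz <- t(R %*% t(as.matrix(atoms[, c("x", "y", "z")]))) +
    matrix(as.numeric(position), nrow(atoms), 3, byrow = TRUE)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Assemble a synthetic pigment-protein complex
#'
#' Combines a helix-bundle scaffold, a list of pigment instances (from
#' [make_chlorin()] / [make_polyene()]) and optional extra atoms into one
#' `StructureModel`, and collects the pigments' registry entries.
#'
#' @param protein data.frame from [make_helix_bundle()], or NULL.
#' @param pigments list of `PigmentInstance` objects.
#' @param extra_atoms optional additional atom rows (internal atom-table
#'   format), e.g. ad-hoc hydrogen-bond partners.
#' @param source provenance label.
#' @return list with `model` (`StructureModel`) and `registry` (named list
#'   of the entries used, synthetic polyene entries included).
#' @export
make_complex <- function(protein = NULL, pigments = list(),
                         extra_atoms = NULL, source = "synthetic complex") {
  parts <- list()
  if (!is.null(protein)) parts <- c(parts, list(protein))
  parts <- c(parts, lapply(pigments, .pigment_atoms))
  if (!is.null(extra_atoms)) parts <- c(parts, list(extra_atoms))
  if (!length(parts)) stop("empty complex")
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  registry <- default_registry()
  for (p in pigments) {
    key <- p$pigment_id$resname
    # a pigment's own entry wins over any default claiming the same code
    registry <- lapply(registry, function(e) {
      e$resnames <- setdiff(e$resnames, key)
      e
    })
    registry <- registry[vapply(registry, function(e) length(e$resnames) > 0,
                                logical(1))]
    registry[[key]] <- p$registry
  }
  list(model = structure_model(atoms, source = source), registry = registry)
}

#' Trajectory schedules
#'
#' Deterministic per-frame rigid motions applied by [make_trajectory()].
#' `schedule_rotation` rotates the selected atoms about `axis` through
#' `pivot` (default: the selection's initial centroid) by `angles_deg[f]`
#' relative to the initial coordinates. `schedule_translation` adds
#' `offsets[f, ]`. `schedule_positions` pins one atom to absolute
#' per-frame positions (e.g. to toggle a hydrogen-bond partner across its
#' cutoff).
#'
#' @param selection an [atom_selection()] (or integer indices).
#' @param angles_deg numeric vector, one angle per frame.
#' @param axis rotation axis.
#' @param pivot rotation pivot, or NULL for the selection centroid.
#' @return a schedule object for [make_trajectory()].
#' @export
schedule_rotation <- function(selection, angles_deg, axis = c(0, 1, 0),
                              pivot = NULL) {
  structure(list(type = "rotation", selection = selection,
                 angles_deg = angles_deg, axis = axis, pivot = pivot),
            class = "lhc_schedule")
}

#' @rdname schedule_rotation
#' @param offsets n_frames x 3 matrix of displacements (Angstrom).
#' @export
schedule_translation <- function(selection, offsets) {
  structure(list(type = "translation", selection = selection,
                 offsets = as.matrix(offsets)),
            class = "lhc_schedule")
}

#' @rdname schedule_rotation
#' @param atom_id "chain/resid/name" atom id.
#' @param positions n_frames x 3 matrix of absolute positions.
#' @export
schedule_positions <- function(atom_id, positions) {
  structure(list(type = "positions", atom_id = .parse_atom_id(atom_id),
                 positions = as.matrix(positions)),
            class = "lhc_schedule")
}

.schedule_len <- function(s) {
  switch(s$type, rotation = length(s$angles_deg),
         translation = nrow(s$offsets), positions = nrow(s$positions))
}

.schedule_indices <- function(s, model) {
  if (s$type == "positions") return(.atom_index(model, s$atom_id))
  if (inherits(s$selection, "AtomSelection")) {
    resolve_selection(model, s$selection)
  } else {
    as.integer(s$selection)
  }
}

#' Generate a synthetic trajectory with known ground truth
#'
#' For each frame the scheduled rigid motions are applied to the base
#' coordinates, then i.i.d. Gaussian noise of standard deviation
#' `noise_sigma` is added to every coordinate. All randomness comes from
#' one explicit seed through R's Mersenne-Twister / inversion generators;
#' the caller's RNG state is left untouched.
#'
#' @param base a `StructureModel` (e.g. from [make_complex()]).
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma per-coordinate Gaussian noise, Angstrom (default 0).
#' @param schedules list of schedule objects (see [schedule_rotation()]);
#'   every schedule's length must equal `n_frames`.
#' @param seed integer random seed (required).
#' @param dt_ns frame spacing in ns (default 1).
#' @return list with `trajectory` (a `Trajectory`) and `truth` (the seed,
#'   noise level and schedules: the record that determines every expected
#'   analysis output).
#' @export
make_trajectory <- function(base, n_frames, noise_sigma = 0,
                            schedules = list(), seed, dt_ns = 1) {
  stopifnot(inherits(base, "StructureModel"), n_frames >= 2L)
  if (missing(seed)) stop("an explicit seed is required")
  for (s in schedules) {
    if (!inherits(s, "lhc_schedule")) stop("schedules must be schedule objects")
    if (.schedule_len(s) != n_frames) {
      stop("schedule length (", .schedule_len(s), ") != n_frames (",
           n_frames, ")")
    }
  }
  idx_list <- lapply(schedules, .schedule_indices, model = base)
  x0 <- coords(base)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- x0
    for (k in seq_along(schedules)) {
      s <- schedules[[k]]; idx <- idx_list[[k]]
      if (s$type == "rotation") {
        pivot <- if (is.null(s$pivot)) colMeans(x0[idx, , drop = FALSE])
                 else as.numeric(s$pivot)
        R <- rotation_matrix(s$axis, s$angles_deg[f])
        xyz[idx, ] <- t(R %*% (t(x0[idx, , drop = FALSE]) - pivot)) +
          matrix(pivot, length(idx), 3, byrow = TRUE)
      } else if (s$type == "translation") {
        xyz[idx, ] <- xyz[idx, , drop = FALSE] +
          matrix(s$offsets[f, ], length(idx), 3, byrow = TRUE)
      } else {
        xyz[idx, ] <- s$positions[f, ]
      }
    }
    if (noise_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                          nrow(xyz), 3)
    }
    frames[[f]] <- xyz
  }
  truth <- list(seed = seed, noise_sigma = noise_sigma,
                schedules = schedules, n_frames = n_frames, dt_ns = dt_ns,
                rng = "Mersenne-Twister/Inversion")
  list(trajectory = trajectory(base, frames,
                               times = (seq_len(n_frames) - 1) * dt_ns),
       truth = truth)
}

#' Synthetic correlated per-simulation ensemble
#'
#' Emulates an ensemble of per-simulation (delta_x, delta_E) points with a
#' known linear relation: delta_x ~ Uniform(x_range), delta_E =
#' slope * delta_x + N(0, noise_sd). The default ensemble size is 6
#' (six independent simulations); the default noise is 10 percent of the
#' linear signal's population standard deviation, giving a population
#' Pearson correlation of about 0.995.
#'
#' @param n_sims number of simulations (>= 3; default 6).
#' @param slope linear coefficient (delta_E units per delta_x unit).
#' @param noise_sd Gaussian noise sd; default
#'   `0.1 * abs(slope) * (diff(x_range) / sqrt(12))`.
#' @param seed integer random seed (required).
#' @param x_range uniform range for delta_x (default c(-1, 1)).
#' @return list with `points` (a [switch_points()] table) and `truth`
#'   (generator parameters plus the population correlation `r_pop`).
#' @export
make_correlated_ensemble <- function(n_sims = 6L, slope = 3,
                                     noise_sd = NULL, seed,
                                     x_range = c(-1, 1)) {
  if (n_sims < 3L) stop("need at least 3 simulations")
  if (missing(seed)) stop("an explicit seed is required")
  sd_x <- diff(x_range) / sqrt(12)
  if (is.null(noise_sd)) noise_sd <- 0.1 * abs(slope) * sd_x
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  dx <- stats::runif(n_sims, x_range[1], x_range[2])
  de <- slope * dx + stats::rnorm(n_sims, 0, noise_sd)
  r_pop <- if (noise_sd == 0) sign(slope) else
    slope * sd_x / sqrt(slope^2 * sd_x^2 + noise_sd^2)
  list(points = switch_points(sprintf("sim%02d", seq_len(n_sims)), dx, de),
       truth = list(n_sims = n_sims, slope = slope, noise_sd = noise_sd,
                    x_range = x_range, seed = seed, r_pop = r_pop,
                    rng = "Mersenne-Twister/Inversion"))
}

#' Synthetic LHCII-like demonstration complex
#'
#' A fully synthetic stand-in for a plant light-harvesting monomer used in
#' examples and end-to-end tests: a 3-helix transmembrane scaffold along z,
#' 8 chlorophyll-a and 6 chlorophyll-b chlorin templates, 4 carotenoid
#' polyenes (two luteins near-parallel to the protein axis, one neoxanthin
#' tilted 60 degrees from it, one violaxanthin), and a 3-atom lipid-like
#' ligand. Residue numbering follows the conventional 601-614 chlorophyll /
#' 620-623 carotenoid scheme. This is generator output, not a crystal
#' structure.
#'
#' @param neo_tilt_deg tilt of the neoxanthin polyene from the z axis
#'   (default 60).
#' @return list with `model` and `registry` as from [make_complex()].
#' @export
lhcii_demo_blueprint <- function(neo_tilt_deg = 60) {
  prot <- make_helix_bundle(n_helices = 3, res_per_helix = 40,
                            start_resid = 14, chain = "A")
  ring <- function(variant, resid, pos, ang) {
    make_chlorin(pos, rotation_matrix(c(0, 1, 0), ang) %*%
                   rotation_matrix(c(0, 0, 1), 37 * resid %% 360),
                 variant, chain = "A", resid = resid)
  }
  chl_a_ids <- c(602, 603, 604, 610, 611, 612, 613, 614)
  chl_b_ids <- c(601, 605, 606, 607, 608, 609)
  pigs <- list()
  for (k in seq_along(chl_a_ids)) {
    phi <- 2 * pi * k / 8
    pigs[[length(pigs) + 1L]] <-
      ring("chl_a", chl_a_ids[k], c(14 * cos(phi), 14 * sin(phi), 6), 25 * k)
  }
  for (k in seq_along(chl_b_ids)) {
    phi <- 2 * pi * k / 6 + 0.3
    pigs[[length(pigs) + 1L]] <-
      ring("chl_b", chl_b_ids[k], c(13 * cos(phi), 13 * sin(phi), -6), 40 * k)
  }
  car <- function(resname, resid, pos, tilt) {
    # template long axis is x; rotate it to z, then tilt away from z
    make_polyene(pos, rotation_matrix(c(0, 1, 0), tilt) %*%
                   rotation_matrix(c(0, 1, 0), -90),
                 n_atoms = 22, chain = "A", resid = resid, resname = resname)
  }
  pigs <- c(pigs, list(
    car("LUT", 620, c(6, 2, 0), 8),
    car("LUT", 621, c(-6, -2, 0), -8),
    car("XAT", 622, c(2, -16, 0), 15),
    car("NEX", 623, c(-2, 16, 0), neo_tilt_deg)
  ))
  lipid <- .atoms_df("HETATM", c("P", "O1", "O2"), "LHG", "A",
                     rep(630L, 3),
                     rbind(c(16, 6, -10), c(17, 6.5, -10.5), c(15.2, 7, -10.2)),
                     element = c("P", "O", "O"))
  make_complex(prot, pigs, lipid, source = "synthetic LHCII-like demo")
}
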