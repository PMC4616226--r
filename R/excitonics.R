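# Vacuum dipole-dipole coupling constant, cm^-1 A^3 D^-2.
# mu1*mu2*kappa/R^3 in these units times this constant gives cm^-1.
# Derived from CODATA: (1 D)^2 / (4 pi eps0 * (1 A)^3 * h c) expressed in
# cm^-1; equivalently (0.2081943 e*A/D)^2 * 14.399645 eV*A * 8065.544 cm^-1/eV.
DIPOLE_COUPLING_CONST <- 5034.1166

#' Orientation factor of two transition dipoles
#'
#' kappa = mu1_hat . mu2_hat - 3 (mu1_hat . r_hat)(mu2_hat . r_hat), where
#' r_hat is the unit vector between the dipole centers. Bounded in [-2, 2].
#'
#' @param d1,d2 [transition_dipole()] objects with distinct centers.
#' @return the orientation factor (dimensionless).
#' @export
orientation_kappa <- function(d1, d2) {
  r <- d2$center - d1$center
  R <- sqrt(sum(r^2))
  if (R < 1e-9) stop("dipole centers coincide; orientation factor undefined")
  rhat <- r / R
  sum(d1$direction * d2$direction) -
    3 * sum(d1$direction * rhat) * sum(d2$direction * rhat)
}

.coupling_result <- function(pair_id, method, energy_cm, kappa, distance_R,
                             screening_f) {
  structure(list(pair_id = pair_id, method = method,
                 energy_cm = energy_cm, kappa = kappa,
                 distance_R = distance_R, screening_f = screening_f),
            class = "CouplingResult")
}

#' @export
print.CouplingResult <- function(x, ...) {
  cat(sprintf("<CouplingResult> %s: %.2f cm^-1 (R = %.2f A%s, f = %g)\n",
              x$method, x$energy_cm, x$distance_R,
              if (is.na(x$kappa)) "" else sprintf(", kappa = %.3f", x$kappa),
              x$screening_f))
  invisible(x)
}

#' Point-dipole excitonic coupling
#'
#' V = C f kappa mu1 mu2 / R^3 with mu in Debye, R in Angstrom and
#' C = 5034.1166 cm^-1 A^3 D^-2 (vacuum). The coupling falls off with the
#' cube of the center-center distance and is signed by the orientation
#' factor.
#'
#' @param d1,d2 [transition_dipole()] objects with distinct centers.
#' @param screening_f dimensionless screening factor (default 1, vacuum).
#' @param pair_id optional identifier carried into the result.
#' @return a `CouplingResult` with fields `energy_cm`, `kappa`, `distance_R`.
#' @export
point_dipole_coupling <- function(d1, d2, screening_f = 1,
                                  pair_id = NULL) {
  r <- d2$center - d1$center
  R <- sqrt(sum(r^2))
  if (R < 1e-9) stop("dipole centers coincide")
  kappa <- orientation_kappa(d1, d2)
  E <- DIPOLE_COUPLING_CONST * screening_f * kappa *
    d1$magnitude_debye * d2$magnitude_debye / R^3
  .coupling_result(pair_id, "point_dipole", E, kappa, R, screening_f)
}

#' Extended-dipole parameters
#'
#' Each transition is represented by two point charges +/- q separated by
#' `length_l` along the dipole direction, with q = mu / l.
#'
#' @param length_l charge separation in Angstrom (> 0); 8.7 A is a common
#'   choice for the chlorophyll Qy transition.
#' @param screening_f dimensionless screening factor.
#' @return object of class `ExtendedDipoleParams`.
#' @export
extended_dipole_params <- function(length_l = 8.7, screening_f = 1) {
  stopifnot(length_l > 0)
  structure(list(length_l = length_l, screening_f = screening_f),
            class = "ExtendedDipoleParams")
}

#' Extended-dipole excitonic coupling
#'
#' Replaces each transition dipole by charges +/- q at
#' center +/- (l/2) direction, q = mu / l (in Debye per Angstrom), and sums
#' the four inter-dipole Coulomb terms with the same unit system as
#' [point_dipole_coupling()]: V = f C sum q_a q_b / r_ab. Converges to the
#' point-dipole value as l / R -> 0 and attenuates the coupling at short
#' range.
#'
#' @param d1,d2 [transition_dipole()] objects.
#' @param params1,params2 [extended_dipole_params()] for each dipole; the
#'   screening factor of `params1` is applied.
#' @param pair_id optional identifier carried into the result.
#' @return a `CouplingResult` (`kappa` is `NA` for this method).
#' @export
extended_dipole_coupling <- function(d1, d2,
                                     params1 = extended_dipole_params(),
                                     params2 = params1,
                                     pair_id = NULL) {
  q1 <- d1$magnitude_debye / params1$length_l
  q2 <- d2$magnitude_debye / params2$length_l
  s1 <- rbind(d1$center + (params1$length_l / 2) * d1$direction,
              d1$center - (params1$length_l / 2) * d1$direction)
  s2 <- rbind(d2$center + (params2$length_l / 2) * d2$direction,
              d2$center - (params2$length_l / 2) * d2$direction)
  qs1 <- c(q1, -q1); qs2 <- c(q2, -q2)
  E <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      rij <- sqrt(sum((s1[i, ] - s2[j, ])^2))
      if (rij < 1e-9) stop("coincident charge sites in extended-dipole model")
      E <- E + qs1[i] * qs2[j] / rij
    }
  }
  E <- DIPOLE_COUPLING_CONST * params1$screening_f * E
  R <- sqrt(sum((d2$center - d1$center)^2))
  .coupling_result(pair_id, "extended_dipole", E, NA_real_, R,
                   params1$screening_f)
}

.parse_pair_id <- function(pair) {
  # "A/611" -> list(chain, resid)
  if (is.character(pair)) {
    parts <- strsplit(pair, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("pigment id must look like 'A/611'")
    list(chain = parts[1], resid = as.integer(parts[2]))
  } else {
    pair
  }
}

#' Per-frame excitonic coupling time series
#'
#' Evaluates the coupling of each pigment pair in every trajectory frame.
#' Frames are processed independently; a missing dipole atom aborts with the
#' frame index in the error message.
#'
#' @param traj a `Trajectory`.
#' @param pairs list of length-2 character vectors of pigment ids, e.g.
#'   `list(c("A/611", "A/612"))`.
#' @param registry pigment registry (default [default_registry()]).
#' @param method "point_dipole" or "extended_dipole".
#' @param screening_f dimensionless screening factor.
#' @param params [extended_dipole_params()] used by the extended method.
#' @return data.frame with columns `frame`, `time_ns`, `pair`, `method`,
#'   `kappa`, `R_A`, `energy_cm`.
#' @export
coupling_series <- function(traj, pairs, registry = default_registry(),
                            method = c("point_dipole", "extended_dipole"),
                            screening_f = 1,
                            params = extended_dipole_params(
                              screening_f = screening_f)) {
  method <- match.arg(method)
  if (is.character(pairs)) pairs <- list(pairs)
  rows <- vector("list", length(pairs) * n_frames(traj))
  k <- 0L
  for (f in seq_len(n_frames(traj))) {
    model <- frame_model(traj, f)
    for (p in pairs) {
      id1 <- .parse_pair_id(p[[1]]); id2 <- .parse_pair_id(p[[2]])
      res <- tryCatch({
        pi1 <- pigment_instance(model, id1$chain, id1$resid, registry)
        pi2 <- pigment_instance(model, id2$chain, id2$resid, registry)
        dd1 <- pigment_dipole(pi1); dd2 <- pigment_dipole(pi2)
        if (method == "point_dipole") {
          point_dipole_coupling(dd1, dd2, screening_f)
        } else {
          extended_dipole_coupling(dd1, dd2, params)
        }
      }, lhc_missing_atom = function(e) {
        stop(sprintf("frame %d: %s", f, conditionMessage(e)), call. = FALSE)
      })
      k <- k + 1L
      rows[[k]] <- data.frame(
        frame = f, time_ns = traj$times[f],
        pair = paste(p[[1]], p[[2]], sep = ":"), method = method,
        kappa = res$kappa, R_A = res$distance_R, energy_cm = res$energy_cm,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Crystal-reference coupling for a pigment pair
#'
#' Computes the single-structure coupling used as the baseline for delta
#' values; the baseline is always computed from coordinates with the active
#' registry, never typed in.
#'
#' @param model the crystal `StructureModel`.
#' @param pair length-2 vector of pigment ids ("A/611" form).
#' @inheritParams coupling_series
#' @return a `CouplingResult`.
#' @export
crystal_coupling <- function(model, pair, registry = default_registry(),
                             method = c("point_dipole", "extended_dipole"),
                             screening_f = 1,
                             params = extended_dipole_params(
                               screening_f = screening_f)) {
  method <- match.arg(method)
  id1 <- .parse_pair_id(pair[[1]]); id2 <- .parse_pair_id(pair[[2]])
  d1 <- pigment_dipole(pigment_instance(model, id1$chain, id1$resid, registry))
  d2 <- pigment_dipole(pigment_instance(model, id2$chain, id2$resid, registry))
  if (method == "point_dipole") {
    point_dipole_coupling(d1, d2, screening_f,
                          pair_id = paste(pair, collapse = ":"))
  } else {
    extended_dipole_coupling(d1, d2, params,
                             pair_id = paste(pair, collapse = ":"))
  }
}
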