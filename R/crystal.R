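#' Fetch a PDB entry from the RCSB archive
#'
#' One-time download into a local cache directory; subsequent calls reuse
#' the cached file. Requires network access for the first call.
#'
#' @param id 4-character PDB accession (e.g. "1RWT").
#' @param cache_dir directory for cached files (default
#'   `tools::R_user_dir("lhcswitch", "cache")`).
#' @return path of the cached PDB file.
#' @export
fetch_pdb <- function(id, cache_dir = tools::R_user_dir("lhcswitch",
                                                        "cache")) {
  id <- toupper(id)
  if (!grepl("^[0-9][A-Z0-9]{3}$", id)) stop("'", id, "' is not a PDB id")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(cache_dir, paste0(id, ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
    ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest)) {
      unlink(dest)
      stop("could not download PDB entry ", id, " from ", url,
           " (no network access?)")
    }
  }
  dest
}

#' Extract one chain of a structure model
#'
#' @param model a `StructureModel`.
#' @param chain chain id to keep.
#' @return a `StructureModel` restricted to that chain.
#' @export
extract_chain <- function(model, chain) {
  idx <- resolve_selection(model, atom_selection(chain = chain))
  if (!length(idx)) stop("no atoms in chain ", chain)
  structure_model(model$atoms[idx, , drop = FALSE], model$model_id,
                  paste0(model$source, " chain ", chain))
}

#' Crystal-structure tilt of a carotenoid against the protein axis
#'
#' Convenience wrapper: estimates the protein axis from the CA backbone of
#' the model, builds the carotenoid S2 dipole, and reports the tilt angle.
#'
#' @param model a single-chain `StructureModel`.
#' @param pigment pigment id ("A/623" form).
#' @param registry pigment registry.
#' @param axis optional precomputed `ProteinAxis`.
#' @param ... passed to [car_s2_dipole()].
#' @return tilt angle in degrees, in [0, 90].
#' @export
crystal_car_tilt <- function(model, pigment, registry = default_registry(),
                             axis = NULL, ...) {
  id <- .parse_pair_id(pigment)
  if (is.null(axis)) axis <- protein_axis(model)
  p <- pigment_instance(model, id$chain, id$resid, registry)
  tilt_angle(car_s2_dipole(p, ...), axis)
}
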