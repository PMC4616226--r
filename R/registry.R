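#' Pigment registry entries
#'
#' A registry maps residue codes to pigment classes and to the atoms that
#' define each pigment's transition dipole. For chlorophylls the dipole is an
#' atom-pair axis (tail -> head) with a separate center atom; for carotenoids
#' it is the ordered list of conjugated-chain atoms whose central portion
#' defines the S2 transition axis.
#'
#' @param resnames residue codes matched against `resname` (e.g. "CLA").
#' @param pigment_class one of "chl_a", "chl_b", "carotenoid", "lipid".
#' @param axis_atoms length-2 character vector (tail, head) for chlorophylls.
#' @param center_atom dipole center atom name for chlorophylls (default Mg).
#' @param chain_atoms ordered conjugated-chain atom names for carotenoids.
#' @param magnitude_debye transition dipole magnitude in Debye (> 0 for
#'   chromophores; ignored for lipids).
#' @return object of class `PigmentRegistryEntry`.
#' @export
registry_entry <- function(resnames, pigment_class,
                           axis_atoms = NULL, center_atom = NULL,
                           chain_atoms = NULL, magnitude_debye = NA_real_) {
  pigment_class <- match.arg(pigment_class,
                             c("chl_a", "chl_b", "carotenoid", "lipid"))
  if (pigment_class %in% c("chl_a", "chl_b")) {
    stopifnot(length(axis_atoms) == 2L, length(center_atom) == 1L)
    if (!is.finite(magnitude_debye) || magnitude_debye <= 0) {
      stop("chromophore entries need magnitude_debye > 0")
    }
  }
  if (pigment_class == "carotenoid") {
    if (length(chain_atoms) < 2L) stop("carotenoid entries need >= 2 chain atoms")
    if (!is.finite(magnitude_debye) || magnitude_debye <= 0) {
      stop("chromophore entries need magnitude_debye > 0")
    }
  }
  structure(list(resnames = resnames, pigment_class = pigment_class,
                 axis_atoms = axis_atoms, center_atom = center_atom,
                 chain_atoms = chain_atoms,
                 magnitude_debye = magnitude_debye),
            class = "PigmentRegistryEntry")
}

#' Default cofactor registry
#'
#' Editable defaults for a plant light-harvesting complex: chlorophyll a
#' (het code CLA, Qy axis NB -> ND, center MG, 4.0 D), chlorophyll b (CHL,
#' 3.4 D), the xanthophylls lutein / neoxanthin / violaxanthin (LUT / NEX /
#' XAT, S2 dipole 13.0 D along the polyene chain), and the
#' phosphatidylglycerol lipid (LHG, no chromophore). Carotenoid chain-atom
#' names follow the common C1-C40 carotenoid numbering; het-code dialects
#' vary between depositions, so verify the codes and atom names against your
#' coordinate file and edit the registry where they differ.
#'
#' @param chl_a_debye,chl_b_debye,car_debye dipole magnitudes in Debye.
#' @return named list of [registry_entry()] objects.
#' @export
default_registry <- function(chl_a_debye = 4.0, chl_b_debye = 3.4,
                             car_debye = 13.0) {
  car_chain <- paste0("C", 7:26)
  list(
    chl_a = registry_entry("CLA", "chl_a", axis_atoms = c("NB", "ND"),
                           center_atom = "MG", magnitude_debye = chl_a_debye),
    chl_b = registry_entry("CHL", "chl_b", axis_atoms = c("NB", "ND"),
                           center_atom = "MG", magnitude_debye = chl_b_debye),
    lutein = registry_entry("LUT", "carotenoid", chain_atoms = car_chain,
                            magnitude_debye = car_debye),
    neoxanthin = registry_entry("NEX", "carotenoid", chain_atoms = car_chain,
                                magnitude_debye = car_debye),
    violaxanthin = registry_entry("XAT", "carotenoid", chain_atoms = car_chain,
                                  magnitude_debye = car_debye),
    dppg = registry_entry("LHG", "lipid")
  )
}

#' Read a registry from a YAML config file
#'
#' The file holds one block per entry with keys `resnames`, `pigment_class`,
#' and the dipole fields of [registry_entry()].
#'
#' @param path YAML file path.
#' @return named list of `PigmentRegistryEntry` objects.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) {
    registry_entry(
      resnames = unlist(e$resnames), pigment_class = e$pigment_class,
      axis_atoms = unlist(e$axis_atoms), center_atom = e$center_atom,
      chain_atoms = unlist(e$chain_atoms),
      magnitude_debye = if (is.null(e$magnitude_debye)) NA_real_
                        else as.numeric(e$magnitude_debye)
    )
  })
}

#' Write a registry to a YAML config file
#'
#' @param registry named list of `PigmentRegistryEntry` objects.
#' @param path output path.
#' @export
write_registry <- function(registry, path) {
  yaml::write_yaml(lapply(registry, unclass), path)
  invisible(path)
}

.registry_lookup <- function(registry, resname) {
  for (nm in names(registry)) {
    if (resname %in% registry[[nm]]$resnames) return(registry[[nm]])
  }
  NULL
}

#' Extract one pigment instance from a structure model
#'
#' Collects the atoms of residue (`chain`, `resid`) and checks that every
#' atom named in the registry entry's dipole specification is present;
#' absent dipole atoms raise a `lhc_missing_atom` error (never a silent
#' substitution) because crystal depositions can lack cofactor atoms.
#'
#' @param model a `StructureModel`.
#' @param chain chain id.
#' @param resid residue number.
#' @param registry registry list (default [default_registry()]).
#' @return object of class `PigmentInstance` with fields `pigment_id`,
#'   `atom_map` (named 3-col matrix) and `registry` (its entry).
#' @export
pigment_instance <- function(model, chain, resid,
                             registry = default_registry()) {
  a <- model$atoms
  rows <- which(a$chain == chain & a$resid == resid)
  if (!length(rows)) {
    stop(sprintf("no residue %s/%s in model", chain, resid))
  }
  resname <- a$resname[rows[1]]
  entry <- .registry_lookup(registry, resname)
  if (is.null(entry)) stop("residue code '", resname, "' not in registry")
  atom_map <- as.matrix(a[rows, c("x", "y", "z")])
  rownames(atom_map) <- a$name[rows]
  needed <- c(entry$axis_atoms, entry$center_atom, entry$chain_atoms)
  absent <- setdiff(needed, rownames(atom_map))
  if (length(absent)) {
    .missing_atom_error(paste(absent, collapse = ", "),
                        sprintf("%s %s/%s", resname, chain, resid))
  }
  structure(list(pigment_id = list(chain = chain, resid = resid,
                                   resname = resname),
                 atom_map = atom_map, registry = entry),
            class = "PigmentInstance")
}

#' @export
print.PigmentInstance <- function(x, ...) {
  cat(sprintf("<PigmentInstance> %s %s/%d (%s), %d atoms\n",
              x$pigment_id$resname, x$pigment_id$chain, x$pigment_id$resid,
              x$registry$pigment_class, nrow(x$atom_map)))
  invisible(x)
}

#' List all registry pigments present in a model
#'
#' @inheritParams pigment_instance
#' @param classes restrict to these pigment classes (default all).
#' @return list of `PigmentInstance` objects, in model residue order.
#' @export
extract_pigments <- function(model, registry = default_registry(),
                             classes = c("chl_a", "chl_b", "carotenoid",
                                         "lipid")) {
  a <- model$atoms
  all_codes <- unlist(lapply(registry, function(e) {
    if (e$pigment_class %in% classes) e$resnames else character()
  }))
  rows <- which(a$resname %in% all_codes)
  if (!length(rows)) return(list())
  key <- paste(a$chain[rows], a$resid[rows])
  first <- rows[!duplicated(key)]
  lapply(first, function(i) {
    pigment_instance(model, a$chain[i], a$resid[i], registry)
  })
}

#' Cofactor census of a model
#'
#' Counts registry-recognised cofactor residues per pigment class.
#'
#' @inheritParams extract_pigments
#' @return named integer vector with one count per pigment class present,
#'   plus `total_pigments` (chromophore classes only: chl_a + chl_b +
#'   carotenoid).
#' @export
pigment_census <- function(model, registry = default_registry()) {
  a <- model$atoms
  classes <- vapply(unique(paste(a$chain, a$resid, a$resname)), function(k) {
    resname <- strsplit(k, " ")[[1]][3]
    e <- .registry_lookup(registry, resname)
    if (is.null(e)) NA_character_ else e$pigment_class
  }, character(1))
  classes <- classes[!is.na(classes)]
  out <- c(table(factor(classes, levels = c("chl_a", "chl_b", "carotenoid",
                                            "lipid"))))
  c(out, total_pigments = sum(out[c("chl_a", "chl_b", "carotenoid")]))
}
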