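#' Conversion from Hartree to kcal/mol
#'
#' @param x Energies in Hartree.
#' @return Energies in kcal/mol (1 Hartree = 627.5095 kcal/mol).
#' @export
hartree_to_kcal <- function(x) x * 627.5095

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Reference enthalpies for thermochemical cycles
#'
#' Reference enthalpies of the hydrogen radical, proton and electron used in
#' the bond-dissociation, proton-affinity and electron-transfer cycles.
#' Defaults for the proton and electron follow the standard literature
#' values for gas phase and implicit (SMD) water; the hydrogen-radical
#' enthalpy is level-of-theory dependent and must be supplied.
#'
#' @param H_hydrogen_radical Enthalpy of H-dot, kcal/mol.
#' @param phase `"smd_water"` or `"in_vacuo"`; selects the proton/electron
#'   defaults (-250.574 / -17.816 kcal/mol in SMD water, 1.481 / 0.752 in
#'   vacuo).
#' @param H_proton,H_electron Optional overrides, kcal/mol.
#' @return Object of class `reference_enthalpies`.
#' @export
reference_enthalpies <- function(H_hydrogen_radical,
                                 phase = c("smd_water", "in_vacuo"),
                                 H_proton = NULL, H_electron = NULL) {
  phase <- match.arg(phase)
  defaults <- switch(phase,
    smd_water = c(proton = -250.574, electron = -17.816),
    in_vacuo  = c(proton = 1.481, electron = 0.752))
  out <- list(
    H_hydrogen_radical = check_finite(H_hydrogen_radical, "H_hydrogen_radical"),
    H_proton = check_finite(H_proton %||% unname(defaults["proton"]), "H_proton"),
    H_electron = check_finite(H_electron %||% unname(defaults["electron"]), "H_electron"),
    phase = phase)
  class(out) <- "reference_enthalpies"
  out
}

#' Per-analyte quantum-chemistry summary record
#'
#' Raw enthalpy-corrected species energies and electronic-structure
#' quantities for one analyte, from which the 13 mechanistic descriptors
#' are computed. Radical and anion enthalpies are maps from hydroxyl-site
#' label to species enthalpy (one O-H abstraction / deprotonation per site).
#'
#' @param analyte_id Identifier, unique within a record set.
#' @param H_parent Enthalpy-corrected energy of the neutral species, kcal/mol.
#' @param H_radical Named numeric vector: site label -> radical enthalpy,
#'   kcal/mol.
#' @param H_anion Named numeric vector: site label -> deprotonated anion
#'   enthalpy, kcal/mol. Must share site labels with `H_radical`.
#' @param E_invacuo,E_solvent Neutral-species enthalpy-corrected energy in
#'   vacuo and in implicit water, kcal/mol.
#' @param E_HOMO,E_LUMO Frontier-orbital energies, eV.
#' @param dipole_total Total dipole moment, Debye.
#' @param nbo_min_charge Excess charge of the most negatively charged atom
#'   (NBO analysis), e.
#' @param n_OH Number of hydroxyl groups (integer >= 0).
#' @return Object of class `qm_record`.
#' @export
qm_record <- function(analyte_id, H_parent, H_radical = numeric(),
                      H_anion = numeric(), E_invacuo, E_solvent,
                      E_HOMO, E_LUMO, dipole_total, nbo_min_charge, n_OH) {
  n_OH <- as.integer(n_OH)
  if (is.na(n_OH) || n_OH < 0) stop("n_OH must be a non-negative integer")
  check_finite(H_parent, "H_parent")
  check_finite(E_invacuo, "E_invacuo")
  check_finite(E_solvent, "E_solvent")
  check_finite(E_HOMO, "E_HOMO")
  check_finite(E_LUMO, "E_LUMO")
  check_finite(dipole_total, "dipole_total")
  check_finite(nbo_min_charge, "nbo_min_charge")
  if (length(H_radical)) check_finite(H_radical, "H_radical")
  if (length(H_anion)) check_finite(H_anion, "H_anion")
  if (length(H_radical) && length(H_anion) &&
      !setequal(names(H_radical), names(H_anion)))
    stop("radical and anion maps must share the same site labels")
  structure(list(
    analyte_id = as.character(analyte_id), H_parent = H_parent,
    H_radical = H_radical, H_anion = H_anion,
    E_invacuo = E_invacuo, E_solvent = E_solvent,
    E_HOMO = E_HOMO, E_LUMO = E_LUMO,
    dipole_total = dipole_total, nbo_min_charge = nbo_min_charge,
    n_OH = n_OH), class = "qm_record")
}

#' Solvation energy
#'
#' Difference between the enthalpy-corrected energy of the neutral analyte
#' in implicit water and in vacuo. Negative values indicate favourable
#' solvation.
#'
#' @param E_solvent,E_invacuo Energies in kcal/mol.
#' @return SE in kcal/mol.
#' @export
solvation_energy <- function(E_solvent, E_invacuo) {
  check_finite(E_solvent, "E_solvent")
  check_finite(E_invacuo, "E_invacuo")
  E_solvent - E_invacuo
}

#' O-H bond dissociation enthalpies over hydroxyl sites
#'
#' For each hydroxyl site s, BDE(s) = H(radical at s) + H(H-dot) -
#' H(parent). The minimum over sites parameterizes the first oxidation
#' step of the hydrogen-atom-transfer (HAT) antioxidant mechanism.
#'
#' @param rec A [qm_record()].
#' @param ref A [reference_enthalpies()].
#' @return List with `per_site` (named vector), `BDE_min` and `site_min`.
#'   For `n_OH = 0` analytes, `BDE_min` is `NA` and the map empty.
#' @export
bond_dissociation_enthalpies <- function(rec, ref) {
  stopifnot(inherits(rec, "qm_record"), inherits(ref, "reference_enthalpies"))
  if (rec$n_OH == 0L)
    return(list(per_site = numeric(), BDE_min = NA_real_, site_min = NA_character_))
  if (!length(rec$H_radical))
    stop("analyte ", rec$analyte_id, ": n_OH >= 1 but radical map is empty")
  per_site <- rec$H_radical + ref$H_hydrogen_radical - rec$H_parent
  i <- which.min(per_site) # ties: first site label wins
  list(per_site = per_site, BDE_min = unname(per_site[i]),
       site_min = names(per_site)[i])
}

#' Electron transfer enthalpy at a hydroxyl site
#'
#' ETE(s) = H(radical at s) + H(e-) - H(anion at s); second step of the
#' sequential proton-loss electron-transfer (SPLET) mechanism.
#'
#' @inheritParams bond_dissociation_enthalpies
#' @param site Site label, present in both the radical and anion maps.
#' @return ETE in kcal/mol.
#' @export
electron_transfer_enthalpy <- function(rec, ref, site) {
  stopifnot(inherits(rec, "qm_record"), inherits(ref, "reference_enthalpies"))
  if (!site %in% names(rec$H_radical) || !site %in% names(rec$H_anion))
    stop("analyte ", rec$analyte_id, ": site '", site,
         "' missing from radical/anion maps")
  unname(rec$H_radical[site] + ref$H_electron - rec$H_anion[site])
}

#' Proton affinity (deprotonation enthalpy) at a hydroxyl site
#'
#' PA(s) = H(anion at s) + H(H+) - H(parent); first step of the SPLET
#' mechanism (negative of the proton-gain enthalpy of the phenolate).
#'
#' @inheritParams electron_transfer_enthalpy
#' @return PA in kcal/mol.
#' @export
proton_affinity <- function(rec, ref, site) {
  stopifnot(inherits(rec, "qm_record"), inherits(ref, "reference_enthalpies"))
  if (!site %in% names(rec$H_anion))
    stop("analyte ", rec$analyte_id, ": site '", site, "' missing from anion map")
  unname(rec$H_anion[site] + ref$H_proton - rec$H_parent)
}

#' Koopmans approximations of IP, EA and the frontier-orbital gap
#'
#' IP = -E(HOMO), EA = -E(LUMO), gap = E(LUMO) - E(HOMO). A LUMO at or
#' below the HOMO triggers a warning (the DFT band-gap caveat) but the
#' values are still returned.
#'
#' @param E_HOMO,E_LUMO Orbital energies, eV.
#' @return List with `IP`, `EA`, `gap` (eV).
#' @export
koopmans_ip_ea <- function(E_HOMO, E_LUMO) {
  check_finite(E_HOMO, "E_HOMO")
  check_finite(E_LUMO, "E_LUMO")
  if (any(E_LUMO <= E_HOMO))
    warning("E_LUMO <= E_HOMO: non-positive frontier-orbital gap")
  list(IP = -E_HOMO, EA = -E_LUMO, gap = E_LUMO - E_HOMO)
}

#' Conceptual-DFT global reactivity indices
#'
#' Global hardness eta = (IP - EA)/2, electronic chemical potential
#' mu = -(IP + EA)/2 (the negative of mu is the absolute
#' electronegativity, returned as `electronegativity`), and
#' electrophilicity omega = mu^2 / (2 eta). A degenerate IP = EA gives
#' eta = 0 and an undefined (NA) omega.
#'
#' @param IP,EA Ionization potential and electron affinity, eV.
#' @return List with `eta`, `mu`, `omega`, `electronegativity` (eV).
#' @export
global_reactivity <- function(IP, EA) {
  check_finite(IP, "IP")
  check_finite(EA, "EA")
  eta <- (IP - EA) / 2
  mu <- -(IP + EA) / 2
  omega <- ifelse(eta == 0, NA_real_, mu^2 / (2 * eta))
  list(eta = eta, mu = mu, omega = omega, electronegativity = -mu)
}

#' Compute the 13-descriptor vector for one analyte
#'
#' The reported ETE and PA values are taken at the minimum-BDE site (the
#' site of the first oxidation step) by default; `site_policy = "min"`
#' instead takes the minimum of each quantity over all sites.
#'
#' @inheritParams bond_dissociation_enthalpies
#' @param site_policy `"bde_min"` (default) or `"min"`.
#' @return Named numeric vector of length 13 (order [descriptor_names()]).
#'   For `n_OH = 0` analytes BDE_min, PA and ETE are `NA`.
#' @export
compute_descriptors <- function(rec, ref, site_policy = c("bde_min", "min")) {
  site_policy <- match.arg(site_policy)
  bde <- bond_dissociation_enthalpies(rec, ref)
  if (rec$n_OH == 0L || is.na(bde$BDE_min)) {
    pa <- ete <- NA_real_
  } else if (site_policy == "bde_min") {
    pa <- proton_affinity(rec, ref, bde$site_min)
    ete <- electron_transfer_enthalpy(rec, ref, bde$site_min)
  } else {
    pa <- min(vapply(names(rec$H_anion), proton_affinity,
                     numeric(1), rec = rec, ref = ref))
    ete <- min(vapply(names(rec$H_radical), electron_transfer_enthalpy,
                      numeric(1), rec = rec, ref = ref))
  }
  k <- koopmans_ip_ea(rec$E_HOMO, rec$E_LUMO)
  g <- global_reactivity(k$IP, k$EA)
  out <- c(SE = solvation_energy(rec$E_solvent, rec$E_invacuo),
           n_OH = as.numeric(rec$n_OH),
           BDE_min = bde$BDE_min, PA = pa, ETE = ete,
           delta_min = rec$nbo_min_charge, M_tot = rec$dipole_total,
           gap_HOMO_LUMO = k$gap, IP = k$IP, EA = k$EA,
           eta = g$eta, mu = g$mu, omega = g$omega)
  out[descriptor_names()]
}

#' Assemble the descriptor matrix for a set of analytes
#'
#' @param records List of [qm_record()] objects with unique analyte ids.
#' @inheritParams compute_descriptors
#' @return Data frame: `analyte_id` plus the 13 descriptor columns in
#'   fixed order. Analytes without hydroxyl groups carry `NA` in the
#'   HAT/SPLET columns and are reported via a message; downstream
#'   modelling drops rows with missing values in the selected subset.
#' @export
assemble_descriptors <- function(records, ref, site_policy = c("bde_min", "min")) {
  site_policy <- match.arg(site_policy)
  ids <- vapply(records, function(r) r$analyte_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate analyte ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  X <- t(vapply(records, compute_descriptors, numeric(13),
                ref = ref, site_policy = site_policy))
  out <- data.frame(analyte_id = ids, X, stringsAsFactors = FALSE)
  incomplete <- ids[!stats::complete.cases(X)]
  if (length(incomplete))
    message("HAT/SPLET descriptors missing (n_OH = 0) for: ",
            paste(incomplete, collapse = ", "))
  out
}

#' Read quantum-chemistry summary records from long-format CSV
#'
#' Expected columns: `analyte_id, species, site, phase, quantity, value,
#' unit` with species in neutral/radical/anion, phase in vacuo/smd,
#' quantity in H/E_HOMO/E_LUMO/dipole/nbo_min/n_OH. Enthalpies with unit
#' `hartree` are converted to kcal/mol. The neutral SMD-phase enthalpy
#' serves as both the solvated energy and the parent enthalpy of the
#' thermochemical cycles.
#'
#' @param path CSV path.
#' @return List of [qm_record()] objects.
#' @export
read_qm_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte_id", "species", "site", "phase", "quantity", "value", "unit")
  if (!all(need %in% names(df)))
    stop("qm_records CSV must have columns: ", paste(need, collapse = ", "))
  conv <- function(v, u) ifelse(tolower(u) == "hartree", hartree_to_kcal(v), v)
  lapply(split(df, df$analyte_id), function(d) {
    pick <- function(sp, ph, qt) {
      r <- d[d$species == sp & d$phase == ph & d$quantity == qt, ]
      if (nrow(r) == 0) stop("analyte ", d$analyte_id[1], ": missing ",
                             sp, "/", ph, "/", qt)
      conv(r$value[1], r$unit[1])
    }
    rad <- d[d$species == "radical" & d$quantity == "H", ]
    an <- d[d$species == "anion" & d$quantity == "H", ]
    H_solv <- pick("neutral", "smd", "H")
    qm_record(
      analyte_id = d$analyte_id[1],
      H_parent = H_solv,
      H_radical = stats::setNames(conv(rad$value, rad$unit), rad$site),
      H_anion = stats::setNames(conv(an$value, an$unit), an$site),
      E_invacuo = pick("neutral", "vacuo", "H"),
      E_solvent = H_solv,
      E_HOMO = pick("neutral", "smd", "E_HOMO"),
      E_LUMO = pick("neutral", "smd", "E_LUMO"),
      dipole_total = pick("neutral", "smd", "dipole"),
      nbo_min_charge = pick("neutral", "smd", "nbo_min"),
      n_OH = pick("neutral", "smd", "n_OH"))
  })
}

#' Write quantum-chemistry records to long-format CSV
#'
#' Inverse of [read_qm_records()].
#'
#' @param records List of [qm_record()] objects.
#' @param path CSV path.
#' @export
write_qm_records <- function(records, path) {
  rows <- lapply(records, function(r) {
    base <- data.frame(
      analyte_id = r$analyte_id,
      species = "neutral", site = NA_character_,
      phase = c("vacuo", "smd", "smd", "smd", "smd", "smd", "smd"),
      quantity = c("H", "H", "E_HOMO", "E_LUMO", "dipole", "nbo_min", "n_OH"),
      value = c(r$E_invacuo, r$E_solvent, r$E_HOMO, r$E_LUMO,
                r$dipole_total, r$nbo_min_charge, r$n_OH),
      unit = c("kcal/mol", "kcal/mol", "eV", "eV", "D", "e", "count"),
      stringsAsFactors = FALSE)
    sp <- function(species, v) if (length(v)) data.frame(
      analyte_id = r$analyte_id, species = species, site = names(v),
      phase = "smd", quantity = "H", value = unname(v), unit = "kcal/mol",
      stringsAsFactors = FALSE) else NULL
    rbind(base, sp("radical", r$H_radical), sp("anion", r$H_anion))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Write / read a descriptor table as CSV
#'
#' @param descriptors Data frame from [assemble_descriptors()].
#' @param path CSV path.
#' @export
write_descriptors <- function(descriptors, path) {
  utils::write.csv(descriptors, path, row.names = FALSE)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("analyte_id", descriptor_names()), names(df))
  if (length(miss)) stop("descriptor CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df[, c("analyte_id", descriptor_names())]
}
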