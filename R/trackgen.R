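# Synthetic 1 ps inputs: toy fixtures, homogeneous boxes for kinetics
# checks, and a calibratable spur-structured track generator that
# reproduces configured 1 ps yields without the full physics stage.

#' Two molecules at a fixed separation
#'
#' @param a,b Species names.
#' @param distance_nm Separation along the x axis (>= 0).
#' @param registry A `chem_registry`.
#' @param box Optional box.
#' @return A `molecule_set` at 1 ps.
#' @export
toy_pair <- function(a, b, distance_nm, registry = default_registry(),
                     box = NULL) {
  stopifnot(distance_nm >= 0)
  molecule_set(c(a, b), rbind(c(0, 0, 0), c(distance_nm, 0, 0)),
               time_ps = registry$constants$chem_t_start_ps,
               box = box, registry = registry)
}

#' Uniform random population at given concentrations
#'
#' @param concentrations_mol_dm3 Named vector, mol/dm^3 per species.
#' @param box_size_nm Cubic box edge length in nm (box spans `[0, size]^3`).
#' @param registry A `chem_registry`.
#' @return A `molecule_set` with the box attached; realised counts are
#'   `round(c N_A V)`.
#' @export
homogeneous_box <- function(concentrations_mol_dm3, box_size_nm,
                            registry = default_registry()) {
  stopifnot(all(concentrations_mol_dm3 >= 0), box_size_nm > 0)
  V_dm3 <- box_size_nm^3 * 1e-24
  counts <- round(concentrations_mol_dm3 * registry$constants$avogadro * V_dm3)
  species <- rep(names(counts), counts)
  n <- length(species)
  pos <- matrix(runif(3 * n, 0, box_size_nm), ncol = 3)
  if (n > 1) {
    # a crude overfill guard: mean spacing must exceed the largest radius
    if ((box_size_nm^3 / n)^(1 / 3) < max(registry$reactions$radius_nm))
      stop("box overfull: mean intermolecular spacing below contact radius")
  }
  molecule_set(species, pos, time_ps = registry$constants$chem_t_start_ps,
               box = list(lo = c(0, 0, 0), hi = rep(box_size_nm, 3)),
               registry = registry)
}

# product-channel stoichiometry used by the generator and its calibration:
# a: ionization-like (direct ionization and auto-ionizing excitations),
# b: A1B1 dissociative decay, c: B1A1 dissociative decay,
# d: dissociative attachment
.channel_products <- list(
  ionization_like = c("H3O+", "OH", "e_aq"),
  a1b1_dissoc = c("OH", "H"),
  b1a1_dissoc = c("OH", "OH", "H2"),
  attachment = c("OH", "OH-", "H2")
)

.channel_matrix <- function(registry) {
  sp <- registry$species$name
  S <- matrix(0, nrow = length(sp), ncol = length(.channel_products),
              dimnames = list(sp, names(.channel_products)))
  for (ch in names(.channel_products))
    for (p in .channel_products[[ch]])
      S[p, ch] <- S[p, ch] + 1
  S
}

#' Calibrate channel frequencies from 1 ps yields
#'
#' Solves the per-100 eV frequencies of the four product channels from
#' target 1 ps yields (G-values) and the channel stoichiometry, by least
#' squares. Channels with identical products (direct ionization and the
#' auto-ionizing excitation channels) are aggregated into one
#' ionization-like rate, which is all the yields can identify.
#'
#' @param yields_per_100eV Named numeric vector of 1 ps G-values; names are
#'   registry species (missing species are treated as 0).
#' @param registry A `chem_registry`.
#' @return Object of class `"track_calibration"`: list with
#'   `rates_per_100eV` (named, the four channels), `yields` (the fitted
#'   1 ps yields implied by the rates) and `target_yields`.
#' @export
calibrate <- function(yields_per_100eV, registry = default_registry()) {
  sp <- registry$species$name
  y <- setNames(numeric(length(sp)), sp)
  unknown <- setdiff(names(yields_per_100eV), sp)
  if (length(unknown))
    stop("uncalibrated species: ", paste(unknown, collapse = ", "))
  y[names(yields_per_100eV)] <- yields_per_100eV
  S <- .channel_matrix(registry)
  rates <- qr.coef(qr(S), y)
  rates[is.na(rates)] <- 0
  if (any(rates < -1e-9))
    stop("infeasible yields: negative channel frequency for ",
         paste(names(rates)[rates < -1e-9], collapse = ", "))
  rates <- pmax(rates, 0)
  structure(list(rates_per_100eV = rates,
                 yields = drop(S %*% rates),
                 target_yields = y),
            class = "track_calibration")
}

#' @export
print.track_calibration <- function(x, ...) {
  cat("<track_calibration> channel frequencies per 100 eV:\n")
  print(round(x$rates_per_100eV, 4))
  invisible(x)
}

# NIST-style proton stopping powers in liquid water (MeV cm^2/g -> eV/nm at
# unit density), log-log interpolated
.pstar_E_MeV <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
.pstar_let <- c(42.8, 26.1, 15.9, 7.91, 4.57, 2.61, 1.25, 0.729)

#' Proton LET in liquid water (stopping-power table)
#' @param E_MeV Proton kinetic energies (0.5-100 MeV).
#' @return LET in eV/nm.
#' @export
proton_let_eV_nm <- function(E_MeV) {
  if (any(E_MeV < min(.pstar_E_MeV)) || any(E_MeV > max(.pstar_E_MeV)))
    stop("proton energy outside tabulated range 0.5-100 MeV")
  exp(stats::approx(log(.pstar_E_MeV), log(.pstar_let), log(E_MeV))$y)
}

# 1 ps G-values (per 100 eV) for the bundled validation presets
.preset_yields <- list(
  e750keV = c("OH" = 5.45, "e_aq" = 4.61, "H3O+" = 4.63, "H" = 0.58,
              "H2" = 0.13, "OH-" = 0.03, "H2O2" = 0),
  p20MeV = c("OH" = 5.48, "e_aq" = 4.61, "H3O+" = 4.64, "H" = 0.60,
             "H2" = 0.14, "OH-" = 0.02, "H2O2" = 0),
  p5MeV = c("OH" = 5.48, "e_aq" = 4.61, "H3O+" = 4.64, "H" = 0.60,
            "H2" = 0.14, "OH-" = 0.02, "H2O2" = 0)
)
.preset_let <- c(e750keV = 0.185, p20MeV = 2.61, p5MeV = 7.91)
.preset_edep <- c(e750keV = 5e4, p20MeV = 2610, p5MeV = 7910)

#' Bundled calibration presets
#'
#' 1 ps yields for the validation beams (750 keV electrons, 20 and 5 MeV
#' protons) with standard stopping-power LETs and a default per-event
#' energy deposit (for protons, one 1 um traversal worth).
#'
#' @param name `"e750keV"`, `"p20MeV"` or `"p5MeV"`.
#' @param registry A `chem_registry`.
#' @return List: `calibration` (a `track_calibration`), `let_eV_nm`,
#'   `edep_eV` (default per-event deposit), `name`.
#' @export
calibration_preset <- function(name = c("e750keV", "p20MeV", "p5MeV"),
                               registry = default_registry()) {
  name <- match.arg(name)
  list(calibration = calibrate(.preset_yields[[name]], registry),
       let_eV_nm = unname(.preset_let[name]),
       edep_eV = unname(.preset_edep[name]),
       name = name)
}

#' Generate a calibrated 1 ps track
#'
#' Emulates the spatial structure of molecular species at the start of the
#' chemical stage: energy is deposited in spurs (localised clusters of
#' activation events) placed along a straight track axis with exponential
#' spacing set by the LET; each spur receives Poisson numbers of
#' product-channel events at the calibrated per-100 eV frequencies, with
#' activation sites spread around the spur centre by an isotropic
#' exponential radial profile. Sites are dissociated with the
#' physicochemical placement rules (fragment separation, hydrated-electron
#' thermalisation displacement).
#'
#' @param calibration A `track_calibration` (or the output of
#'   [calibration_preset()], whose LET and default deposit are then used).
#' @param edep_eV Target energy deposit per event; realised as an integer
#'   number of spurs (the realised value is returned and used for G-value
#'   normalisation).
#' @param let_eV_nm Linear energy transfer controlling spur spacing.
#' @param registry A `chem_registry`.
#' @param spur_energy_eV Mean energy per spur.
#' @param spur_radius_nm Mean of the exponential radial site spread.
#' @param separation_nm Dissociation fragment separation.
#' @param thermalization Hydrated-electron displacement law.
#' @param pad_nm Box padding around the track bounding region.
#' @return List: `m` (`molecule_set` at 1 ps), `edep_eV` (realised),
#'   `n_sites`, `let_eV_nm`.
#' @export
simplified_track <- function(calibration, edep_eV = NULL, let_eV_nm = NULL,
                             registry = default_registry(),
                             spur_energy_eV = 62.5, spur_radius_nm = 1.0,
                             separation_nm = 0.8,
                             thermalization = list(type = "exponential",
                                                   mean_nm = 6),
                             pad_nm = 500) {
  if (!inherits(calibration, "track_calibration")) {
    preset <- calibration
    calibration <- preset$calibration
    if (is.null(edep_eV)) edep_eV <- preset$edep_eV
    if (is.null(let_eV_nm)) let_eV_nm <- preset$let_eV_nm
  }
  stopifnot(inherits(calibration, "track_calibration"),
            edep_eV >= 0, let_eV_nm > 0)
  if (edep_eV == 0)
    return(list(m = molecule_set(character(), matrix(numeric(), 0, 3),
                                 registry = registry),
                edep_eV = 0, n_sites = 0L, let_eV_nm = let_eV_nm))
  n_spurs <- max(1L, as.integer(round(edep_eV / spur_energy_eV)))
  edep <- n_spurs * spur_energy_eV
  spacing <- spur_energy_eV / let_eV_nm
  zc <- cumsum(rexp(n_spurs, rate = 1 / spacing))
  rates <- calibration$rates_per_100eV
  mols <- list()
  n_sites <- 0L
  for (s in seq_len(n_spurs)) {
    center <- c(0, 0, zc[s])
    for (ch in names(.channel_products)) {
      n_k <- rpois(1, spur_energy_eV / 100 * rates[[ch]])
      for (i in seq_len(n_k)) {
        n_sites <- n_sites + 1L
        site <- center + rexp(1, 1 / spur_radius_nm) * .iso_dir()
        pl <- .place_channel(.channel_products[[ch]], site, separation_nm)
        if (nrow(pl$molecules)) mols[[length(mols) + 1L]] <- pl$molecules
        for (r in seq_len(nrow(pl$eaq_candidates)))
          mols[[length(mols) + 1L]] <-
            thermalize_electron(pl$eaq_candidates[r, ], thermalization)
      }
    }
  }
  box <- list(lo = c(-pad_nm, -pad_nm, -pad_nm),
              hi = c(pad_nm, pad_nm, max(zc) + pad_nm))
  if (!length(mols)) {
    m <- molecule_set(character(), matrix(numeric(), 0, 3),
                      time_ps = registry$constants$chem_t_start_ps,
                      box = box, registry = registry)
    return(list(m = m, edep_eV = edep, n_sites = n_sites,
                let_eV_nm = let_eV_nm))
  }
  all <- do.call(rbind, mols)
  all$x_nm <- pmin(pmax(all$x_nm, box$lo[1]), box$hi[1])
  all$y_nm <- pmin(pmax(all$y_nm, box$lo[2]), box$hi[2])
  all$z_nm <- pmin(pmax(all$z_nm, box$lo[3]), box$hi[3])
  m <- molecule_set(all$species, as.matrix(all[, c("x_nm", "y_nm", "z_nm")]),
                    time_ps = registry$constants$chem_t_start_ps,
                    box = box, registry = registry)
  list(m = m, edep_eV = edep, n_sites = n_sites, let_eV_nm = let_eV_nm)
}
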