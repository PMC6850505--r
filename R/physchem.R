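# Physicochemical stage: activated water (excited/ionized molecules and
# dissociative-attachment anions) turns into radicals and ions well before
# 1 ps; sub-excitation electrons thermalise and solvate. The output is the
# molecular population handed to the chemical stage at t = 1 ps.

# place a product channel around a site: heavy fragments back-to-back along
# a random axis at `separation_nm`; any e_aq entries are returned as
# solvation candidates at the site (they get the thermalisation
# displacement, not the fragment geometry)
.place_channel <- function(products, site, separation_nm) {
  heavy <- products[products != "e_aq"]
  out <- NULL
  if (length(heavy)) {
    axis <- .iso_dir()
    off <- (separation_nm / 2) * axis
    pos <- switch(as.character(length(heavy)),
      "1" = matrix(site, 1, 3, byrow = TRUE),
      "2" = rbind(site + off, site - off),
      "3" = rbind(site + off, site - off, site))
    out <- data.frame(species = heavy, x_nm = pos[, 1], y_nm = pos[, 2],
                      z_nm = pos[, 3])
  } else {
    out <- data.frame(species = character(), x_nm = numeric(),
                      y_nm = numeric(), z_nm = numeric())
  }
  n_eaq <- sum(products == "e_aq")
  cand <- data.frame(x_nm = rep(site[1], n_eaq), y_nm = rep(site[2], n_eaq),
                     z_nm = rep(site[3], n_eaq))
  list(molecules = out, eaq_candidates = cand)
}

#' Dissociate one activated water molecule
#'
#' Draws a dissociation/relaxation channel for the activation's parent
#' state with the registry branching fractions. Dissociative decay places
#' the fragments back-to-back along a random axis; relaxation produces
#' nothing (the excess energy is released locally); auto-ionization
#' channels additionally yield a hydrated-electron candidate at the site.
#'
#' @param activation List or one-row data frame with `x_nm,y_nm,z_nm` and
#'   `state` (a registry parent state).
#' @param registry A `chem_registry`.
#' @param separation_nm Fragment separation in nm (default 0.8, the thermal-migration scale of the dissociation fragments).
#' @return List: `molecules` (data frame `species,x_nm,y_nm,z_nm`),
#'   `eaq_candidates` (data frame `x_nm,y_nm,z_nm`), `mode` (the channel
#'   drawn), `released_eV` flag-like (TRUE for relaxation draws).
#' @export
dissociate <- function(activation, registry = default_registry(),
                       separation_nm = 0.8) {
  ds <- registry$dissociation
  ch <- ds[ds$parent == activation$state, , drop = FALSE]
  if (!nrow(ch)) stop("unknown activation state '", activation$state, "'")
  u <- runif(1) * 100
  k <- findInterval(u, cumsum(ch$fraction_percent), left.open = TRUE) + 1L
  k <- min(k, nrow(ch))
  site <- c(activation$x_nm, activation$y_nm, activation$z_nm)
  if (ch$mode[k] == "relaxation") {
    pl <- .place_channel(character(), site, separation_nm)
    return(c(pl, list(mode = "relaxation", released = TRUE)))
  }
  pl <- .place_channel(ch$products[[k]], site, separation_nm)
  c(pl, list(mode = ch$mode[k], released = FALSE))
}

#' Thermalise a sub-excitation electron into a hydrated electron
#'
#' The candidate is displaced isotropically from its stopping point with a
#' radial magnitude drawn from the configured law, then becomes e_aq at the
#' chemical-stage start time.
#'
#' @param candidate List or one-row data frame with `x_nm,y_nm,z_nm`.
#' @param law List: `type` (`"exponential"` or `"none"`) and `mean_nm`.
#' @return Data frame `species,x_nm,y_nm,z_nm` with one e_aq row.
#' @export
thermalize_electron <- function(candidate,
                                law = list(type = "exponential",
                                           mean_nm = 6)) {
  pos <- c(candidate$x_nm, candidate$y_nm, candidate$z_nm)
  if (identical(law$type, "exponential") && law$mean_nm > 0) {
    r <- rexp(1, rate = 1 / law$mean_nm)
    pos <- pos + r * .iso_dir()
  }
  data.frame(species = "e_aq", x_nm = pos[1], y_nm = pos[2], z_nm = pos[3])
}

#' Build the 1 ps molecular population from a physics event
#'
#' Dissociates every water activation and solvates every sub-excitation
#' electron candidate of one transport event; the resulting population is
#' time-stamped at the chemical-stage start (1 ps).
#'
#' @param event Output of [transport_event()] (`activations`, `solvation`).
#' @param registry A `chem_registry`.
#' @param box Simulation box for the chemical stage (`NULL` = unbounded).
#' @param separation_nm Fragment separation for dissociation.
#' @param thermalization Displacement law for [thermalize_electron()].
#' @return A `molecule_set` at `chem_t_start_ps`.
#' @export
build_initial_population <- function(event, registry = default_registry(),
                                     box = NULL, separation_nm = 0.8,
                                     thermalization = list(
                                       type = "exponential", mean_nm = 6)) {
  mols <- list()
  cands <- list()
  act <- event$activations
  for (r in seq_len(nrow(act))) {
    d <- dissociate(act[r, ], registry, separation_nm)
    if (nrow(d$molecules)) mols[[length(mols) + 1L]] <- d$molecules
    if (nrow(d$eaq_candidates)) cands[[length(cands) + 1L]] <- d$eaq_candidates
  }
  sol <- event$solvation
  if (!is.null(sol) && nrow(sol))
    cands[[length(cands) + 1L]] <- sol[, c("x_nm", "y_nm", "z_nm")]
  cands <- if (length(cands)) do.call(rbind, cands) else NULL
  if (!is.null(cands))
    for (r in seq_len(nrow(cands)))
      mols[[length(mols) + 1L]] <- thermalize_electron(cands[r, ],
                                                       thermalization)
  if (!length(mols)) {
    return(molecule_set(character(), matrix(numeric(), 0, 3),
                        time_ps = registry$constants$chem_t_start_ps,
                        box = box, registry = registry))
  }
  all <- do.call(rbind, mols)
  if (!is.null(box)) {  # clip rare out-of-box placements to the boundary
    all$x_nm <- pmin(pmax(all$x_nm, box$lo[1]), box$hi[1])
    all$y_nm <- pmin(pmax(all$y_nm, box$lo[2]), box$hi[2])
    all$z_nm <- pmin(pmax(all$z_nm, box$lo[3]), box$hi[3])
  }
  molecule_set(all$species, as.matrix(all[, c("x_nm", "y_nm", "z_nm")]),
               time_ps = registry$constants$chem_t_start_ps,
               box = box, registry = registry)
}
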