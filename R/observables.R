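# G-values, their time profiles and LET scans.

#' G-value
#'
#' Number of molecules per 100 eV of energy deposited in the medium.
#'
#' @param count Molecule count(s).
#' @param total_edep_eV Energy deposited in the scoring target, eV (> 0).
#' @return `100 * count / total_edep_eV`.
#' @export
g_value <- function(count, total_edep_eV) {
  if (any(total_edep_eV <= 0)) stop("total energy deposit must be positive")
  100 * count / total_edep_eV
}

#' Per-event G-value time series
#'
#' @param result A `chem_result`.
#' @param edep_eV The event's energy deposit in eV.
#' @return Species x time matrix of G-values.
#' @export
g_value_profile <- function(result, edep_eV) {
  g_value(result$counts, edep_eV)
}

#' Aggregate G-value profiles over events
#'
#' Per-time mean and sample standard deviation across events (the default);
#' optionally also the pooled, deposit-weighted G
#' (`100 * sum(counts) / sum(edep)`).
#'
#' @param results List of `chem_result` objects on a common time grid.
#' @param edep_eV Numeric vector of per-event deposits.
#' @param weighted If `TRUE` include the pooled deposit-weighted mean as
#'   `G_pooled`.
#' @return Object of class `"gvalue_series"`: list with `time_ps`,
#'   `species`, `G_mean`, `G_sd` (species x time matrices), `n_events`, and
#'   optionally `G_pooled`.
#' @export
aggregate_events <- function(results, edep_eV, weighted = FALSE) {
  stopifnot(length(results) >= 2, length(results) == length(edep_eV))
  t0 <- results[[1]]$time_ps
  for (r in results)
    if (!isTRUE(all.equal(r$time_ps, t0)))
      stop("events sampled on mismatched time grids")
  G <- lapply(seq_along(results),
              function(i) g_value_profile(results[[i]], edep_eV[i]))
  arr <- simplify2array(G)                       # S x T x n
  G_mean <- apply(arr, c(1, 2), mean)
  G_sd <- apply(arr, c(1, 2), sd)
  dimnames(G_mean) <- dimnames(G_sd) <- dimnames(G[[1]])
  out <- list(time_ps = t0, species = rownames(results[[1]]$counts),
              G_mean = G_mean, G_sd = G_sd, n_events = length(results))
  if (weighted) {
    tot <- Reduce(`+`, lapply(results, function(r) r$counts))
    out$G_pooled <- g_value(tot, sum(edep_eV))
    dimnames(out$G_pooled) <- dimnames(G_mean)
  }
  class(out) <- "gvalue_series"
  out
}

#' @export
print.gvalue_series <- function(x, ...) {
  nt <- length(x$time_ps)
  cat("<gvalue_series>", x$n_events, "events,", nt, "times (",
      x$time_ps[1], "-", x$time_ps[nt], "ps )\n")
  cat("  G at", x$time_ps[nt], "ps:\n")
  print(round(cbind(mean = x$G_mean[, nt], sd = x$G_sd[, nt]), 3))
  invisible(x)
}

#' Tidy data frame from a G-value series
#' @param x A `gvalue_series`.
#' @param ... Unused.
#' @return Data frame `species, t_ps, G_mean, G_sd, n_events`.
#' @export
as.data.frame.gvalue_series <- function(x, ...) {
  data.frame(species = rep(x$species, times = length(x$time_ps)),
             t_ps = rep(x$time_ps, each = length(x$species)),
             G_mean = as.vector(x$G_mean), G_sd = as.vector(x$G_sd),
             n_events = x$n_events)
}

#' Run a calibrated ensemble of track events through the chemical stage
#'
#' Convenience driver behind the G-value validation workflows: generates
#' `n_events` synthetic 1 ps tracks and evolves each to the last sample
#' time.
#'
#' @param preset A [calibration_preset()] result (or `track_calibration`
#'   plus explicit `edep_eV`, `let_eV_nm` passed through `...`).
#' @param n_events Number of independent events.
#' @param sample_times Chemical-stage output grid in ps.
#' @param registry A `chem_registry`.
#' @param ... Passed to [simplified_track()].
#' @return List: `results` (list of `chem_result`), `edep_eV` (vector),
#'   `gv` (a `gvalue_series`).
#' @export
run_track_ensemble <- function(preset, n_events = 10,
                               sample_times = chem_sample_times(),
                               registry = default_registry(), ...) {
  results <- vector("list", n_events)
  edep <- numeric(n_events)
  for (i in seq_len(n_events)) {
    tr <- simplified_track(preset, registry = registry, ...)
    results[[i]] <- run_chemical_stage(tr$m, registry, sample_times)
    edep[i] <- tr$edep_eV
  }
  list(results = results, edep_eV = edep,
       gv = aggregate_events(results, edep))
}

#' LET scan of 1 us G-values
#'
#' For each beam energy (or LET), runs an ensemble of events and reports
#' the per-species G-value at the final sample time. The default engine
#' uses the calibrated track generator (LET from the proton stopping-power
#' table); the `"physics"` engine transports primaries through a cubic
#' target with cross-section tables, computes the LET from the mean
#' deposit, and hands the 1 ps populations to the chemical stage.
#'
#' @param energies_MeV Proton kinetic energies (0.5-100 MeV), or `NULL` if
#'   `lets_eV_nm` is given directly.
#' @param lets_eV_nm Optional explicit LET values (trackgen engine only).
#' @param n_events Events per energy.
#' @param engine `"trackgen"` or `"physics"`.
#' @param yields 1 ps yields used to calibrate the generator.
#' @param registry A `chem_registry`.
#' @param sample_times Chemical-stage output grid.
#' @param cube_nm Target cube edge for the physics engine (default 1 um).
#' @param tables Cross-section tables for the physics engine.
#' @param ... Passed to [simplified_track()].
#' @return Data frame `E_MeV, LET_eV_per_nm, species, G, sd`.
#' @export
let_scan <- function(energies_MeV = NULL, lets_eV_nm = NULL, n_events = 10,
                     engine = c("trackgen", "physics"),
                     yields = .preset_yields$p20MeV,
                     registry = default_registry(),
                     sample_times = chem_sample_times(),
                     cube_nm = 1000, tables = toy_xs_tables(), ...) {
  engine <- match.arg(engine)
  if (engine == "trackgen") {
    if (is.null(lets_eV_nm)) {
      if (is.null(energies_MeV) || !length(energies_MeV))
        stop("no energies given")
      lets_eV_nm <- proton_let_eV_nm(energies_MeV)
    } else if (is.null(energies_MeV)) {
      energies_MeV <- rep(NA_real_, length(lets_eV_nm))
    }
    cal <- calibrate(yields, registry)
    out <- list()
    for (k in seq_along(lets_eV_nm)) {
      let <- lets_eV_nm[k]
      ens <- run_track_ensemble(
        list(calibration = cal, let_eV_nm = let, edep_eV = let * cube_nm),
        n_events = n_events, sample_times = sample_times,
        registry = registry, ...)
      nt <- length(ens$gv$time_ps)
      out[[k]] <- data.frame(E_MeV = energies_MeV[k],
                             LET_eV_per_nm = let,
                             species = ens$gv$species,
                             G = ens$gv$G_mean[, nt],
                             sd = ens$gv$G_sd[, nt])
    }
    return(do.call(rbind, out))
  }
  if (is.null(energies_MeV) || !length(energies_MeV)) stop("no energies given")
  box <- list(lo = c(-cube_nm / 2, -cube_nm / 2, 0),
              hi = c(cube_nm / 2, cube_nm / 2, cube_nm))
  out <- list()
  for (k in seq_along(energies_MeV)) {
    results <- list(); edep <- numeric(0)
    for (i in seq_len(n_events)) {
      ev <- transport_event(particle_state("proton", energies_MeV[k] * 1e6,
                                           c(0, 0, 0), c(0, 0, 1)),
                            box, registry, tables)
      m <- build_initial_population(ev, registry, box = box)
      results[[i]] <- run_chemical_stage(m, registry, sample_times)
      edep[i] <- ev$edep_eV
    }
    let <- compute_let(edep, cube_nm)
    gv <- aggregate_events(results, pmax(edep, 1e-12))
    nt <- length(gv$time_ps)
    out[[k]] <- data.frame(E_MeV = energies_MeV[k], LET_eV_per_nm = let,
                           species = gv$species, G = gv$G_mean[, nt],
                           sd = gv$G_sd[, nt])
  }
  do.call(rbind, out)
}
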