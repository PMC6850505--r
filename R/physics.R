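#' Create a charged-particle state
#'
#' @param kind One of `"electron"`, `"proton"`, `"hydrogen"`, `"He0"`,
#'   `"He+"`, `"He++"`.
#' @param energy_eV Kinetic energy in eV.
#' @param position Length-3 position in nm.
#' @param direction Length-3 direction (normalised internally).
#' @param time_ps Creation time in ps.
#' @return An object of class `"particle_state"`.
#' @export
particle_state <- function(kind, energy_eV, position = c(0, 0, 0),
                           direction = c(0, 0, 1), time_ps = 0) {
  kind <- match.arg(kind, c("electron", "proton", "hydrogen",
                            "He0", "He+", "He++"))
  stopifnot(energy_eV >= 0, length(position) == 3, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm <= 0) stop("direction must be non-zero")
  structure(list(kind = kind, energy_eV = as.numeric(energy_eV),
                 position = as.numeric(position),
                 direction = as.numeric(direction) / nrm,
                 time_ps = as.numeric(time_ps), alive = TRUE),
            class = "particle_state")
}

# allowed discrete processes per particle kind (charge changing restricted
# to the physically allowed directions)
.allowed_processes <- list(
  electron = c("elastic", "excitation", "ionization", "vibrational",
               "attachment"),
  proton   = c("elastic", "excitation", "ionization", "charge_decrease"),
  hydrogen = c("elastic", "excitation", "ionization", "charge_increase"),
  He0      = c("elastic", "excitation", "ionization", "charge_increase"),
  "He+"    = c("elastic", "excitation", "ionization", "charge_increase",
               "charge_decrease"),
  "He++"   = c("elastic", "excitation", "ionization", "charge_decrease")
)

.charge_up <- c(hydrogen = "proton", He0 = "He+", "He+" = "He++")
.charge_down <- c(proton = "hydrogen", "He++" = "He+", "He+" = "He0")

#' Read cross-section tables
#'
#' Tables are stored in a structured YAML file: one entry per
#' (particle, process) with a strictly increasing energy grid (eV), total
#' cross sections per water molecule (nm^2) and a small sampler block
#' (energy-loss convention, binding energy, secondary-energy fraction,
#' angular model, excitation state tag). Totals are interpolated log-log
#' inside the grid range and are zero outside it.
#'
#' @param path YAML file path.
#' @return Object of class `"xs_tables"`: list of process tables.
#' @export
read_xs_tables <- function(path) {
  raw <- yaml::read_yaml(path)
  tabs <- lapply(raw$processes, function(p) {
    E <- as.numeric(unlist(p$E_eV))
    s <- as.numeric(unlist(p$sigma_nm2))
    if (length(E) < 2 || any(diff(E) <= 0))
      stop("energy grid must be strictly increasing (", p$particle, "/",
           p$process, ")")
    if (length(s) != length(E) || any(s < 0))
      stop("invalid cross sections (", p$particle, "/", p$process, ")")
    if (!p$process %in% .allowed_processes[[p$particle]])
      stop("process '", p$process, "' not allowed for ", p$particle)
    list(particle = p$particle, process = p$process,
         E_eV = E, sigma_nm2 = s,
         loss_eV = as.numeric(p$loss_eV %||% 0),
         binding_eV = as.numeric(p$binding_eV %||% 0),
         secondary_fraction_max = as.numeric(p$secondary_fraction_max %||% 0.5),
         secondary_max_eV = as.numeric(p$secondary_max_eV %||% Inf),
         angle = as.character(p$angle %||% "forward"),
         state = as.character(p$state %||% ""))
  })
  structure(tabs, class = "xs_tables")
}

#' Bundled toy cross-section tables
#'
#' A deliberately simple, self-consistent table set (constant and power-law
#' totals, fixed energy losses, uniform secondary spectra) that exercises
#' the whole transport pipeline without external data. It is not a
#' high-fidelity liquid-water model.
#' @return An `xs_tables` object.
#' @export
toy_xs_tables <- function() {
  read_xs_tables(system.file("extdata", "toy_cross_sections.yaml",
                             package = "trackchem", mustWork = TRUE))
}

# interpolated total cross section (log-log), zero outside the grid range
.xs_sigma <- function(tab, E) {
  if (E < tab$E_eV[1] || E > tab$E_eV[length(tab$E_eV)]) return(0)
  exp(stats::approx(log(tab$E_eV), log(pmax(tab$sigma_nm2, 1e-300)),
                    xout = log(E), rule = 2)$y)
}

#' Sample the next step length and process
#'
#' For every process applicable at the particle's energy an exponential
#' free path is drawn from its total cross section; the shortest step wins.
#'
#' @param p A `particle_state`.
#' @param tables An `xs_tables` object.
#' @param n_density Water molecule number density in 1/nm^3
#'   (see [number_density()]); density scaling of the medium enters here.
#' @return List `step_nm`, `process` (a process table entry), or
#'   `step_nm = Inf` with `process = NULL` when all cross sections vanish.
#' @export
sample_step_and_process <- function(p, tables, n_density) {
  best <- Inf; chosen <- NULL; any_valid <- FALSE
  for (tab in tables) {
    if (tab$particle != p$kind) next
    sig <- .xs_sigma(tab, p$energy_eV)
    if (sig <= 0) next
    any_valid <- TRUE
    s <- rexp(1, rate = n_density * sig)
    if (s < best) { best <- s; chosen <- tab }
  }
  if (!any_valid) return(list(step_nm = Inf, process = NULL))
  list(step_nm = best, process = chosen)
}

.iso_dir <- function() {
  z <- 2 * runif(1) - 1
  phi <- 2 * pi * runif(1)
  s <- sqrt(1 - z * z)
  c(s * cos(phi), s * sin(phi), z)
}

#' Apply a discrete interaction
#'
#' Updates the particle, and emits secondaries, local energy deposits and
#' water activations. Energy is conserved per interaction: the primary's
#' energy loss equals the local deposit plus secondary kinetic energy
#' (excitation and binding energies are counted as locally deposited).
#'
#' @param p A `particle_state`.
#' @param process A process table entry (from [sample_step_and_process()]).
#' @return List with `p` (updated), `secondaries` (list of
#'   `particle_state`), `deposits` (data frame `x_nm,y_nm,z_nm,amount_eV,
#'   process`), `activations` (data frame `x_nm,y_nm,z_nm,state,time_ps`).
#' @export
apply_interaction <- function(p, process) {
  if (!process$process %in% .allowed_processes[[p$kind]])
    stop("process '", process$process, "' invalid for particle kind '",
         p$kind, "'")
  pos <- p$position
  dep <- data.frame(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                    amount_eV = numeric(), process = character())
  act <- data.frame(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                    state = character(), time_ps = numeric())
  sec <- list()
  add_dep <- function(amount) {
    if (amount > 0)
      dep[nrow(dep) + 1L, ] <<- list(pos[1], pos[2], pos[3], amount,
                                     process$process)
  }
  add_act <- function(state) {
    act[nrow(act) + 1L, ] <<- list(pos[1], pos[2], pos[3], state, p$time_ps)
  }
  switch(process$process,
    elastic = {
      if (process$angle == "isotropic") p$direction <- .iso_dir()
    },
    vibrational = {
      loss <- min(process$loss_eV, p$energy_eV)
      p$energy_eV <- p$energy_eV - loss
      add_dep(loss)
    },
    excitation = {
      loss <- min(process$loss_eV, p$energy_eV)
      p$energy_eV <- p$energy_eV - loss
      add_dep(loss)
      add_act(process$state)
    },
    ionization = {
      b <- min(process$binding_eV, p$energy_eV)
      avail <- p$energy_eV - b
      es <- runif(1) * min(process$secondary_fraction_max * avail,
                           process$secondary_max_eV)
      p$energy_eV <- avail - es
      add_dep(b)
      add_act("ionized")
      sec[[1]] <- particle_state("electron", es, pos, .iso_dir(), p$time_ps)
    },
    attachment = {
      add_dep(p$energy_eV)
      add_act("dissoc_attachment")
      p$energy_eV <- 0
      p$alive <- FALSE
    },
    charge_increase = {
      loss <- min(process$loss_eV, p$energy_eV)
      p$energy_eV <- p$energy_eV - loss
      add_dep(loss)
      p$kind <- .charge_up[[p$kind]]
    },
    charge_decrease = {
      loss <- min(process$loss_eV, p$energy_eV)
      p$energy_eV <- p$energy_eV - loss
      add_dep(loss)
      p$kind <- .charge_down[[p$kind]]
    },
    stop("unknown process '", process$process, "'")
  )
  list(p = p, secondaries = sec, deposits = dep, activations = act)
}

.tracking_cut <- function(kind, registry) {
  cuts <- registry$constants$tracking_cuts_eV
  as.numeric(cuts[[kind]] %||% 0)
}

#' Transport one primary particle (an event)
#'
#' Discrete step-by-step transport of the primary and all its secondaries
#' (LIFO track stack) until each particle falls below its tracking cut or
#' leaves the box. Below the cut the remaining kinetic energy is deposited
#' locally. Electrons reaching the sub-excitation threshold (8.22 eV) leave
#' the loop as solvation candidates (their residual energy is deposited at
#' the stopping point and recorded for the thermalisation law).
#'
#' @param primary A `particle_state` inside the box.
#' @param box List with `lo`, `hi` (length-3, nm).
#' @param registry A `chem_registry` (tracking cuts, density, thresholds).
#' @param tables An `xs_tables` object.
#' @param density_scale Medium density multiplier (scales all interaction
#'   probabilities per unit length).
#' @param max_iter Failsafe bound on interactions per event.
#' @return List: `deposits`, `activations`, `solvation` (data frame
#'   `x_nm,y_nm,z_nm,energy_eV,time_ps`), `edep_eV` (total deposited),
#'   `escaped_eV` (kinetic energy carried out of the box).
#' @export
transport_event <- function(primary, box, registry = default_registry(),
                            tables = toy_xs_tables(), density_scale = 1,
                            max_iter = 1e6) {
  stopifnot(inherits(primary, "particle_state"))
  inside <- function(q) all(q >= box$lo) && all(q <= box$hi)
  if (!inside(primary$position)) stop("primary starts outside the box")
  nden <- number_density(registry, density_scale)
  sub_exc <- registry$constants$sub_excitation_threshold_eV
  stack <- list(primary)
  deposits <- list(); activations <- list()
  solvation <- data.frame(x_nm = numeric(), y_nm = numeric(),
                          z_nm = numeric(), energy_eV = numeric(),
                          time_ps = numeric())
  escaped <- 0
  iter <- 0
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    while (p$alive) {
      iter <- iter + 1
      if (iter > max_iter) stop("transport exceeded max_iter interactions")
      cut <- .tracking_cut(p$kind, registry)
      stop_energy <- if (p$kind == "electron") max(cut, sub_exc) else cut
      if (p$energy_eV <= stop_energy) {
        if (p$energy_eV > 0)
          deposits[[length(deposits) + 1L]] <-
            data.frame(x_nm = p$position[1], y_nm = p$position[2],
                       z_nm = p$position[3], amount_eV = p$energy_eV,
                       process = "tracking_cut")
        if (p$kind == "electron" && p$energy_eV <= sub_exc &&
            p$energy_eV > cut)
          solvation[nrow(solvation) + 1L, ] <-
            list(p$position[1], p$position[2], p$position[3],
                 p$energy_eV, p$time_ps)
        p$alive <- FALSE
        break
      }
      st <- sample_step_and_process(p, tables, nden)
      if (is.null(st$process)) {
        if (is.infinite(st$step_nm))
          stop("no applicable process for ", p$kind, " at ",
               p$energy_eV, " eV (mis-built tables)")
      }
      newpos <- p$position + st$step_nm * p$direction
      if (!inside(newpos)) {           # leaves the geometry
        escaped <- escaped + p$energy_eV
        p$alive <- FALSE
        break
      }
      p$position <- newpos
      res <- apply_interaction(p, st$process)
      p <- res$p
      if (nrow(res$deposits))
        deposits[[length(deposits) + 1L]] <- res$deposits
      if (nrow(res$activations))
        activations[[length(activations) + 1L]] <- res$activations
      for (s in res$secondaries) stack[[length(stack) + 1L]] <- s
    }
  }
  deposits <- if (length(deposits)) do.call(rbind, deposits) else
    data.frame(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
               amount_eV = numeric(), process = character())
  activations <- if (length(activations)) do.call(rbind, activations) else
    data.frame(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
               state = character(), time_ps = numeric())
  list(deposits = deposits, activations = activations,
       solvation = solvation, edep_eV = sum(deposits$amount_eV),
       escaped_eV = escaped)
}

#' Radial dose distribution
#'
#' Scores energy deposits into concentric cylindrical shells around the
#' beam axis (z), with logarithmically spaced radii, and converts to dose.
#'
#' @param deposits Data frame `x_nm,y_nm,z_nm,amount_eV` pooled over events.
#' @param n_events Number of incident particles (normalisation).
#' @param inner_nm,outer_nm Radial scoring range (defaults 1 and 250 nm).
#' @param n_shells Number of logarithmic shells (default 100).
#' @param height_nm Cylinder height along z from 0 (default 10 um).
#' @param density_g_cm3 Medium density.
#' @return Data frame `r_lo_nm, r_hi_nm, r_mid_nm, edep_eV, dose_Gy`
#'   (dose per incident particle). Deposits outside the radial range or the
#'   height are ignored.
#' @export
radial_dose <- function(deposits, n_events = 1, inner_nm = 1,
                        outer_nm = 250, n_shells = 100, height_nm = 1e4,
                        density_g_cm3 = 1) {
  if (inner_nm <= 0 || outer_nm <= inner_nm)
    stop("need 0 < inner < outer radius")
  edges <- 10^seq(log10(inner_nm), log10(outer_nm), length.out = n_shells + 1)
  r <- sqrt(deposits$x_nm^2 + deposits$y_nm^2)
  keep <- r >= inner_nm & r <= outer_nm &
    deposits$z_nm >= 0 & deposits$z_nm <= height_nm
  bin <- cut(r[keep], breaks = edges, include.lowest = TRUE, labels = FALSE)
  e <- vapply(seq_len(n_shells),
              function(k) sum(deposits$amount_eV[keep][bin == k]), 0)
  vol <- pi * (edges[-1]^2 - edges[-(n_shells + 1)]^2) * height_nm  # nm^3
  # 1 eV / (g/cm^3 * nm^3) = 1.602176634e5 Gy
  dose <- e / n_events / (density_g_cm3 * vol) * 1.602176634e5
  data.frame(r_lo_nm = edges[-(n_shells + 1)], r_hi_nm = edges[-1],
             r_mid_nm = sqrt(edges[-(n_shells + 1)] * edges[-1]),
             edep_eV = e / n_events, dose_Gy = dose)
}

#' Linear energy transfer from per-event deposits
#'
#' LET is the mean total energy deposited per event divided by the path
#' length through the target; eV/nm is numerically equal to keV/um.
#'
#' @param event_edep_eV Numeric vector, total deposit per event (zero-deposit
#'   events included).
#' @param path_length_nm Traversed path length through the target.
#' @return LET in eV/nm.
#' @export
compute_let <- function(event_edep_eV, path_length_nm) {
  if (!length(event_edep_eV)) stop("no events")
  stopifnot(path_length_nm > 0)
  mean(event_edep_eV) / path_length_nm
}
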