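# Discrete physics transport on tabulated cross sections.

# tiny in-code table sets for controlled sampling checks
single_process_tables <- function(sigma, process = "ionization",
                                  binding = 20, fmax = 0) {
  structure(list(list(particle = "electron", process = process,
                      E_eV = c(10, 1e6), sigma_nm2 = c(sigma, sigma),
                      loss_eV = 0, binding_eV = binding,
                      secondary_fraction_max = fmax,
                      secondary_max_eV = Inf,
                      angle = "forward", state = "")),
            class = "xs_tables")
}

test_that("free paths are exponential with mean 1/(n sigma)", {
  reg <- default_registry()
  n <- number_density(reg)
  tabs <- single_process_tables(2e-4)
  p <- particle_state("electron", 1000)
  set.seed(21)
  steps <- vapply(1:20000, function(i)
    sample_step_and_process(p, tabs, n)$step_nm, 0)
  expect_equal(mean(steps), 1 / (n * 2e-4), tolerance = 0.02)
  # doubling the density halves the mean free path
  set.seed(22)
  steps2 <- vapply(1:20000, function(i)
    sample_step_and_process(p, tabs, number_density(reg, 2))$step_nm, 0)
  expect_equal(mean(steps2), mean(steps) / 2, tolerance = 0.03)
})

test_that("competing processes are selected by their cross sections", {
  reg <- default_registry()
  n <- number_density(reg)
  tabs <- structure(list(
    list(particle = "electron", process = "ionization", E_eV = c(10, 1e6),
         sigma_nm2 = c(2e-4, 2e-4), loss_eV = 0, binding_eV = 20,
         secondary_fraction_max = 0, secondary_max_eV = Inf,
         angle = "forward", state = ""),
    list(particle = "electron", process = "excitation", E_eV = c(10, 1e6),
         sigma_nm2 = c(1e-4, 1e-4), loss_eV = 10, binding_eV = 0,
         secondary_fraction_max = 0, secondary_max_eV = Inf,
         angle = "forward", state = "A1B1")), class = "xs_tables")
  p <- particle_state("electron", 1000)
  set.seed(23)
  sel <- vapply(1:20000, function(i)
    sample_step_and_process(p, tabs, n)$process$process, "")
  expect_equal(mean(sel == "ionization"), 2 / 3, tolerance = 0.02)
  # vanishing cross sections: no applicable process, infinite step
  p2 <- particle_state("electron", 5)  # below both grids
  expect_equal(sample_step_and_process(p2, tabs, n)$step_nm, Inf)
})

test_that("interactions conserve energy and emit the right products", {
  tabs <- toy_xs_tables()
  ion <- Filter(function(t) t$particle == "electron" &&
                  t$process == "ionization", tabs)[[1]]
  set.seed(24)
  p <- particle_state("electron", 1000)
  res <- apply_interaction(p, ion)
  expect_length(res$secondaries, 1)
  expect_equal(res$activations$state, "ionized")
  dE <- 1000 - res$p$energy_eV
  expect_equal(dE, sum(res$deposits$amount_eV) +
                 res$secondaries[[1]]$energy_eV, tolerance = 1e-9)

  exc <- Filter(function(t) t$particle == "electron" &&
                  t$process == "excitation" && t$state == "A1B1", tabs)[[1]]
  res <- apply_interaction(p, exc)
  expect_equal(res$activations$state, "A1B1")
  expect_equal(1000 - res$p$energy_eV, sum(res$deposits$amount_eV))

  ela <- Filter(function(t) t$particle == "electron" &&
                  t$process == "elastic", tabs)[[1]]
  res <- apply_interaction(p, ela)
  expect_equal(res$p$energy_eV, 1000)
  expect_equal(nrow(res$deposits), 0)

  att <- Filter(function(t) t$particle == "electron" &&
                  t$process == "attachment", tabs)[[1]]
  res <- apply_interaction(particle_state("electron", 6), att)
  expect_false(res$p$alive)
  expect_equal(res$activations$state, "dissoc_attachment")
  expect_equal(sum(res$deposits$amount_eV), 6)

  # charge exchange obeys the allowed directions
  cd <- Filter(function(t) t$particle == "He++" &&
                 t$process == "charge_decrease", tabs)[[1]]
  res <- apply_interaction(particle_state("He++", 1e4), cd)
  expect_equal(res$p$kind, "He+")
  expect_error(apply_interaction(particle_state("He0", 1e4), cd),
               "invalid for particle kind")
})

test_that("transport stops at cuts, thresholds and the box boundary", {
  reg <- default_registry()
  box <- list(lo = c(-500, -500, 0), hi = c(500, 500, 1000))
  # below the 7.4 eV electron cut: immediate local deposit, nothing else
  ev <- transport_event(particle_state("electron", 7.0, c(0, 0, 500)),
                        box, reg)
  expect_equal(ev$edep_eV, 7.0)
  expect_equal(ev$deposits$process, "tracking_cut")
  expect_equal(nrow(ev$activations), 0)
  expect_equal(nrow(ev$solvation), 0)
  # between the cut and the 8.22 eV solvation threshold: a candidate
  ev <- transport_event(particle_state("electron", 8.0, c(0, 0, 500)),
                        box, reg)
  expect_equal(nrow(ev$solvation), 1)
  expect_equal(ev$solvation$energy_eV, 8.0)
  # aimed outward from a face: no deposits, full energy escapes
  ev <- transport_event(particle_state("electron", 1000, c(0, 0, 0),
                                       c(0, 0, -1)), box, reg)
  expect_equal(nrow(ev$deposits), 0)
  expect_equal(ev$escaped_eV, 1000)
  expect_error(transport_event(particle_state("electron", 100,
                                              c(0, 0, -10)), box, reg),
               "outside the box")
})

test_that("per-event energy is conserved and bounded", {
  reg <- default_registry()
  box <- list(lo = rep(-2000, 3), hi = rep(2000, 3))
  set.seed(25)
  for (E0 in c(200, 1000, 5000)) {
    ev <- transport_event(particle_state("electron", E0), box, reg)
    expect_equal(ev$edep_eV + ev$escaped_eV, E0, tolerance = 1e-9)
    expect_lte(ev$edep_eV, E0 + 1e-9)
  }
  # fixed-loss ionization-only table: a 100 eV electron cannot make more
  # than 5 activations (energy bookkeeping bound, 20 eV per interaction)
  tabs <- single_process_tables(5e-4, binding = 20, fmax = 0)
  set.seed(26)
  for (i in 1:20) {
    ev <- transport_event(particle_state("electron", 100), box, reg, tabs)
    expect_lte(nrow(ev$activations), 5)
    expect_equal(ev$edep_eV + ev$escaped_eV, 100, tolerance = 1e-9)
  }
})

test_that("radial dose bins deposits into logarithmic shells", {
  # default geometry: 100 log-spaced shells from 1 to 250 nm
  dep <- data.frame(x_nm = 5, y_nm = 0, z_nm = 100, amount_eV = 100)
  rd <- radial_dose(dep)
  expect_equal(nrow(rd), 100)
  expect_equal(rd$r_lo_nm[1], 1)
  expect_equal(rd$r_hi_nm[100], 250)
  expect_equal(diff(log(rd$r_lo_nm)), rep(log(250) / 100, 99))
  hit <- which(rd$edep_eV > 0)
  expect_length(hit, 1)
  expect_true(rd$r_lo_nm[hit] <= 5 && rd$r_hi_nm[hit] >= 5)
  V <- pi * (rd$r_hi_nm[hit]^2 - rd$r_lo_nm[hit]^2) * 1e4
  expect_equal(rd$dose_Gy[hit], 100 / V * 1.602176634e5, tolerance = 1e-12)
  # shell volumes close under the cylinder volume formula
  vols <- pi * (rd$r_hi_nm^2 - rd$r_lo_nm^2) * 1e4
  expect_equal(sum(vols), pi * (250^2 - 1^2) * 1e4, tolerance = 1e-9)
  # out-of-range deposits are ignored
  far <- data.frame(x_nm = 300, y_nm = 0, z_nm = 100, amount_eV = 50)
  expect_equal(sum(radial_dose(far)$edep_eV), 0)
  expect_error(radial_dose(dep, inner_nm = 0), "inner")
})

test_that("LET is the mean deposit over the path, ordered in proton energy", {
  expect_equal(compute_let(c(300, 500), 1000), 0.4)
  expect_equal(compute_let(c(300, 500, 0, 0), 1000), 0.2)  # zeros included
  expect_error(compute_let(numeric(), 1000), "no events")

  reg <- default_registry()
  tabs <- toy_xs_tables()
  cube <- list(lo = c(-500, -500, 0), hi = c(500, 500, 1000))
  set.seed(27)
  let_at <- function(E_MeV, n = 8) {
    dep <- vapply(1:n, function(i)
      transport_event(particle_state("proton", E_MeV * 1e6, c(0, 0, 0),
                                     c(0, 0, 1)), cube, reg, tabs)$edep_eV, 0)
    compute_let(dep, 1000)
  }
  expect_gt(let_at(5), let_at(20))
})
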