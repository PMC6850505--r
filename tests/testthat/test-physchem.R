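# Physicochemical stage: dissociation branching, electron solvation,
# population assembly.

test_that("dissociation channels follow the branching table", {
  reg <- default_registry()
  act <- list(x_nm = 0, y_nm = 0, z_nm = 0, state = "ionized")
  set.seed(30)
  for (i in 1:20) {
    d <- dissociate(act, reg)
    expect_setequal(d$molecules$species, c("H3O+", "OH"))
    expect_equal(nrow(d$eaq_candidates), 0)
  }
  expect_error(dissociate(list(x_nm = 0, y_nm = 0, z_nm = 0,
                               state = "plasma"), reg), "unknown")

  # A1B1 branching: 65% dissociative (OH + H), 35% relaxation (nothing)
  act$state <- "A1B1"
  set.seed(31)
  n <- 30000
  modes <- character(n)
  for (i in 1:n) modes[i] <- dissociate(act, reg)$mode
  obs <- table(factor(modes, c("dissociative_decay", "relaxation")))
  expect_gt(chisq.test(obs, p = c(0.65, 0.35))$p.value, 0.001)
  expect_equal(unname(obs[1] / n), 0.65, tolerance = 0.02)

  # auto-ionization yields an e_aq candidate besides the heavy fragments
  act$state <- "rydberg_diffuse"
  set.seed(32)
  saw_auto <- FALSE
  for (i in 1:50) {
    d <- dissociate(act, reg)
    if (d$mode == "auto_ionization") {
      saw_auto <- TRUE
      expect_setequal(d$molecules$species, c("H3O+", "OH"))
      expect_equal(nrow(d$eaq_candidates), 1)
    } else {
      expect_equal(nrow(d$molecules), 0)
    }
  }
  expect_true(saw_auto)
})

test_that("fragments separate by the configured distance, isotropically", {
  reg <- default_registry()
  act <- list(x_nm = 1, y_nm = 2, z_nm = 3, state = "A1B1")
  set.seed(33)
  seps <- c(); disp <- NULL
  while (length(seps) < 500) {
    d <- dissociate(act, reg, separation_nm = 0.8)
    if (d$mode != "dissociative_decay") next
    seps <- c(seps, sqrt(sum((as.numeric(d$molecules[1, 2:4]) -
                                as.numeric(d$molecules[2, 2:4]))^2)))
    disp <- rbind(disp, as.numeric(d$molecules[1, 2:4]) - c(1, 2, 3))
  }
  expect_equal(seps, rep(0.8, 500), tolerance = 1e-9)
  # fragment axis is isotropic: mean displacement compatible with zero
  expect_true(all(abs(colMeans(disp)) < 3 * 0.4 / sqrt(3) / sqrt(500)))
})

test_that("electron thermalisation follows the displacement law", {
  cand <- list(x_nm = 5, y_nm = 5, z_nm = 5)
  e <- thermalize_electron(cand, law = list(type = "none"))
  expect_equal(as.numeric(e[1, 2:4]), c(5, 5, 5))
  set.seed(34)
  n <- 20000
  d <- matrix(0, n, 3)
  for (i in 1:n)
    d[i, ] <- as.numeric(thermalize_electron(
      cand, law = list(type = "exponential", mean_nm = 6))[1, 2:4]) - 5
  r <- sqrt(rowSums(d^2))
  expect_equal(mean(r), 6, tolerance = 0.02)
  # isotropy: mean vector within 3 standard errors of zero
  se <- sd(r) / sqrt(3) / sqrt(n) * sqrt(3)  # per-axis spread ~ r/sqrt(3)
  expect_true(all(abs(colMeans(d)) < 3 * sqrt(mean(r^2) / 3) / sqrt(n)))
})

test_that("initial populations assemble from activations and candidates", {
  reg <- default_registry()
  empty <- list(activations = data.frame(x_nm = numeric(), y_nm = numeric(),
                                         z_nm = numeric(), state = character(),
                                         time_ps = numeric()),
                solvation = NULL)
  m <- build_initial_population(empty, reg)
  expect_equal(sum(m$alive), 0)
  expect_equal(m$time_ps, 1)

  # one ionization plus its stopped secondary: H3O+, OH, e_aq
  ev <- list(activations = data.frame(x_nm = 0, y_nm = 0, z_nm = 0,
                                      state = "ionized", time_ps = 0),
             solvation = data.frame(x_nm = 1, y_nm = 0, z_nm = 0,
                                    energy_eV = 5, time_ps = 0.1))
  set.seed(35)
  m <- build_initial_population(ev, reg)
  cnt <- species_counts(m)
  expect_equal(cnt[["H3O+"]], 1)
  expect_equal(cnt[["OH"]], 1)
  expect_equal(cnt[["e_aq"]], 1)
  expect_equal(sum(cnt), 3)
})

test_that("full physics path yields obey the branching stoichiometry", {
  # ionization-like channels give {H3O+, OH, e_aq}, A1B1 decay {OH, H},
  # B1A1 decay {2 OH, H2}, attachment {OH, OH-, H2}; two identities follow:
  #   OH  = H3O+ + H + 2 H2 - OH-
  #   H3O+ - e_aq = n_ionized_activations - n_solvation_candidates
  reg <- default_registry()
  tabs <- toy_xs_tables()
  box <- list(lo = rep(-2000, 3), hi = rep(2000, 3))
  set.seed(36)
  for (i in 1:6) {
    ev <- transport_event(particle_state("electron", 2000), box, reg, tabs)
    m <- build_initial_population(ev, reg)
    cnt <- species_counts(m)
    expect_equal(cnt[["OH"]],
                 cnt[["H3O+"]] + cnt[["H"]] + 2 * cnt[["H2"]] - cnt[["OH-"]])
    n_ion <- sum(ev$activations$state == "ionized")
    expect_equal(cnt[["H3O+"]] - cnt[["e_aq"]], n_ion - nrow(ev$solvation))
    expect_equal(cnt[["H2O2"]], 0)
  }
})
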