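# The four chemical-stage kernels, unit-level.

test_that("candidate pair search matches a brute-force oracle", {
  reg <- default_registry()
  expect_equal(nrow(find_candidate_pairs(
    molecule_set("OH", matrix(0, 1, 3)), reg)), 0)
  m <- molecule_set(c("e_aq", "OH", "H2"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  p <- find_candidate_pairs(m, reg)
  expect_equal(nrow(p), 1)
  expect_equal(reg$reactions$products[[p$reaction]], "OH-")

  set.seed(301)
  for (rep in 1:5) {
    m <- random_molecule_set(50)
    p <- find_candidate_pairs(m, reg)
    # oracle: plain double loop over all molecule pairs
    exp_pairs <- list()
    for (i in 1:49) for (j in (i + 1):50) {
      rx <- lookup_reaction(reg, m$species_names[m$species[i]],
                            m$species_names[m$species[j]])
      if (!is.null(rx))
        exp_pairs[[length(exp_pairs) + 1]] <-
          c(i, j, sqrt(sum((m$pos[i, ] - m$pos[j, ])^2)))
    }
    oracle <- do.call(rbind, exp_pairs)
    expect_equal(nrow(p), nrow(oracle))
    key <- function(i, j) paste(i, j)
    expect_setequal(key(p$i, p$j), key(oracle[, 1], oracle[, 2]))
    o <- match(key(p$i, p$j), key(oracle[, 1], oracle[, 2]))
    expect_equal(p$d_nm, oracle[o, 3])
    expect_true(!is.unsorted(p$d_nm))
  }
})

test_that("contact reactions respect the radius and conflict resolution", {
  reg <- default_registry()
  R_eaq_oh <- lookup_reaction(reg, "e_aq", "OH")$radius_nm  # about 0.506

  react_at <- function(d) {
    m <- toy_pair("e_aq", "OH", d)
    react_contacts(find_candidate_pairs(m, reg), m, reg)
  }
  rc <- react_at(0.40)
  expect_equal(nrow(rc$events), 1)
  expect_equal(species_counts(rc$m)[["OH-"]], 1)
  expect_equal(sum(rc$m$alive), 1)
  rc <- react_at(0.60)
  expect_equal(nrow(rc$events), 0)
  expect_true(0.40 < R_eaq_oh && R_eaq_oh < 0.60)

  # three mutually close OH: exactly one H2O2 forms, one OH survives
  m <- molecule_set(rep("OH", 3),
                    rbind(c(0, 0, 0), c(0.05, 0, 0), c(0, 0.05, 0)))
  rc <- react_contacts(find_candidate_pairs(m, reg), m, reg)
  cnt <- species_counts(rc$m)
  expect_equal(nrow(rc$events), 1)
  expect_equal(cnt[["H2O2"]], 1)
  expect_equal(cnt[["OH"]], 1)
})

test_that("product placement follows the midpoint/parent rule", {
  reg <- default_registry()
  # single product at the midpoint
  rx <- lookup_reaction(reg, "H", "H")
  expect_equal(place_products(rx, c(0, 0, 0), c(2, 0, 0)),
               matrix(c(1, 0, 0), 1))
  # two products inherit parent positions in product order
  rx <- lookup_reaction(reg, "e_aq", "H2O2")  # OH- + OH
  pp <- place_products(rx, c(1, 2, 3), c(4, 5, 6))
  expect_equal(pp[1, ], c(1, 2, 3))  # OH- at the e_aq position
  expect_equal(pp[2, ], c(4, 5, 6))  # OH at the H2O2 position
  # three products: extras at the midpoint
  rx <- lookup_reaction(reg, "e_aq", "e_aq")  # H2 + 2 OH-
  pp <- place_products(rx, c(0, 0, 0), c(2, 0, 0))
  expect_equal(nrow(pp), 3)
  expect_equal(pp[3, ], c(1, 0, 0))
  # a reaction with no tracked products (water only) places nothing
  rx <- lookup_reaction(reg, "H3O+", "OH-")
  expect_equal(nrow(place_products(rx, c(0, 0, 0), c(1, 0, 0))), 0)
})

test_that("dynamic time step follows the minimal-distance pair", {
  reg <- default_registry()
  # contact limit: d_min = R gives a raw step of zero, clamped to 1 ps
  R <- lookup_reaction(reg, "OH", "OH")$radius_nm
  m <- toy_pair("OH", "OH", R)
  pairs <- find_candidate_pairs(m, reg)
  st <- compute_time_step(m, pairs, reg)
  expect_equal(st$dt_raw_ps, 0)
  expect_equal(st$dt_ps, 1)
  expect_true(st$clamped)
  # OH pair with a 1 nm gap: (1 nm)^2 / (32 * D_OH)
  m <- toy_pair("OH", "OH", R + 1)
  st <- compute_time_step(m, find_candidate_pairs(m, reg), reg)
  D <- reg$species$D_nm2_ps[reg$species$name == "OH"]
  expect_equal(st$dt_raw_ps, 1 / (32 * D), tolerance = 1e-12)
  expect_equal(st$dt_raw_ps, 11.16, tolerance = 1e-3)
  expect_false(st$clamped)
  # equal-D identity: 8(2 sqrt(D))^2 = 32 D for any equal-coefficient pair
  m <- toy_pair("H", "H", 2)
  st <- compute_time_step(m, find_candidate_pairs(m, reg), reg)
  DH <- reg$species$D_nm2_ps[reg$species$name == "H"]
  RH <- lookup_reaction(reg, "H", "H")$radius_nm
  expect_equal(st$dt_raw_ps, (2 - RH)^2 / (32 * DH))
  # no pairs: run to the next checkpoint
  m <- molecule_set("H2", matrix(0, 1, 3))
  st <- compute_time_step(m, find_candidate_pairs(m, reg), reg, t_next = 10)
  expect_equal(st$dt_ps, 9)
  expect_false(st$clamped)
})

test_that("diffusion obeys the Einstein relation and removes escapers", {
  reg <- default_registry()
  m <- molecule_set("H3O+", matrix(0, 1, 3))
  m0 <- diffuse(m, 0, reg)
  expect_equal(m0$pos, m$pos)

  set.seed(42)
  n <- 20000
  m <- molecule_set(rep("H3O+", n), matrix(0, n, 3))
  m <- diffuse(m, 1, reg)
  msd <- mean(rowSums(m$pos^2))
  expect_equal(msd, 6 * 9e-3 * 1, tolerance = 0.02)   # (0.2324 nm)^2
  expect_equal(sqrt(6 * 9e-3), 0.2324, tolerance = 1e-3)

  # exit removal is permanent
  m <- molecule_set(rep("H3O+", 500), matrix(0.5, 500, 3),
                    box = list(lo = rep(0, 3), hi = rep(1, 3)))
  m <- diffuse(m, 50, reg)  # rms per axis about 0.95 nm: most escape
  expect_gt(attr(m, "n_exited"), 400)
  expect_equal(sum(m$alive) + attr(m, "n_exited"), 500)
})

test_that("bridge probability has the contact and decay limits", {
  expect_equal(bridge_probability(0.3, 0.5, 0.3, 5.6e-3, 1), 1)  # d_i = R
  expect_equal(bridge_probability(0.5, 0.3, 0.3, 5.6e-3, 1), 1)  # d_f = R
  # (0.1 nm)(0.1 nm) / (5.6e-3 nm^2/ps * 1 ps)
  expect_equal(bridge_probability(0.4, 0.4, 0.3, 5.6e-3, 1),
               exp(-0.01 / 5.6e-3), tolerance = 1e-12)
  expect_equal(bridge_probability(0.4, 0.4, 0.3, 5.6e-3, 1), 0.1676,
               tolerance = 1e-3)
  expect_lt(bridge_probability(1.3, 1.3, 0.3, 5.6e-3, 1), 1e-50)
  # p in [0, 1] always; p = 1 iff an endpoint is inside R
  set.seed(7)
  di <- runif(500, 0, 3); df <- runif(500, 0, 3)
  p <- bridge_probability(di, df, 0.5, 7.7e-3, 1)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p == 1, di <= 0.5 | df <= 0.5)
})

test_that("unclamped steps rarely end inside the reaction radius", {
  # statistical form of the step-safety guarantee: diffusing an OH pair over
  # its own unclamped step, the end-inside-R fraction stays below 2%
  reg <- default_registry()
  R <- lookup_reaction(reg, "OH", "OH")$radius_nm
  D <- reg$species$D_nm2_ps[reg$species$name == "OH"]
  set.seed(11)
  inside <- 0
  n <- 10000
  for (d0 in c(R + 0.3, R + 1)) {
    dt <- (d0 - R)^2 / (32 * D)
    sd1 <- sqrt(2 * D * dt)
    a <- matrix(rnorm(3 * n, 0, sd1), ncol = 3)
    b <- matrix(rnorm(3 * n, 0, sd1), ncol = 3) + matrix(c(d0, 0, 0), n, 3,
                                                         byrow = TRUE)
    df <- sqrt(rowSums((a - b)^2))
    expect_lt(mean(df < R), 0.02)
  }
})
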