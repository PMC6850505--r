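#' Create a molecular population
#'
#' The chemical-stage state: positions (nm), species, alive flags, current
#' time (ps) and the simulation box. Species names must exist in the
#' registry.
#'
#' @param species Character vector of species names (one per molecule).
#' @param positions Numeric N x 3 matrix of positions in nm.
#' @param time_ps Population time stamp in ps.
#' @param box `NULL` (unbounded) or a list with numeric length-3 `lo`, `hi`.
#' @param registry A `chem_registry`; defines the species name space.
#' @return An object of class `"molecule_set"`.
#' @export
molecule_set <- function(species, positions, time_ps = 1,
                         box = NULL, registry = default_registry()) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  stopifnot(length(species) == nrow(positions))
  idx <- match(species, registry$species$name)
  if (anyNA(idx))
    stop("unknown species: ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  if (!is.null(box)) {
    stopifnot(length(box$lo) == 3, length(box$hi) == 3, all(box$hi > box$lo))
    inside <- positions[, 1] >= box$lo[1] & positions[, 1] <= box$hi[1] &
      positions[, 2] >= box$lo[2] & positions[, 2] <= box$hi[2] &
      positions[, 3] >= box$lo[3] & positions[, 3] <= box$hi[3]
    if (!all(inside)) stop("molecules outside the simulation box")
  }
  structure(list(pos = positions, species = as.integer(idx),
                 alive = rep(TRUE, length(idx)),
                 time_ps = as.numeric(time_ps), box = box,
                 species_names = registry$species$name),
            class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("<molecule_set> t =", x$time_ps, "ps;",
      sum(x$alive), "alive /", length(x$alive), "total\n")
  tab <- species_counts(x)
  tab <- tab[tab > 0]
  if (length(tab))
    cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Alive-molecule counts per species
#' @param m A `molecule_set`.
#' @return Named integer vector over all registry species.
#' @export
species_counts <- function(m) {
  out <- setNames(integer(length(m$species_names)), m$species_names)
  t <- table(factor(m$species_names[m$species[m$alive]],
                    levels = m$species_names))
  out[names(t)] <- as.integer(t)
  out
}

#' Find candidate reactant pairs
#'
#' All unordered pairs of alive molecules whose species have a reaction
#' channel, with their intermolecular distances. The reference
#' implementation is an exhaustive O(N^2/2) scan; `cutoff` restricts the
#' result to pairs within a distance (used by the grid-accelerated engine,
#' which must return the identical set for any configuration).
#'
#' @param m A `molecule_set`.
#' @param registry A `chem_registry`.
#' @param cutoff Maximum pair distance in nm (`Inf` = exhaustive).
#' @return Data frame with columns `i`, `j` (i < j), `reaction` (row index
#'   into `registry$reactions`), `d_nm`, ordered by increasing distance with
#'   stable index tie-break.
#' @export
find_candidate_pairs <- function(m, registry, cutoff = Inf) {
  comp <- .compile_registry(registry)
  idx <- which(m$alive)
  empty <- data.frame(i = integer(), j = integer(), reaction = integer(),
                      d_nm = numeric())
  if (length(idx) < 2) return(empty)
  cmb <- utils::combn(idx, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  rx <- comp$pair[cbind(m$species[i], m$species[j])]
  keep <- rx > 0L
  i <- i[keep]; j <- j[keep]; rx <- rx[keep]
  if (!length(i)) return(empty)
  dx <- m$pos[i, 1] - m$pos[j, 1]
  dy <- m$pos[i, 2] - m$pos[j, 2]
  dz <- m$pos[i, 3] - m$pos[j, 3]
  d2 <- dx * dx + dy * dy + dz * dz
  keep <- d2 <= cutoff * cutoff
  out <- data.frame(i = i[keep], j = j[keep], reaction = rx[keep],
                    d_nm = sqrt(d2[keep]))
  out[order(out$d_nm, out$i, out$j), , drop = FALSE]
}

# product positions for one reaction event; pos_a corresponds to the
# molecule matching the reaction's first reactant.
#' Positions for reaction products
#'
#' Placement rule: a single product sits at the reactants' midpoint; two
#' products inherit the two parent positions (assigned stably in product
#' order, first product to the first-listed reactant); any third product
#' (the 2 e_aq channel) sits at the midpoint.
#'
#' @param reaction One-row data frame from `registry$reactions`.
#' @param pos_a,pos_b Length-3 parent positions (nm); `pos_a` belongs to the
#'   molecule matching `reaction$a`.
#' @return Matrix (n_products x 3) of product positions.
#' @export
place_products <- function(reaction, pos_a, pos_b) {
  np <- reaction$n_products
  mid <- (pos_a + pos_b) / 2
  if (np == 0) return(matrix(numeric(), 0, 3))
  if (np == 1) return(matrix(mid, 1, 3, byrow = TRUE))
  out <- rbind(pos_a, pos_b)
  if (np == 3) out <- rbind(out, mid)
  unname(out)
}

#' Contact reactions
#'
#' Every candidate pair closer than its reaction radius reacts, subject to
#' conflict resolution: pairs are processed in increasing distance (stable
#' index tie-break) and each molecule is consumed at most once. Reactants
#' are replaced by products placed with [place_products()].
#'
#' @param pairs Output of [find_candidate_pairs()].
#' @param m A `molecule_set`.
#' @param registry A `chem_registry`.
#' @return List with the updated `molecule_set` (`m`) and a data frame of
#'   accepted `events` (`i`, `j`, `reaction`, `d_nm`).
#' @export
react_contacts <- function(pairs, m, registry) {
  R <- registry$reactions$radius_nm[pairs$reaction]
  hit <- pairs[pairs$d_nm < R, , drop = FALSE]
  events <- hit[0, , drop = FALSE]
  for (r in seq_len(nrow(hit))) {
    i <- hit$i[r]; j <- hit$j[r]
    if (!m$alive[i] || !m$alive[j]) next
    m <- .apply_reaction(m, registry, i, j, hit$reaction[r],
                         m$pos[i, ], m$pos[j, ])
    events <- rbind(events, hit[r, , drop = FALSE])
  }
  list(m = m, events = events)
}

# kill parents i, j and append products; ea/eb are the effective parent
# positions (equal to current positions for contact events)
.apply_reaction <- function(m, registry, i, j, rx, ea, eb) {
  reac <- registry$reactions[rx, , drop = FALSE]
  if (m$species_names[m$species[i]] != reac$a) { tmp <- i; i <- j; j <- tmp
                                                 tmp <- ea; ea <- eb; eb <- tmp }
  m$alive[c(i, j)] <- FALSE
  newpos <- place_products(reac, ea, eb)
  if (nrow(newpos)) {
    ps <- match(reac$products[[1]], m$species_names)
    m$pos <- rbind(m$pos, newpos)
    m$species <- c(m$species, as.integer(ps))
    m$alive <- c(m$alive, rep(TRUE, length(ps)))
  }
  m
}

#' Dynamic time step
#'
#' \eqn{\Delta t = (d_{min} - R)^2 / (8(\sqrt{D_A}+\sqrt{D_B})^2)} for the
#' minimal-distance candidate pair; clamped below at `dt_min` (1 ps) and
#' capped so the step does not overshoot `t_next`. With no candidate pairs
#' the step runs to `t_next`.
#'
#' @param m A `molecule_set`.
#' @param pairs Surviving candidate pairs (see [find_candidate_pairs()]).
#' @param registry A `chem_registry`.
#' @param dt_min Minimum time step in ps.
#' @param t_next Next output checkpoint time in ps (cap).
#' @return List: `dt_ps` (step to take), `dt_raw_ps` (unclamped value),
#'   `clamped` (TRUE when the step taken exceeds the safe step, so the
#'   Brownian-bridge check must run), `d_min_nm`.
#' @export
compute_time_step <- function(m, pairs, registry,
                              dt_min = registry$constants$dt_min_ps,
                              t_next = Inf) {
  cap <- t_next - m$time_ps
  if (nrow(pairs) == 0) {
    return(list(dt_ps = cap, dt_raw_ps = Inf, clamped = FALSE, d_min_nm = Inf))
  }
  p <- pairs[1, ]  # pairs are distance-ordered
  R <- registry$reactions$radius_nm[p$reaction]
  DA <- registry$species$D_nm2_ps[m$species[p$i]]
  DB <- registry$species$D_nm2_ps[m$species[p$j]]
  ss <- sqrt(DA) + sqrt(DB)
  dt_raw <- (p$d_nm - R) * (p$d_nm - R) / (8 * (ss * ss))
  dt <- max(dt_raw, dt_min)
  dt <- min(dt, cap)
  list(dt_ps = dt, dt_raw_ps = dt_raw, clamped = dt > dt_raw,
       d_min_nm = p$d_nm)
}

#' Diffuse molecules over a time step
#'
#' Isotropic Gaussian (Brownian) displacement with per-axis standard
#' deviation \eqn{\sqrt{2 D \Delta t}}; molecules that leave the box are
#' removed permanently. Time advances by `dt_ps`.
#'
#' @param m A `molecule_set`.
#' @param dt_ps Time step in ps.
#' @param registry A `chem_registry`.
#' @return Updated `molecule_set` (attribute `n_exited` reports removals).
#' @export
diffuse <- function(m, dt_ps, registry = default_registry()) {
  stopifnot(dt_ps >= 0)
  idx <- which(m$alive)
  n_exited <- 0L
  if (length(idx) && dt_ps > 0) {
    D <- registry$species$D_nm2_ps[m$species[idx]]
    sdv <- sqrt(2 * D * dt_ps)
    step <- matrix(rnorm(3 * length(idx)), ncol = 3, byrow = TRUE) * sdv
    m$pos[idx, ] <- m$pos[idx, , drop = FALSE] + step
    if (!is.null(m$box)) {
      p <- m$pos[idx, , drop = FALSE]
      out <- p[, 1] < m$box$lo[1] | p[, 1] > m$box$hi[1] |
        p[, 2] < m$box$lo[2] | p[, 2] > m$box$hi[2] |
        p[, 3] < m$box$lo[3] | p[, 3] > m$box$hi[3]
      m$alive[idx[out]] <- FALSE
      n_exited <- sum(out)
    }
  }
  m$time_ps <- m$time_ps + dt_ps
  attr(m, "n_exited") <- n_exited
  m
}

#' Brownian-bridge encounter probability
#'
#' Probability that two molecules whose endpoints are outside the reaction
#' radius nevertheless met during the step:
#' \eqn{p = \exp(-(d_i - R)(d_f - R) / ((D_A + D_B)\Delta t))}, clipped to
#' \[0, 1\]; `p = 1` whenever either endpoint distance is within `R`.
#'
#' @param d_i,d_f Pre- and post-diffusion pair distances (nm). Vectorised.
#' @param R Reaction radius (nm).
#' @param D_sum Summed diffusion coefficient (nm^2/ps).
#' @param dt_ps Time step (ps).
#' @return Probability in \[0, 1\].
#' @export
bridge_probability <- function(d_i, d_f, R, D_sum, dt_ps) {
  p <- exp(-((d_i - R) * (d_f - R) / (D_sum * dt_ps)))
  p[d_i <= R | d_f <= R] <- 1
  pmin(pmax(p, 0), 1)
}

#' Brownian-bridge check over surviving candidate pairs
#'
#' Executed only for clamped steps. For each surviving candidate pair the
#' encounter probability is evaluated from the pre- and post-diffusion
#' distances and accepted by a uniform draw; accepted events are resolved
#' with the contact-reaction conflict rule (increasing final distance,
#' stable index tie-break) and products are placed at the parents'
#' path midpoints.
#'
#' @param m_pre `molecule_set` before diffusion (post contact reactions).
#' @param m `molecule_set` after diffusion.
#' @param pairs Surviving candidate pairs (from the pre-diffusion search).
#' @param dt_ps The (clamped) step in ps.
#' @param registry A `chem_registry`.
#' @param p_floor Probabilities at or below this floor consume no draw.
#' @return List with updated `m` and accepted `events` data frame.
#' @export
bridge_check <- function(m_pre, m, pairs, dt_ps, registry, p_floor = 1e-30) {
  comp <- .compile_registry(registry)
  # draw order: pair index order
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  acc <- data.frame(i = integer(), j = integer(), reaction = integer(),
                    d_f = numeric())
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!m$alive[i] || !m$alive[j]) next
    rx <- pairs$reaction[r]
    R <- comp$radius[rx]
    di <- pairs$d_nm[r]
    dx <- m$pos[i, 1] - m$pos[j, 1]
    dy <- m$pos[i, 2] - m$pos[j, 2]
    dz <- m$pos[i, 3] - m$pos[j, 3]
    df <- sqrt(dx * dx + dy * dy + dz * dz)
    if (di <= R || df <= R) prob <- 1
    else prob <- exp(-((di - R) * (df - R) / (comp$D_sum[rx] * dt_ps)))
    if (prob <= p_floor) next
    if (unif_rand1() < prob)
      acc <- rbind(acc, data.frame(i = i, j = j, reaction = rx, d_f = df))
  }
  if (nrow(acc)) {
    acc <- acc[order(acc$d_f, acc$i, acc$j), , drop = FALSE]
    for (r in seq_len(nrow(acc))) {
      i <- acc$i[r]; j <- acc$j[r]
      if (!m$alive[i] || !m$alive[j]) next
      ea <- (m_pre$pos[i, ] + m$pos[i, ]) / 2
      eb <- (m_pre$pos[j, ] + m$pos[j, ]) / 2
      m <- .apply_reaction(m, registry, i, j, acc$reaction[r], ea, eb)
    }
  }
  list(m = m, events = acc)
}

# single uniform draw from R's stream (same consumption as unif_rand in C)
unif_rand1 <- function() runif(1)

#' Default logarithmic output grid
#' @param t_start,t_end Window in ps.
#' @param per_decade Output points per decade.
#' @return Sorted times in ps including both endpoints.
#' @export
chem_sample_times <- function(t_start = 1, t_end = 1e6, per_decade = 10) {
  g <- 10^seq(log10(t_start), log10(t_end), by = 1 / per_decade)
  sort(unique(c(t_start, g, t_end)))
}

#' Run the chemical stage
#'
#' Repeats the four kernels (pair search + contact reactions, dynamic time
#' step, Gaussian diffusion, Brownian-bridge check on clamped steps) from
#' the population's time stamp to the last sample time, recording alive
#' species counts and reaction-event tallies at each sample time.
#'
#' @param m A `molecule_set` (time stamp = chemical-stage start, 1 ps).
#' @param registry A `chem_registry`.
#' @param sample_times Output checkpoint times in ps.
#' @param engine `"grid"` (hashed cell-grid pair search, C++) or
#'   `"reference"` (exhaustive O(N^2) search, C++) or `"r"` (exhaustive,
#'   pure R; used for cross-validation). All engines consume the RNG stream
#'   in the same order and produce identical trajectories for a fixed seed.
#' @param pair_cutoff Grid search cutoff in nm; covers all contact radii and
#'   every bridge pair with acceptance probability above `p_floor`.
#' @param p_floor Bridge probabilities at or below this floor consume no
#'   RNG draw (identical in all engines).
#' @param max_iter Failsafe iteration bound.
#' @return Object of class `"chem_result"`: list with `time_ps`, `counts`
#'   (species x time matrix), `reaction_events` (reaction x time, events
#'   since the previous sample), `n_exited`, `n_steps`, and the `final`
#'   `molecule_set`.
#' @export
run_chemical_stage <- function(m, registry = default_registry(),
                               sample_times = chem_sample_times(
                                 m$time_ps, registry$constants$chem_t_end_ps),
                               engine = c("grid", "reference", "r"),
                               pair_cutoff = 4, p_floor = 1e-30,
                               max_iter = 5e6) {
  engine <- match.arg(engine)
  stopifnot(inherits(m, "molecule_set"))
  sample_times <- sort(unique(as.numeric(sample_times)))
  if (any(sample_times < m$time_ps - 1e-9))
    stop("sample times precede the population time stamp")
  comp <- .compile_registry(registry)
  if (engine %in% c("grid", "reference")) {
    box_lo <- if (is.null(m$box)) rep(-1e30, 3) else as.numeric(m$box$lo)
    box_hi <- if (is.null(m$box)) rep(1e30, 3) else as.numeric(m$box$hi)
    react_a <- match(registry$reactions$a, registry$species$name)
    res <- .chem_run_cpp(m$pos, m$species, comp$D, comp$pair,
                         comp$radius, comp$D_sum, comp$products,
                         as.integer(comp$n_products), as.integer(react_a),
                         box_lo, box_hi, m$time_ps,
                         registry$constants$dt_min_ps, sample_times,
                         p_floor, pair_cutoff, max_iter,
                         engine == "grid")
    final <- m
    final$pos <- res$pos
    final$species <- res$species
    final$alive <- res$alive
    final$time_ps <- sample_times[length(sample_times)]
    out <- list(time_ps = sample_times,
                counts = res$counts,
                reaction_events = res$reaction_events,
                n_exited = res$n_exited, n_steps = res$n_steps,
                final = final)
  } else {
    out <- .run_chem_r(m, registry, sample_times, p_floor, max_iter)
  }
  rownames(out$counts) <- registry$species$name
  rownames(out$reaction_events) <- paste(registry$reactions$a, "+",
                                         registry$reactions$b)
  class(out) <- "chem_result"
  out
}

#' @export
print.chem_result <- function(x, ...) {
  nt <- length(x$time_ps)
  cat("<chem_result>", nt, "sample times,", x$n_steps, "steps,",
      x$n_exited, "boundary exits\n")
  cat("  final counts:",
      paste(rownames(x$counts), x$counts[, nt], sep = ":", collapse = "  "),
      "\n")
  invisible(x)
}

# pure-R exhaustive driver; mirrors the C++ engine step for step, including
# the RNG consumption order
.run_chem_r <- function(m, registry, sample_times, p_floor, max_iter) {
  S <- nrow(registry$species)
  NR <- nrow(registry$reactions)
  NT <- length(sample_times)
  counts <- matrix(0, S, NT)
  reac_counts <- matrix(0, NR, NT)
  pend <- numeric(NR)
  n_exited <- 0
  n_steps <- 0
  next_sample <- 1L
  record <- function(k) {
    tab <- tabulate(m$species[m$alive], nbins = S)
    counts[, k] <<- tab
    reac_counts[, k] <<- pend
    pend <<- numeric(NR)
  }
  while (next_sample <= NT && sample_times[next_sample] <= m$time_ps + 1e-9) {
    record(next_sample); next_sample <- next_sample + 1L
  }
  t_end <- sample_times[NT]
  iter <- 0
  while (next_sample <= NT && m$time_ps < t_end - 1e-12) {
    iter <- iter + 1
    if (iter > max_iter) stop("chemical stage exceeded max_iter steps")
    pairs <- find_candidate_pairs(m, registry)
    rc <- react_contacts(pairs, m, registry)
    m <- rc$m
    if (nrow(rc$events))
      pend <- pend + tabulate(rc$events$reaction, nbins = NR)
    surv <- pairs[m$alive[pairs$i] & m$alive[pairs$j], , drop = FALSE]
    st <- compute_time_step(m, surv, registry,
                            t_next = sample_times[next_sample])
    m_pre <- m
    m <- diffuse(m, st$dt_ps, registry)
    n_exited <- n_exited + attr(m, "n_exited")
    if (st$clamped) {
      br <- bridge_check(m_pre, m, surv, st$dt_ps, registry, p_floor)
      m <- br$m
      if (nrow(br$events))
        pend <- pend + tabulate(br$events$reaction, nbins = NR)
    }
    n_steps <- n_steps + 1
    while (next_sample <= NT &&
           sample_times[next_sample] <= m$time_ps + 1e-9) {
      record(next_sample); next_sample <- next_sample + 1L
    }
  }
  while (next_sample <= NT) { record(next_sample); next_sample <- next_sample + 1L }
  list(time_ps = sample_times, counts = counts,
       reaction_events = reac_counts, n_exited = n_exited,
       n_steps = n_steps, final = m)
}
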