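#' @useDynLib trackchem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp rpois setNames lm coef sd
#' @importFrom utils read.csv write.csv modifyList
NULL

# Internal unit conventions: length nm, time ps, energy eV.
# 1 m^2/s = 1e6 nm^2/ps.
.M2S_TO_NM2PS <- 1e6

#' Smoluchowski reaction radius
#'
#' Contact radius of a diffusion-controlled bimolecular reaction,
#' \eqn{R = k / (4 \pi N_A D_{sum})}, where `k` is the rate constant and
#' `D_sum` the summed diffusion coefficient of the two partners.
#'
#' @param k_dm3_per_mol_s Rate constant in dm^3/(mol s). Vectorised.
#' @param D_sum_m2_per_s Summed diffusion coefficient in m^2/s. Vectorised.
#' @param avogadro Avogadro's constant (1/mol).
#' @return Reaction radius in nm.
#' @examples
#' reaction_radius(2.95e10, 7.7e-9)  # e_aq + OH, about 0.506 nm
#' @export
reaction_radius <- function(k_dm3_per_mol_s, D_sum_m2_per_s,
                            avogadro = 6.02214076e23) {
  if (any(k_dm3_per_mol_s <= 0) || any(D_sum_m2_per_s <= 0))
    stop("reaction_radius(): k and D_sum must be positive")
  k_m3 <- k_dm3_per_mol_s * 1e-3            # dm^3 -> m^3
  r_m <- k_m3 / (4 * pi * avogadro * D_sum_m2_per_s)
  r_m * 1e9                                  # m -> nm
}

#' Build a parameter registry
#'
#' Validates and assembles the tables that drive the simulator: molecular
#' species with diffusion coefficients, bimolecular reactions with rate
#' constants (from which Smoluchowski radii are derived), dissociation
#' channels of activated water, and physical constants. The bundled default
#' parameter set describes liquid water at unit density.
#'
#' @param config Path to a YAML parameter file, or an already-parsed list
#'   with elements `species`, `reactions`, `dissociation`, `constants`.
#'   `NULL` loads the bundled defaults.
#' @param identical_reactant_factor Multiplier applied to the derived radius
#'   of identical-reactant channels (2e_aq, OH+OH, H+H). The default 1 takes
#'   the printed rate constants at face value; whether a statistical factor
#'   of 2 belongs here is a known ambiguity of the Smoluchowski convention
#'   for identical pairs (see the methods vignette).
#' @return An object of class `"chem_registry"`: a list with data frames
#'   `species` (internal diffusion coefficients `D_nm2_ps`), `reactions`
#'   (derived `radius_nm`, `D_sum_m2_s`), `dissociation`, and list
#'   `constants`.
#' @export
build_registry <- function(config = NULL, identical_reactant_factor = 1) {
  if (is.null(config))
    config <- system.file("extdata", "default_parameters.yaml",
                          package = "trackchem", mustWork = TRUE)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (part in c("species", "reactions", "dissociation", "constants"))
    if (is.null(config[[part]]))
      stop("registry config is missing section '", part, "'")

  sp <- do.call(rbind, lapply(config$species, function(s) {
    data.frame(name = as.character(s$name),
               D_m2_s = as.numeric(s$D_m2_per_s),
               charge = as.integer(s$charge),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(sp$name)) stop("duplicate species names in registry")
  if (any(sp$D_m2_s <= 0)) stop("diffusion coefficients must be positive")
  sp$D_nm2_ps <- sp$D_m2_s * .M2S_TO_NM2PS

  cn <- config$constants
  constants <- list(
    avogadro = as.numeric(cn$avogadro %||% 6.02214076e23),
    water_density_g_cm3 = as.numeric(cn$water_density_g_cm3 %||% 1),
    water_molar_mass_g_mol = as.numeric(cn$water_molar_mass_g_mol %||% 18.0153),
    sub_excitation_threshold_eV = as.numeric(cn$sub_excitation_threshold_eV %||% 8.22),
    dt_min_ps = as.numeric(cn$dt_min_ps %||% 1),
    chem_t_start_ps = as.numeric(cn$chem_t_start_ps %||% 1),
    chem_t_end_ps = as.numeric(cn$chem_t_end_ps %||% 1e6),
    tracking_cuts_eV = lapply(cn$tracking_cuts_eV, as.numeric)
  )
  if (any(unlist(constants[1:7]) <= 0) ||
      constants$chem_t_start_ps >= constants$chem_t_end_ps)
    stop("invalid constants block")

  find_species <- function(nm, where) {
    i <- match(nm, sp$name)
    if (anyNA(i))
      stop("unknown species '", paste(nm[is.na(i)], collapse = ", "),
           "' referenced by ", where)
    i
  }

  rx_list <- config$reactions
  rx <- data.frame(
    a = vapply(rx_list, function(r) as.character(r$reactants[[1]]), ""),
    b = vapply(rx_list, function(r) as.character(r$reactants[[2]]), ""),
    k_dm3_mol_s = vapply(rx_list, function(r) as.numeric(r$k_dm3_per_mol_s), 0),
    n_products = vapply(rx_list, function(r) length(r$products), 0L),
    stringsAsFactors = FALSE
  )
  rx$products <- lapply(rx_list, function(r) as.character(unlist(r$products)))
  if (any(rx$k_dm3_mol_s <= 0)) stop("reaction rate constants must be positive")
  ia <- find_species(rx$a, "a reaction")
  ib <- find_species(rx$b, "a reaction")
  for (r in rx$products) if (length(r)) find_species(r, "reaction products")
  key <- paste(pmin(rx$a, rx$b), pmax(rx$a, rx$b))
  if (anyDuplicated(key)) stop("duplicate reactant pair in reaction table")
  rx$D_sum_m2_s <- sp$D_m2_s[ia] + sp$D_m2_s[ib]
  rx$radius_nm <- reaction_radius(rx$k_dm3_mol_s, rx$D_sum_m2_s,
                                  constants$avogadro) *
    ifelse(rx$a == rx$b, identical_reactant_factor, 1)

  ds_list <- config$dissociation
  ds <- data.frame(
    parent = vapply(ds_list, function(d) as.character(d$parent), ""),
    mode = vapply(ds_list, function(d) as.character(d$mode), ""),
    fraction_percent = vapply(ds_list, function(d) as.numeric(d$fraction_percent), 0),
    stringsAsFactors = FALSE
  )
  ds$products <- lapply(ds_list, function(d) as.character(unlist(d$products)))
  ok_parent <- c("ionized", "A1B1", "B1A1", "rydberg_diffuse", "dissoc_attachment")
  if (!all(ds$parent %in% ok_parent))
    stop("unknown dissociation parent state(s): ",
         paste(setdiff(ds$parent, ok_parent), collapse = ", "))
  if (!all(ds$mode %in% c("dissociative_decay", "auto_ionization", "relaxation")))
    stop("unknown dissociation mode")
  for (p in ds$products) if (length(p)) find_species(p, "a dissociation channel")
  sums <- tapply(ds$fraction_percent, ds$parent, sum)
  bad <- names(sums)[abs(sums - 100) > 1e-9]
  if (length(bad))
    stop("dissociation fractions for state(s) ", paste(bad, collapse = ", "),
         " do not sum to 100")

  structure(list(species = sp, reactions = rx, dissociation = ds,
                 constants = constants),
            class = "chem_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chem_registry <- function(x, ...) {
  cat("<chem_registry>\n")
  cat("  species:     ", nrow(x$species), " (",
      paste(x$species$name, collapse = ", "), ")\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (radii ", sprintf("%.3f", min(x$reactions$radius_nm)), "-",
      sprintf("%.3f", max(x$reactions$radius_nm)), " nm)\n", sep = "")
  cat("  dissociation:", length(unique(x$dissociation$parent)),
      "parent states,", nrow(x$dissociation), "channels\n")
  invisible(x)
}

# Cached default registry (tables never change within a session).
.registry_cache <- new.env(parent = emptyenv())

#' Default liquid-water registry
#'
#' The bundled parameter set (7 species, 9 reactions, 5 dissociation parent
#' states), built once and cached.
#' @return A `chem_registry`.
#' @export
default_registry <- function() {
  if (is.null(.registry_cache$default))
    .registry_cache$default <- build_registry(NULL)
  .registry_cache$default
}

#' Look up the reaction for a species pair
#'
#' Symmetric in its two arguments; returns `NULL` when the pair has no
#' reaction channel.
#'
#' @param registry A `chem_registry`.
#' @param a,b Species names.
#' @return One-row data frame from `registry$reactions`, or `NULL`.
#' @export
lookup_reaction <- function(registry, a, b) {
  sp <- registry$species$name
  if (!(a %in% sp) || !(b %in% sp))
    stop("unknown species: ", paste(setdiff(c(a, b), sp), collapse = ", "))
  rx <- registry$reactions
  hit <- which((rx$a == a & rx$b == b) | (rx$a == b & rx$b == a))
  if (!length(hit)) return(NULL)
  rx[hit, , drop = FALSE]
}

#' Molecular number density of the medium
#'
#' @param registry A `chem_registry`.
#' @param density_scale Multiplier on the default 1 g/cm^3 water density.
#' @return Molecules per nm^3.
#' @export
number_density <- function(registry, density_scale = 1) {
  cn <- registry$constants
  rho <- cn$water_density_g_cm3 * density_scale          # g/cm^3
  rho * cn$avogadro / cn$water_molar_mass_g_mol * 1e-21  # 1/cm^3 -> 1/nm^3
}

# Internal: registry compiled to plain vectors for the fast engine.
# species indexed 1..S in registry order; pair_table[s1, s2] = reaction row or 0.
.compile_registry <- function(registry) {
  sp <- registry$species
  rx <- registry$reactions
  S <- nrow(sp)
  pair <- matrix(0L, S, S)
  ia <- match(rx$a, sp$name); ib <- match(rx$b, sp$name)
  for (r in seq_len(nrow(rx))) {
    pair[ia[r], ib[r]] <- r
    pair[ib[r], ia[r]] <- r
  }
  prod_mat <- matrix(0L, nrow(rx), 3)
  for (r in seq_len(nrow(rx))) {
    p <- match(rx$products[[r]], sp$name)
    if (length(p)) prod_mat[r, seq_along(p)] <- p
  }
  list(D = sp$D_nm2_ps, names = sp$name, pair = pair,
       radius = rx$radius_nm,
       D_sum = rx$D_sum_m2_s * .M2S_TO_NM2PS,
       products = prod_mat,
       n_products = rx$n_products)
}
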