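# Shared fixtures. Ensembles used by several acceptance/trend tests are
# computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# reduced-size electron-beam ensemble (10 events, 10 keV per event)
electron_ensemble <- function() {
  if (is.null(.fixture_cache$electron)) {
    .fixture_cache$electron <- with_fixed_seed(20260930, {
      run_track_ensemble(calibration_preset("e750keV"), n_events = 10,
                         edep_eV = 1e4)
    })
  }
  .fixture_cache$electron
}

# 20 MeV proton ensemble (one 1 um traversal per event)
proton_ensemble <- function() {
  if (is.null(.fixture_cache$proton)) {
    .fixture_cache$proton <- with_fixed_seed(20260931, {
      run_track_ensemble(calibration_preset("p20MeV"), n_events = 12)
    })
  }
  .fixture_cache$proton
}

# a small random reactive configuration for pair-search / engine tests
random_molecule_set <- function(n, box_nm = 20, species = NULL,
                                registry = default_registry()) {
  if (is.null(species))
    species <- sample(registry$species$name, n, replace = TRUE)
  molecule_set(species, matrix(runif(3 * n, 0, box_nm), ncol = 3),
               box = list(lo = rep(0, 3), hi = rep(box_nm, 3)),
               registry = registry)
}
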