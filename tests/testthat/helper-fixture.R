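# Shared lazily-loaded fixture and reproduction objects (the calibration in
# reproduce_tables is the only moderately expensive step; compute it once).
.qm_test_cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(.qm_test_cache$fx)) .qm_test_cache$fx <- load_fixture()
  .qm_test_cache$fx
}

cached_reproduction <- function() {
  if (is.null(.qm_test_cache$rep)) {
    .qm_test_cache$rep <- reproduce_tables(cached_fixture())
  }
  .qm_test_cache$rep
}

RT298 <- physical_constants()$R_kcal * 298.15

# one well-formed bimolecular channel for quick tests
demo_channel <- function(...) {
  reaction_channel("PS", "HO", "HAT", "1", "water",
                   dG_act_kcal = 0, dG_rxn_kcal = -39.9, ...)
}

demo_media <- function() {
  list(water = medium_spec("water", 298.15, 8.91e-4, "aqueous"))
}

demo_species <- function() {
  list(PS = species_spec("PS", "antioxidant", stokes_radius = 3.6e-10),
       HO = species_spec("HO", "radical", stokes_radius = 2.2e-10))
}
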