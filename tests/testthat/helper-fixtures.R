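# Shared fixtures: tables and cross-section sets are cached once per test run.
ref_tables <- load_reference_tables()

fixture_env <- new.env(parent = emptyenv())

# cross-section set covering water + skin + brown/orange/black @100%
standard_xs <- function() {
  if (is.null(fixture_env$xs)) {
    mats <- list(water_material())
    for (nm in unique(ref_tables$skin_layers$name))
      mats <- c(mats, list(skin_material(nm, ref_tables)))
    for (ink in c("brown", "orange", "black"))
      mats <- c(mats, list(tattoo_mixture(ink, 100, tables = ref_tables)))
    fixture_env$xs <- build_cross_sections(mats)
  }
  fixture_env$xs
}

control_phantom <- function() {
  if (is.null(fixture_env$ctrl))
    fixture_env$ctrl <- build_phantom(NULL, tables = ref_tables)
  fixture_env$ctrl
}

ink_phantom <- function(ink, loading = 100) {
  key <- paste0(ink, loading)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- build_phantom(
      tattoo_mixture(ink, loading, tables = ref_tables), tables = ref_tables)
  fixture_env[[key]]
}
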