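# small-study configs used across tests (two sites keeps generation fast)
small_config <- function(seed = 1L, ...) {
  synth_config(seed = seed, n_sites = 2L, watershed_labels = "WFT", ...)
}

# summer-only reach descriptors for a generated study
summer_reach_descriptors <- function(temps) {
  descriptor_table(temps, level = "reach", seasons = "Summer")
}
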