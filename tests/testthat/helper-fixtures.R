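# Shared fixtures. The study-scale synthetic corpus (2000 documents,
# default acronym specs, seed 42) and its simulation are generated once
# per test run and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

default_synth <- function() {
  if (is.null(.fixture_cache$synth)) {
    cfg <- synth_config(seed = 42)
    .fixture_cache$config <- cfg
    .fixture_cache$synth <- generate_corpus(cfg)
  }
  .fixture_cache$synth
}

default_simulation <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_corpus(default_synth()$corpus, seed = 42)
  }
  .fixture_cache$sim
}

# small two-definition corpus used by several unit tests
tiny_corpus <- function() {
  acro_corpus(list(
    acro_document(
      "doc1",
      paste0("Magnetic resonance spectroscopy (MRS) was performed. ",
             "Magnetic resonance spectroscopy showed changes.")),
    acro_document(
      "doc2",
      paste0("Patients with anterior cruciate ligament (ACL) tears were ",
             "scanned. The ACL was ruptured."))
  ))
}

# three mentions of DM2 with the variant surfaces unified by C0011860
dm2_mentions <- function() {
  data.frame(
    doc_id = c("a", "b", "c"),
    short_form = c("DM2", "DM2", "DM2"),
    long_form = c("diabetes mellitus type 2", "diabetes mellitus type II",
                  "type two diabetes mellitus"),
    stringsAsFactors = FALSE)
}

dm2_concept_map <- function() {
  concept_map(
    c("diabetes mellitus type 2", "diabetes mellitus type II",
      "type two diabetes mellitus"),
    c("C0011860", "C0011860", "C0011860"))
}
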