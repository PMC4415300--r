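# A small simulated repertoire shared across test files (built once per
# test run; ~15 s including the mining pass).

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_repertoire(synth_config(
      seed = 7, species = c("Til", "Bur"),
      counts = c(complete_2exon = 4L, complete_1exon = 2L,
                 pseudogene_frameshift = 2L, pseudogene_stop = 1L,
                 edge = 2L, fragment = 1L, decoy_gpcr = 2L),
      ortholog_pairs = 1L, ortholog_triplets = 0L))
  }
  .fixture_env$sim
}

small_rep <- function() {
  if (is.null(.fixture_env$rep)) {
    sim <- small_sim()
    .fixture_env$rep <- mine_repertoire(sim$assemblies, sim$pos_baits,
                                        sim$neg_baits)
  }
  .fixture_env$rep
}
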