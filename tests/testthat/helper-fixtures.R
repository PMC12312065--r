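# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

fixture_design <- function() memo("design", ngt_design(seed = 1))

# a small zero-artefact, zero-error parameter set for round-trip checks
clean_params <- function(...) {
  sim_params(seq_error = 0, jackpot_rate = 0, end_repair_rate = 0,
             single_strand_rate = 0, ...)
}

# simulate one small sample and return everything the tests may inspect
small_sample <- function(level = 0.10, n_per_locus = 300L, seed = 42L,
                         params = sim_params(), design = fixture_design()) {
  mix <- design_mixture(design$edits, level)
  fr <- duplexr:::hap_frequencies(mix, design$edits, level)
  haps <- apply_edits(design$reference, design$edits)
  sim <- simulate_molecules(design$reference, haps, fr, params,
                            n_per_locus, seed = seed)
  em <- emit_fastq(sim, params, seed = seed + 1L)
  list(design = design, sim = sim, reads = em$reads, params = params)
}

# the acceptance-scale titration, shared across acceptance test blocks
acceptance_titration <- function() {
  memo("acceptance_titration", {
    run_titration(fixture_design(),
                  levels = c(0.001, 0.005, 0.009, 0.10),
                  replicates = 3L, duplex_depth = 8000L,
                  params = sim_params(), seed = 1L)
  })
}
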