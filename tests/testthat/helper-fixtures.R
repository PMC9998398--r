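# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

small_sim_list <- function() {
  list(genome_length_per_chrom = 80000L, n_chromosomes = 1L,
       te_island_count = 6L, te_island_length_range = c(1000L, 2000L),
       decoy_te_count = 6L)
}

small_sim_config <- function(seed = 101L, ...) {
  do.call(sim_config, c(small_sim_list(), list(seed = seed), list(...)))
}

build_fixture <- function(cfg) {
  gen <- generate_genome(cfg)
  ctx <- assign_contexts(gen$genome)
  lens <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  samples <- lapply(cfg$sample_ids, function(sid)
    simulate_methylome(gen$genome, gen$truth, sid, cfg, contexts = ctx))
  names(samples) <- cfg$sample_ids
  positions <- filter_by_coverage(samples, 5, "CG")
  de <- simulate_expression(gen$annotations, gen$truth, cfg)
  list(cfg = cfg, gen = gen, ctx = ctx, lens = lens, samples = samples,
       positions = positions, de = de)
}

# Desk-scale fixture for unit tests (1 x 80 kb, 6 islands).
small_fixture <- function() {
  if (is.null(.fx$small)) .fx$small <- build_fixture(small_sim_config())
  .fx$small
}

# Full study-condition fixture (2 x 500 kb, 20 islands, 30X, depletion 4.5).
default_fixture <- function() {
  if (is.null(.fx$default)) .fx$default <- build_fixture(sim_config())
  .fx$default
}

# DMR calls at study defaults against the reference, cached per fixture.
fixture_dmrs <- function(fx_name = "default") {
  key <- paste0("dmrs_", fx_name)
  if (is.null(.fx[[key]])) {
    fx <- if (fx_name == "default") default_fixture() else small_fixture()
    kos <- fx$cfg$sample_ids[2:3]
    sets <- lapply(kos, function(ko)
      call_dmrs(fx$samples[[1]], fx$samples[[ko]], fx$lens, fx$positions))
    names(sets) <- kos
    .fx[[key]] <- sets
  }
  .fx[[key]]
}
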