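# Small trained models shared across test files; built once per run.
.fixture_cache <- new.env(parent = emptyenv())

# tiny simulated dataset: 3 active + 2 null programs, 2 batches
tiny_sim <- function(seed = 11) {
  simulate_gp_counts(n_cells = 300, n_genes = 80, n_programs_active = 3,
                     n_programs_null = 2, genes_per_program = 10,
                     n_conditions = 2, seed = seed)
}

tiny_mask <- function(sim, soft = TRUE, ...) {
  build_gp_mask(sim$gene_sets, sim$gene_names, min_genes = 5, soft = soft, ...)
}

# quick fit used by analysis / surgery unit tests (seconds, not minutes)
tiny_model <- function() {
  if (is.null(.fixture_cache$tiny)) {
    sim <- tiny_sim()
    mask <- tiny_mask(sim)
    .fixture_cache$tiny <- list(
      sim = sim, mask = mask,
      model = gpvae(sim$counts, sim$conditions, mask, hidden_sizes = c(64, 64),
                    epochs = 60, batch_size = 64, seed = 5)
    )
  }
  .fixture_cache$tiny
}
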