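# Shared fixture builders. Everything is generated in code; datasets are
# cached within a test run so repeated helper calls are cheap.

.fixture_cache <- new.env(parent = emptyenv())

# A small clean dataset with its GRM, memoised per (n, m, h2, seed, ...).
test_dataset <- function(n_lines = 200, n_markers = 500, heritability = 0.5,
                         seed = 1, ...) {
  key <- paste(n_lines, n_markers, heritability, seed,
               paste(unlist(list(...)), collapse = "_"), sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                      heritability = heritability, seed = seed, ...)
    ds <- simulate_dataset(cfg)
    ds$grm <- compute_grm(ds$markers)
    .fixture_cache[[key]] <- ds
  }
  .fixture_cache[[key]]
}

# Deterministic 80/20 split by line order (for tests where randomness of the
# split is irrelevant).
head_tail_split <- function(ids, test_fraction = 0.2) {
  n_test <- round(length(ids) * test_fraction)
  train_test_split(ids[seq_len(length(ids) - n_test)],
                   ids[seq(length(ids) - n_test + 1L, length(ids))])
}
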