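# Shared fixtures, built once per test run and cached.

# Large noise-free F1 with many phase blocks (used for distributional and
# balance checks).
f1_block_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- simulate_species_pair(280000, divergence = 0.0368,
                                     polymorphism = 0, seed = 42)
      f1 <- simulate_cross(panel, "F1", seed = 43)
      blocks <- simulate_phase_blocks(f1, seed = 44)
      cache <<- list(panel = panel, f1 = f1, blocks = blocks,
                     filtered = filter_blocks(blocks))
    }
    cache
  }
})

# Small panel + pedigree trio for triangle statistics.
trio_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- simulate_species_pair(4000, divergence = 0.25,
                                     polymorphism = 0, seed = 11)
      cache <<- list(
        panel = panel,
        p1 = simulate_cross(panel, "P1", seed = 12),
        p2 = simulate_cross(panel, "P2", seed = 13),
        f1 = simulate_cross(panel, "F1", seed = 14))
    }
    cache
  }
})

trio_aims <- function(fx = trio_fixture()) {
  discover_aims(genotypes(fx$p1), genotypes(fx$p2), delta = 1.0)
}

# Hand-built pileup over positions 1..n from a read table.
make_pileup <- function(reads, n, start = 1L) {
  positions <- seq.int(start, start + n - 1L)
  depth <- as.integer(table(factor(reads$pos, levels = positions)))
  structure(list(region = c(start, start + n - 1L), positions = positions,
                 depth = depth, reads = reads, sample_id = "test"),
            class = "pileup")
}

# Hand-built checklist table from compact arguments.
make_checklists <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(checklist_id = r[[1]], locality_id = r[[2]],
               lon = as.numeric(r[[3]]), lat = as.numeric(r[[4]]),
               date = r[[5]], complete = TRUE, species = r[[6]],
               stringsAsFactors = FALSE)))
  checklist_table(df)
}
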