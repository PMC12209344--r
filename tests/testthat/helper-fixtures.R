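# Fixture builders shared across test files. Everything is generated in
# code; no stored data files.

toy_taxonomy <- function() {
  default_scat_taxonomy()
}

# Long-format counts rows from parallel vectors.
counts_df <- function(scat, rep, taxon, reads) {
  data.frame(scat_id = scat, replicate = rep, taxon_id = taxon,
             reads = reads, stringsAsFactors = FALSE)
}

# A scat_composition with the given diet items (equal reads unless shares
# are supplied); bypasses filtering for metric-level tests.
comp_fixture <- function(scat_id, taxa, defecator = "Vulpes vulpes",
                         reads = NULL, shares = NULL, status = "assigned") {
  n <- length(taxa)
  reads <- reads %||% rep(100L, n)
  total <- sum(reads) + 1000L  # defecator reads included in the sample total
  shares <- shares %||% (reads / total)
  items <- data.frame(taxon_id = taxa, combined_reads = as.integer(reads),
                      share = shares, stringsAsFactors = FALSE)
  scatdiet:::new_scat_composition(scat_id, status, defecator = defecator,
                                  diet_items = items,
                                  total_retained_reads = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free simulation parameters: no dropout, no tag jumping, no
# contamination, no failed replicates. alpha = 2 keeps within-scat prey
# proportions away from zero so finite-depth multinomials detect every taxon.
noise_free_params <- function(n = 5L, seed = 1L, ...) {
  simulation_params(n_scats_per_species = n, dropout_d0 = 0, tagjump_rate = 0,
                    contamination_prob = 0, failed_replicate_prob = 0,
                    dirichlet_alpha = 2, seed = seed, ...)
}

# Permissive thresholds: every detected taxon retained, any positive
# replicate valid. Used where tests compare against sub-threshold truth.
permissive_config <- function(...) {
  filter_config(min_reads_per_replicate = 0, min_rra = 1e-6,
                exploration_rra = 1e-6, min_item_share = 1e-6, ...)
}

# Run filter + assignment + exclusions over a counts table.
assign_all <- function(counts, taxonomy, config = filter_config()) {
  filtered <- filter_all_scats(counts, config)
  out <- lapply(names(filtered), function(sid) {
    f <- filtered[[sid]]
    if (f$status == "failed_amplification")
      return(scatdiet:::new_scat_composition(sid, "failed_amplification"))
    apply_exclusions(assign_defecator(f, taxonomy, config, scat_id = sid),
                     config)
  })
  stats::setNames(out, names(filtered))
}
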