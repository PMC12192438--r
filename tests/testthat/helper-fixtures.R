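# Shared fixtures: small simulated bundles and hand-built tables.

small_sim <- function(seed = 7, ...) {
  args <- list(seed = seed, n_contigs = 40, n_months = 4, n_trap_samples = 8,
               contig_length_range = c(300, 1500))
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_dataset(do.call(sim_config, args))
}

# coverage_table from an explicit matrix
tab_from_matrix <- function(m, mode = "raw") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  coverage_table_new(m, mode)
}

# metadata for a simple planktonic + trap layout
toy_metadata <- function(sample_ids, depths, habitats) {
  data.frame(sample_id = sample_ids, date = "2015-01-01", depth_m = depths,
             habitat = habitats, total_reads = 1e6,
             mapped_reads = 5e3, stringsAsFactors = FALSE)
}

# independent brute-force Q2Q3 oracle: literal sort, drop k lowest and k
# highest ranks, average the rest
q2q3_oracle <- function(d) {
  L <- length(d)
  if (L < 4) return(mean(d))
  k <- floor(L / 4)
  s <- sort(d)
  kept <- s[seq.int(k + 1, L - k)]
  mean(kept)
}
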