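# Shared fixtures: study-condition communities and brute-force oracles.

# Paired bulk/concentrate simulation under the recovery study conditions:
# 50 genomes, 5 ultrasmall planted at exactly 1000-fold, concentrate
# dominated by large-cell carryover (capture 0.99), sequencing effort set so
# the shallowest planted genome reaches 2x in bulk and 20x in concentrate.
study_conditions_run <- function(seed = 42) {
  spec <- community_spec(n_genomes = 50, n_ultrasmall = 5,
                         enrichment_range = c(1000, 1000),
                         concentrate_capture_of_large = 0.99, seed = seed)
  comm <- build_community(spec)
  sb <- seq_bases_for_depth(comm, "bulk", 2)
  sc <- seq_bases_for_depth(comm, "concentrate", 20)
  cov_b <- simulate_coverage(comm, "bulk", sb, seed = seed + 1L)
  cov_c <- simulate_coverage(comm, "concentrate", sc, seed = seed + 2L)
  pb <- profile_depth_vectors(cov_b, "bulk")
  pc <- profile_depth_vectors(cov_c, "concentrate")
  rb <- relative_abundance(pb)
  rc <- relative_abundance(pc)
  E <- enrichment_factor(rc$base_fraction, rb$base_fraction,
                         unit_id = rb$scaffold_id)
  list(community = comm, profiles_bulk = pb, profiles_concentrate = pc,
       enrichment = E,
       planted_ids = comm$genomes$genome_id[comm$genomes$is_ultrasmall])
}

# brute-force LCS: enumerate every subsequence of `a`, keep the longest that
# is also a subsequence of `b`
brute_lcs <- function(a, b) {
  is_subseq <- function(x, y) {
    if (length(x) == 0L) return(TRUE)
    j <- 1L
    for (el in y) {
      if (el == x[j]) j <- j + 1L
      if (j > length(x)) return(TRUE)
    }
    FALSE
  }
  best <- 0L
  for (mask in 0:(2^length(a) - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(a) - 1L)) > 0L)
    if (length(idx) > best && is_subseq(a[idx], b)) best <- length(idx)
  }
  best
}

# depth records data.frame in samtools-depth layout
depth_records <- function(scaffold, pos, depth) {
  data.frame(scaffold = scaffold, pos = pos, depth = depth,
             stringsAsFactors = FALSE)
}
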