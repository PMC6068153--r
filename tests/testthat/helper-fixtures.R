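# shared fixture builders; everything is generated in code

# a tiny hand-made plex table with given intensities (proteins x channels)
make_plex <- function(plex_id, m, ref = character()) {
  plex_table(plex_id, m, reference_channels = ref)
}

# single-plex design: two genotypes, one diet, n per group, 10 channels
small_design <- function(n = 4L) {
  experiment_design(diets = "LF", replicates_per_group = n, plexes = 1L)
}

# push a hand-made plex list through the mandatory provenance steps
normalize_plexes <- function(tables, metadata) {
  quantify_plexes(tables, metadata)
}

# metadata for a list of plex tables where every sample channel is a sample
auto_metadata <- function(tables, genotype = "g1", diet = "d1") {
  rows <- do.call(rbind, lapply(tables, function(tb) {
    sc <- setdiff(colnames(tb$intensities), tb$reference_channels)
    data.frame(plex = tb$plex_id, channel = sc, stringsAsFactors = FALSE)
  }))
  rows$sample_id <- sprintf("S%02d", seq_len(nrow(rows)))
  rows$genotype <- genotype
  rows$diet <- diet
  rows[, c("sample_id", "genotype", "diet", "plex", "channel")]
}

# brute-force two-sided binomial split p-value (independent oracle)
binom_split_oracle <- function(zA, zB, nA, nB) {
  z <- zA + zB
  if (z == 0) return(1)
  probs <- dbinom(0:z, z, nA / (nA + nB))
  sum(probs[probs <= probs[zA + 1] * (1 + 1e-10)])
}

# brute-force BH step-up (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ge <- which(p[o] >= p[o][i])
    q[o[i]] <- min(1, min(m * p[o][ge] / ge))
  }
  q
}

# brute-force hypergeometric upper tail by direct summation of choose()
hyper_tail_oracle <- function(overlap, K, N, n) {
  ks <- overlap:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
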