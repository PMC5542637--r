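# Shared fixtures, built in code at test time.

# A small deterministic genome + annotation used across tests.
tiny_world <- function(seed = 101, lengths = c(2e5, 2e5), n_genes = 10) {
  make_toy_genome(length(lengths), lengths, n_genes = n_genes,
                  gene_length_range = c(500, 1500), seed = seed)
}

# A complete simulated dataset: genome, events, reads, truth.
tiny_sim <- function(seed = 101, n_events = 30, depth = 2000,
                     error_rate = 0, concatemers = NULL, ...) {
  toy <- tiny_world(seed)
  sc <- sim_config(n_events = n_events, depth = depth,
                   error_rate = error_rate, seed = seed + 1, ...)
  ev <- plant_integrations(toy$genome, sc)
  sim <- lam_pcr_reads(toy$genome, ev, toy_vector(), toy_linker(),
                       lam_enzymes(), sc, concatemers = concatemers)
  list(toy = toy, config = sc, events = ev, sim = sim)
}

# Independent brute-force two-sided Fisher p using explicit binomial
# coefficients (never dhyper), for oracle comparisons.
fisher_oracle <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Brute-force full-scan ungapped aligner: every position, both strands.
brute_force_hits <- function(fragment, genome, min_identity = 0.95) {
  seqs <- as.character(genome)
  len <- nchar(fragment)
  out <- NULL
  for (ci in seq_along(seqs)) {
    s <- seqs[ci]
    for (orient in c("+", "-")) {
      q <- if (orient == "+") fragment else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(fragment)))
      for (start0 in 0:(nchar(s) - len)) {
        ref <- substr(s, start0 + 1, start0 + len)
        mm <- sum(charToRaw(q) != charToRaw(ref))
        identity <- (len - mm) / len
        if (identity >= min_identity) {
          out <- rbind(out, data.frame(
            chrom = names(genome)[ci], start = start0,
            pos = if (orient == "+") start0 else start0 + len - 1,
            strand = orient, identity = identity,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  out
}
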