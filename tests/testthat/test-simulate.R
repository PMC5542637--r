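# Synthetic-data generator: toy genomes, planted events, restriction
# truncation, LAM-PCR amplicons.

test_that("make_toy_genome honours lengths, seed determinism and GC", {
  toy <- make_toy_genome(2, c(100000, 50000), n_genes = 8,
                         gene_length_range = c(500, 1500), seed = 7)
  expect_equal(unname(Biostrings::width(toy$genome)), c(100000L, 50000L))

  toy2 <- make_toy_genome(2, c(100000, 50000), n_genes = 8,
                          gene_length_range = c(500, 1500), seed = 7)
  expect_identical(as.character(toy$genome), as.character(toy2$genome))

  # binomial oracle: observed GC within 4 sd of the target
  toy3 <- make_toy_genome(1, 100000, gc_content = 0.6, n_genes = 0,
                          seed = 11)
  gc <- sum(Biostrings::letterFrequency(toy3$genome, c("G", "C"))) / 100000
  expect_lt(abs(gc - 0.6), 4 * sqrt(0.6 * 0.4 / 100000))
})

test_that("toy genome genes are in bounds, non-overlapping and flagged", {
  toy <- make_toy_genome(2, c(3e5, 2e5), n_genes = 25,
                         gene_length_range = c(1000, 3000),
                         cancer_fraction = 0.4, seed = 3)
  g <- toy$genes
  expect_equal(nrow(g), 25L)
  lens <- chrom_lengths <- stats::setNames(Biostrings::width(toy$genome),
                                           names(toy$genome))
  expect_true(all(g$start >= 0 & g$end <= lens[g$chrom]))
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  expect_equal(sum(g$cancer), 10L)
})

test_that("duplicated_segment copies a segment exactly", {
  dup <- list(src_chrom = "chr1", src_start = 1000L, length = 5000L,
              dest_chrom = "chr2", dest_start = 2000L)
  toy <- make_toy_genome(2, c(50000, 50000), n_genes = 0,
                         duplicated_segment = dup, seed = 9)
  a <- as.character(Biostrings::subseq(toy$genome[["chr1"]], 1001, 6000))
  b <- as.character(Biostrings::subseq(toy$genome[["chr2"]], 2001, 7000))
  expect_identical(a, b)
})

test_that("plant_integrations places events per the binomial oracles", {
  toy <- tiny_world(seed = 21, lengths = c(5e5, 5e5))

  expect_equal(nrow(plant_integrations(
    toy$genome, sim_config(n_events = 0, seed = 1))), 0L)

  # hotspot fraction
  cfg <- sim_config(n_events = 400,
                    hotspot = list(chrom = "chr1", start = 100000,
                                   end = 150000, fraction = 0.25),
                    seed = 5)
  ev <- plant_integrations(toy$genome, cfg)
  inside <- sum(ev$chrom == "chr1" & ev$pos >= 100000 & ev$pos < 150000)
  expect_lt(abs(inside - 100), 4 * sqrt(400 * 0.25 * 0.75))

  # no hotspot: two equal chromosomes split evenly
  cfg2 <- sim_config(n_events = 2000, seed = 6)
  ev2 <- plant_integrations(toy$genome, cfg2)
  expect_lt(abs(sum(ev2$chrom == "chr1") - 1000), 4 * sqrt(2000 * 0.25))

  expect_error(plant_integrations(
    toy$genome, sim_config(hotspot = list(chrom = "chr1", start = 0,
                                          end = 1e7, fraction = 0.5))),
    "hotspot window")
})

test_that("truncate_at_enzyme retains up to the nearest cut", {
  enz <- lam_enzymes()
  expect_identical(truncate_at_enzyme("ACGGTTAACC", enz$MseI), "ACGGT")
  expect_identical(truncate_at_enzyme("ACGAATTCGG", enz$MluCI), "ACG")
  expect_true(is.na(truncate_at_enzyme("ACGCGCGCGC", enz)))
  # nearest site of ANY enzyme wins
  expect_identical(truncate_at_enzyme("CCAATTCCTTAACC", enz), "CC")
  # site beyond max_flank is ignored
  expect_true(is.na(truncate_at_enzyme("ACGGTTAACC", enz$MseI,
                                       max_flank = 3)))
  expect_error(truncate_at_enzyme("", enz), "non-empty")
})

test_that("error-free reads reconstruct the amplicon exactly", {
  # plant one event with a known MseI site 30 nt downstream
  toy <- tiny_world(seed = 31, lengths = c(5000, 5000), n_genes = 2)
  s <- as.character(toy$genome[["chr1"]])
  flank30 <- paste0(paste(rep("C", 30), collapse = ""), "TTAA")
  substr(s, 2001, 2000 + nchar(flank30)) <- flank30
  genome <- Biostrings::DNAStringSet(c(chr1 = s,
                                       chr2 = as.character(
                                         toy$genome[["chr2"]])))
  ev <- data.frame(event_id = "ev1", chrom = "chr1", pos = 2000L,
                   orient = "+", abundance = 1, stringsAsFactors = FALSE)
  cfg <- sim_config(n_events = 1, depth = 50, error_rate = 0,
                    max_flank = 100, seed = 2)
  vc <- toy_vector(); lk <- toy_linker()
  sim <- lam_pcr_reads(genome, ev, vc, lk, lam_enzymes(), cfg)
  expected <- substr(paste0(substr(vc$sequence, vc$anchor_start + 1,
                                   vc$terminus_offset),
                            paste0(substr(s, 2001, 2031)),
                            lk$sequence), 1, cfg$read_length)
  expect_equal(nrow(sim$reads), 50L)
  expect_true(all(sim$reads$sequence == expected))
  expect_true(all(sim$truth$recoverable))
})

test_that("events without a reachable enzyme site emit no reads", {
  toy <- tiny_world(seed = 41, lengths = c(20000, 20000))
  cfg <- sim_config(n_events = 40, depth = 1000, error_rate = 0,
                    max_flank = 30, seed = 3)  # short window: sites often missed
  ev <- plant_integrations(toy$genome, cfg)
  sim <- lam_pcr_reads(toy$genome, ev, toy_vector(), toy_linker(),
                       lam_enzymes(), cfg)
  no_amp <- sim$events$event_id[is.na(sim$events$fragment_length)]
  expect_gt(length(no_amp), 0)  # the short window must exclude some events
  expect_false(any(sim$truth$source_id %in% no_amp))
  expect_false(any(sim$events$recoverable[is.na(sim$events$fragment_length)]))
})

test_that("read allocation follows abundances multinomially", {
  toy <- tiny_world(seed = 51, lengths = c(50000, 50000))
  cfg <- sim_config(n_events = 2, depth = 1000, error_rate = 0,
                    abundance_model = "uniform", seed = 4)
  ev <- plant_integrations(toy$genome, cfg)
  ev$abundance <- c(9, 1)
  sim <- lam_pcr_reads(toy$genome, ev, toy_vector(), toy_linker(),
                       lam_enzymes(), cfg)
  # both events must be amplifiable for the 9:1 check to make sense
  expect_true(all(!is.na(sim$events$fragment_length)))
  n1 <- sum(sim$truth$source_id == "ev0001")
  expect_lt(abs(n1 - 900), 4 * sqrt(1000 * 0.9 * 0.1))
  expect_equal(nrow(sim$reads), 1000L)
})

test_that("simulation invariants: depth, bijective truth, determinism", {
  ts <- tiny_sim(seed = 61, n_events = 20, depth = 1500,
                 concatemers = concatemer_junctions(abundances = c(2, 1, 1)))
  sim <- ts$sim
  expect_equal(nrow(sim$reads), 1500L)
  expect_identical(sort(sim$reads$read_id), sort(sim$truth$read_id))
  expect_equal(anyDuplicated(sim$reads$read_id), 0L)

  ts2 <- tiny_sim(seed = 61, n_events = 20, depth = 1500,
                  concatemers = concatemer_junctions(abundances = c(2, 1, 1)))
  expect_identical(sim$reads, ts2$sim$reads)
  expect_identical(sim$truth, ts2$sim$truth)
})

test_that("reads round-trip through FASTQ", {
  ts <- tiny_sim(seed = 71, n_events = 5, depth = 100)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(ts$sim, fq)
  back <- read_fastq(fq)
  expect_identical(back$read_id, ts$sim$reads$read_id)
  expect_identical(back$sequence, ts$sim$reads$sequence)
})
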