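# Site collapsing, clonal quantification, sample summaries, persistence.

mk_mapped <- function(pos, chrom = "chr1", strand = "+",
                      status = "unique") {
  n <- length(pos)
  data.frame(read_id = paste0("r", seq_len(n)), fragment = "",
             chrom = rep_len(chrom, n), pos = pos,
             strand = rep_len(strand, n), score = 1,
             n_best = ifelse(rep_len(status, n) == "multi", 2L, 1L),
             status = rep_len(status, n), stringsAsFactors = FALSE)
}

test_that("collapse_sites merges within the window and is strand-aware", {
  s1 <- collapse_sites(mk_mapped(c(1000, 1001, 1002, 1000)), window_bp = 3)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$read_count, 4L)
  expect_equal(s1$pos, 1000L)  # modal position

  s2 <- collapse_sites(mk_mapped(c(1000, 1010)), window_bp = 3)
  expect_equal(nrow(s2), 2L)

  m3 <- rbind(mk_mapped(1000, strand = "+"), mk_mapped(1000, strand = "-"))
  expect_equal(nrow(collapse_sites(m3, window_bp = 3)), 2L)

  # multi and unmapped junctions are excluded
  m4 <- rbind(mk_mapped(1000), mk_mapped(5000, status = "multi"))
  expect_equal(nrow(collapse_sites(m4)), 1L)
})

test_that("collapse_sites is idempotent", {
  set.seed(43)
  pos <- sort(sample(1:100000, 80))
  sites <- collapse_sites(mk_mapped(pos), window_bp = 3)
  again <- collapse_sites(
    data.frame(read_id = paste0("s", seq_len(nrow(sites))), fragment = "",
               chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               score = 1, n_best = 1L, status = "unique",
               stringsAsFactors = FALSE), window_bp = 3)
  expect_identical(again$pos, sites$pos)
  expect_equal(nrow(again), nrow(sites))
})

test_that("quantify_sites normalises and top_sites ranks correctly", {
  sites <- data.frame(chrom = "chr1", pos = c(1, 2, 3) * 1000,
                      strand = "+", read_count = c(50L, 30L, 20L),
                      stringsAsFactors = FALSE)
  q <- quantify_sites(sites)
  expect_equal(q$relative_count, c(0.5, 0.3, 0.2))

  one <- quantify_sites(sites[1, ])
  expect_equal(one$relative_count, 1.0)

  expect_error(quantify_sites(sites[0, ]), "no sites")

  set.seed(47)
  many <- data.frame(chrom = "chr1", pos = (1:12) * 1000, strand = "+",
                     read_count = sample(1:100, 12),
                     stringsAsFactors = FALSE)
  top <- top_sites(many, 10)
  expect_equal(nrow(top), 10L)
  expect_gte(min(top$read_count), max(many$read_count[
    !paste(many$chrom, many$pos) %in% paste(top$chrom, top$pos)]))
})

test_that("relative counts sum to one on simulated data", {
  ts <- tiny_sim(seed = 53, n_events = 20, depth = 1500)
  calls <- classify_reads(filter_quality(ts$sim)$reads, toy_vector(),
                          toy_linker())
  idx <- build_index(ts$toy$genome, k = 16)
  sites <- quantify_sites(collapse_sites(map_fragments(calls, idx)))
  expect_equal(sum(sites$relative_count), 1, tolerance = 1e-9)
})

test_that("summarize_sample reproduces the composition percentages", {
  mk_calls <- function(n_is, n_conc, n_int = 0, n_unc = 0) {
    data.frame(read_id = paste0("r", seq_len(n_is + n_conc + n_int + n_unc)),
               category = rep(c("IS", "concatemer", "internal",
                                "unclassified"),
                              c(n_is, n_conc, n_int, n_unc)),
               fragment = "", anchor_end = NA_integer_,
               linker_found = FALSE, stringsAsFactors = FALSE)
  }
  # the composition printed for the re-challenged animal: 61.4% IS
  s <- summarize_sample(mk_calls(614, 386))
  expect_equal(s$pct_is, 61.4)
  expect_equal(s$pct_concatemer, 38.6)
  expect_equal(s$pct_is + s$pct_concatemer, 100)

  s2 <- summarize_sample(mk_calls(100, 0))
  expect_equal(s2$pct_is, 100)
  expect_equal(s2$pct_concatemer, 0)

  s3 <- summarize_sample(mk_calls(0, 0, 0, 10))
  expect_true(is.na(s3$pct_is) && is.na(s3$pct_concatemer))

  # site accounting: unique sites + multi clusters
  mapped <- rbind(mk_mapped(c(1000, 2000)),
                  mk_mapped(c(5000, 9000), status = "multi"))
  sites <- collapse_sites(mapped)
  s4 <- summarize_sample(mk_calls(4, 0), mapped, sites,
                         dna_mass_ug = 2)
  expect_equal(s4$n_sites_unique, 2L)
  expect_equal(s4$n_sites_multi, 2L)
  expect_equal(s4$n_sites_total, 4L)
  expect_equal(s4$is_per_ug, 2)
})

test_that("serial_persistence finds sites shared across time points", {
  t1 <- data.frame(chrom = "chr1", pos = c(1000L, 5000L), strand = "+",
                   read_count = c(10L, 5L), stringsAsFactors = FALSE)
  t2 <- data.frame(chrom = "chr1", pos = c(1001L, 9000L), strand = "+",
                   read_count = c(7L, 3L), stringsAsFactors = FALSE)
  res <- serial_persistence(list(t1 = t1, t2 = t2), window_bp = 3)
  expect_equal(sum(res$persistent), 1L)
  hit <- res[res$persistent, ]
  expect_equal(hit$pos, 1000L)
  expect_equal(hit$timepoints, "t1,t2")

  # disjoint sets: nothing persists
  t3 <- data.frame(chrom = "chr2", pos = 2000L, strand = "+",
                   read_count = 1L, stringsAsFactors = FALSE)
  res2 <- serial_persistence(list(t1 = t1, t3 = t3), window_bp = 3)
  expect_equal(sum(res2$persistent), 0L)

  expect_error(serial_persistence(list(t1 = t1)), ">=2 time points")
})

test_that("sites get nearest-gene annotation with signed distances", {
  genes <- data.frame(chrom = "chr1", start = 10000L, end = 12000L,
                      strand = "+", name = "geneA", cancer = FALSE,
                      stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(11000L, 9000L, 13000L),
                      strand = "+", read_count = 1L,
                      stringsAsFactors = FALSE)
  ann <- annotate_sites(sites, genes)
  expect_equal(ann$nearest_gene, rep("geneA", 3))
  expect_true(ann$in_gene[1])
  expect_equal(ann$distance_to_gene[1], 0L)
  expect_equal(ann$distance_to_gene[2], -1000L)  # upstream of gene start
  expect_equal(ann$distance_to_gene[3], 1001L)   # downstream of gene end
})
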