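# Synthetic random datasets, Fisher machinery, hotspot scan, gene
# context, cancer-gene enrichment.

test_that("random_null samples the requested size uniformly", {
  lens <- c(chr1 = 5e5, chr2 = 5e5)
  null <- random_null(lens, size = 8628, seed = 2)
  expect_equal(nrow(null), 8628L)
  expect_true(all(null$pos >= 0 & null$pos < lens[null$chrom]))

  null2 <- random_null(lens, size = 10000, seed = 3)
  expect_lt(abs(sum(null2$chrom == "chr1") - 5000), 4 * sqrt(10000 * 0.25))

  # determinism
  expect_equal(random_null(lens, 500, seed = 9),
               random_null(lens, 500, seed = 9))
})

test_that("site-matched nulls land exactly on enzyme cut positions", {
  toy <- tiny_world(seed = 63, lengths = c(50000, 50000))
  null <- random_null(toy$genome, size = 2000, mode = "site_matched",
                      enzymes = lam_enzymes(), seed = 4)
  seqs <- as.character(toy$genome)
  ok <- vapply(seq_len(nrow(null)), function(i) {
    s <- seqs[[null$chrom[i]]]
    p <- null$pos[i]
    # pos is a cut position: site TTAA starting at pos-1 (T^TAA) or
    # AATT starting at pos (^AATT)
    (p >= 1 && substr(s, p, p + 3) == "TTAA") ||
      substr(s, p + 1, p + 4) == "AATT"
  }, logical(1))
  expect_true(all(ok))

  expect_error(random_null(
    Biostrings::DNAStringSet(c(chr1 = strrep("G", 1000))),
    size = 10, mode = "site_matched", enzymes = lam_enzymes()),
    "no restriction sites")
})

test_that("fisher_exact matches symmetry and enumeration oracles", {
  expect_equal(fisher_exact(c(5, 5, 5, 5))$p_value, 1.0)
  expect_equal(fisher_exact(c(2, 0, 0, 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(c(1, 9, 11, 3))$p_value,
               fisher_oracle(1, 9, 11, 3), tolerance = 1e-12)
  expect_error(fisher_exact(c(0, 0, 0, 0)), "all-zero")
  expect_true(is.na(fisher_exact(c(0, 5, 0, 5))$odds_ratio))
  expect_equal(fisher_exact(c(4, 2, 1, 8))$odds_ratio, 16)
})

test_that("fisher_exact agrees with stats::fisher.test across a sweep", {
  set.seed(71)
  for (i in 1:200) {
    x <- as.integer(rmultinom(1, sample(4:50, 1), rep(1, 4)))
    if (sum(x) == 0) next
    mine <- fisher_exact(x)$p_value
    ref <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("hotspot scan flags a loaded chromosome and spares the null", {
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  null <- random_null(lens, size = 8628, seed = 5)
  # all sites on chr1: flagged with q far below alpha
  sites <- data.frame(chrom = "chr1",
                      pos = as.integer(seq(1000, 999000, length.out = 120)),
                      strand = "+", stringsAsFactors = FALSE)
  scan <- chrom_hotspot_scan(sites, null, alpha = 0.05)
  expect_true(scan$hotspot[scan$label == "chr1"])
  expect_lt(scan$q_value[scan$label == "chr1"], 1e-10)

  # single-chromosome genome: one row, q equals p
  null1 <- random_null(c(chr1 = 1e6), size = 1000, seed = 6)
  sites1 <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                       stringsAsFactors = FALSE)
  scan1 <- chrom_hotspot_scan(sites1, null1)
  expect_equal(nrow(scan1), 1L)
  expect_equal(scan1$q_value, scan1$p_value)

  expect_error(chrom_hotspot_scan(sites1[0, ], null1), "empty")
})

test_that("gene_context bins by distance and fractions sum to one", {
  genes <- data.frame(chrom = "chr1", start = 100000L, end = 120000L,
                      strand = "+", name = "geneA", cancer = FALSE,
                      stringsAsFactors = FALSE)
  pos <- data.frame(chrom = "chr1",
                    pos = c(110000L,          # inside
                            125000L,          # 5 kb away
                            170000L,          # 50 kb away
                            350000L),         # 230 kb away
                    strand = "+", stringsAsFactors = FALSE)
  ctx <- gene_context(pos, genes)
  expect_equal(ctx$count, rep(1L, 4))
  expect_equal(ctx$bin, c("in_gene", "<=10kb", "10kb-100kb", ">100kb"))
  expect_equal(sum(ctx$fraction), 1)

  # no genes: everything lands in the farthest bin, with a warning
  expect_warning(ctx0 <- gene_context(pos, genes[0, ]), "no genes")
  expect_equal(ctx0$count, c(0L, 0L, 0L, 4L))
})

test_that("null gene-context converges to annotation geometry", {
  toy <- make_toy_genome(2, c(5e5, 5e5), n_genes = 30, seed = 73)
  null <- random_null(toy$genome, size = 50000, seed = 74)
  ctx <- gene_context(null, toy$genes)
  # analytic expectation from interval geometry
  gr <- GenomicRanges::GRanges(
    toy$genes$chrom,
    IRanges::IRanges(toy$genes$start + 1L, toy$genes$end))
  lens <- stats::setNames(Biostrings::width(toy$genome),
                          names(toy$genome))
  total <- sum(lens)
  cov_width <- function(expand) {
    g <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2 * expand,
                               fix = "center")
    g <- GenomicRanges::trim(GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(g), IRanges::IRanges(
        pmax(BiocGenerics::start(g), 1),
        pmin(BiocGenerics::end(g), lens[as.character(
          GenomeInfoDb::seqnames(g))]))))
    sum(GenomicRanges::width(GenomicRanges::reduce(g)))
  }
  f_gene <- cov_width(0) / total
  f_10k <- cov_width(1e4) / total - f_gene
  f_100k <- cov_width(1e5) / total - f_gene - f_10k
  f_far <- 1 - f_gene - f_10k - f_100k
  expect_equal(ctx$fraction, c(f_gene, f_10k, f_100k, f_far),
               tolerance = 0.012)
})

test_that("cancer_gene_enrichment reports fractions and Fisher p", {
  genes <- data.frame(chrom = c("chr1", "chr1"),
                      start = c(10000L, 50000L), end = c(20000L, 60000L),
                      strand = "+", name = c("onc1", "bystander"),
                      cancer = c(TRUE, FALSE), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(15000L, 55000L, 80000L),
                      strand = "+", stringsAsFactors = FALSE)
  null <- data.frame(chrom = "chr1",
                     pos = as.integer(seq(25000, 45000, length.out = 50)),
                     strand = "+", stringsAsFactors = FALSE)
  enr <- cancer_gene_enrichment(sites, genes, null)
  expect_equal(enr$sample_in, 1L)
  expect_equal(enr$null_in, 0L)
  expect_equal(enr$sample_pct, 100 / 3)
  expect_equal(enr$p_value,
               fisher_oracle(1, 2, 0, 50), tolerance = 1e-12)

  expect_error(cancer_gene_enrichment(sites, genes[!genes$cancer, ], null),
               "cancer-flagged")

  # extremes: nothing in cancer genes in either set -> p = 1
  far <- data.frame(chrom = "chr1", pos = c(80000L, 90000L), strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(cancer_gene_enrichment(far, genes, null)$p_value, 1)

  # everything in cancer genes vs nothing -> tiny p
  all_in <- data.frame(chrom = "chr1",
                       pos = as.integer(seq(10500, 19500, length.out = 50)),
                       strand = "+", stringsAsFactors = FALSE)
  big_null <- data.frame(chrom = "chr1",
                         pos = as.integer(seq(25000, 45000,
                                              length.out = 1000)),
                         strand = "+", stringsAsFactors = FALSE)
  expect_lt(cancer_gene_enrichment(all_in, genes, big_null)$p_value, 1e-6)
})
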