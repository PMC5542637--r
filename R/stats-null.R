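# Synthetic random IS datasets and the comparative statistics used to
# test for chromosomal hotspots and cancer-gene enrichment.

#' Generate a synthetic random integration-site dataset
#'
#' The null comparison distribution for hotspot and enrichment tests.
#' `uniform` mode samples positions uniformly over the total genome
#' length; `site_matched` mode samples uniformly among all restriction
#' cut positions, modelling the recovery bias of restriction-based
#' LAM-PCR. Strand is a fair coin. The default size of 8,628 mirrors the
#' scale at which such random datasets are typically generated.
#'
#' @param genome A [Biostrings::DNAStringSet], or (for `uniform` mode) a
#'   named numeric vector of chromosome lengths.
#' @param size Number of null positions.
#' @param mode `"uniform"` or `"site_matched"`.
#' @param enzymes Required for `site_matched`: list of
#'   [restriction_enzyme()]s whose cut positions are sampled.
#' @param seed Integer seed.
#' @return A `data.frame` (`chrom`, `pos`, `strand`) with attributes
#'   `mode`, `size` and `seed`.
#' @export
random_null <- function(genome, size = 8628, mode = c("uniform",
                                                      "site_matched"),
                        enzymes = NULL, seed = NULL) {
  mode <- match.arg(mode)
  size <- as.integer(size)
  if (size < 1) stop("size must be >= 1")
  lens <- chrom_lengths(genome)
  out <- with_seed(seed, {
    if (mode == "uniform") {
      ci <- sample.int(length(lens), size, replace = TRUE, prob = lens)
      data.frame(chrom = names(lens)[ci],
                 pos = as.integer(floor(stats::runif(size) * lens[ci])),
                 strand = sample(c("+", "-"), size, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      if (is.null(enzymes)) stop("site_matched mode requires enzymes")
      if (!methods::is(genome, "DNAStringSet")) {
        stop("site_matched mode requires genome sequences")
      }
      cuts <- enzyme_cut_positions(genome, enzymes)
      if (nrow(cuts) == 0) {
        stop("no restriction sites found in genome; cannot build a ",
             "site-matched null")
      }
      pick <- sample.int(nrow(cuts), size, replace = TRUE)
      data.frame(chrom = cuts$chrom[pick], pos = cuts$pos[pick],
                 strand = sample(c("+", "-"), size, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
  })
  attr(out, "mode") <- mode
  attr(out, "size") <- size
  attr(out, "seed") <- seed
  out
}

# All cut positions (site start + cut offset) of the enzymes over the
# genome plus strand.
enzyme_cut_positions <- function(genome, enzymes) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  seqs <- as.character(genome)
  rows <- list()
  for (i in seq_along(seqs)) {
    for (enz in enzymes) {
      hits <- gregexpr(enz$recognition, seqs[i], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(genome)[i],
        pos = as.integer(hits) - 1L + enz$cut_offset,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (with a small relative tolerance for
#' floating-point ties), and the sample odds ratio `ad/bc`.
#'
#' @param table A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `(a, b, c, d)` filling the table by row.
#' @return A list with `odds_ratio` (NA when 0/0) and `p_value`.
#' @export
#' @examples
#' fisher_exact(c(5, 5, 5, 5))$p_value   # 1
fisher_exact <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    x <- as.vector(t(table))
  } else {
    stopifnot(length(table) == 4)
    x <- as.numeric(table)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  if (sum(x) == 0) stop("all-zero table")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (a * d == 0 && b * cc == 0) NA_real_ else (a * d) / (b * cc)
  list(odds_ratio = or, p_value = p)
}

# One enrichment-result row.
enrichment_row <- function(label, a, b, cc, d) {
  ft <- fisher_exact(c(a, b, cc, d))
  data.frame(label = label, sample_in = a, sample_out = b,
             null_in = cc, null_out = d, odds_ratio = ft$odds_ratio,
             p_value = ft$p_value, stringsAsFactors = FALSE)
}

#' Scan chromosomes for integration hotspots
#'
#' For every chromosome, compares the on/off-chromosome split of the
#' sample sites against the null dataset with Fisher's exact test, then
#' adjusts across chromosomes. A chromosome is flagged a hotspot when its
#' adjusted p-value falls below `alpha`.
#'
#' @param sites Site or position table (`chrom`, `pos`).
#' @param null Null dataset from [random_null()].
#' @param alpha Significance level on the adjusted scale.
#' @param correction `"BH"`, `"bonferroni"` or `"none"`.
#' @return A `data.frame` with one row per chromosome: counts, odds
#'   ratio, `p_value`, `q_value`, `hotspot`.
#' @export
chrom_hotspot_scan <- function(sites, null, alpha = 0.05,
                               correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  if (nrow(sites) == 0) stop("empty site list")
  chroms <- sort(unique(c(sites$chrom, null$chrom)))
  rows <- lapply(chroms, function(ch) {
    a <- sum(sites$chrom == ch); b <- nrow(sites) - a
    cc <- sum(null$chrom == ch); d <- nrow(null) - cc
    enrichment_row(ch, a, b, cc, d)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = correction)
  out$hotspot <- out$q_value < alpha
  out
}

# Distances from positions to the nearest gene span (0 inside).
gene_distances <- function(positions, genes) {
  if (nrow(genes) == 0) return(rep(Inf, nrow(positions)))
  gr_pos <- GenomicRanges::GRanges(
    positions$chrom, IRanges::IRanges(positions$pos + 1L, width = 1L))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  d <- rep(Inf, nrow(positions))
  hits <- GenomicRanges::distanceToNearest(gr_pos, gr_genes,
                                           ignore.strand = TRUE)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  inside <- GenomicRanges::countOverlaps(gr_pos, gr_genes,
                                         ignore.strand = TRUE) > 0
  d[inside] <- 0
  attr(d, "inside") <- inside
  d
}

fmt_bp <- function(x) {
  if (x %% 1000 == 0) paste0(x / 1000, "kb") else paste0(x, "bp")
}

#' Gene-context distribution of integration positions
#'
#' Assigns each position to a distance-to-gene bin: inside a gene, or
#' within successive distance bands of the nearest gene span (defaults:
#' <=10 kb, 10-100 kb, >100 kb). Fractions sum to 1.
#'
#' @param positions Position table (`chrom`, `pos`) -- sites or a null
#'   dataset.
#' @param genes Gene table; with no genes, every position lands in the
#'   farthest bin (with a warning).
#' @param breaks Increasing distance break points in bp.
#' @return A `data.frame` (`bin`, `count`, `fraction`) with one row per
#'   bin in order.
#' @export
gene_context <- function(positions, genes, breaks = c(1e4, 1e5)) {
  labels <- c("in_gene", paste0("<=", fmt_bp(breaks[1])))
  if (length(breaks) > 1) {
    for (i in seq_len(length(breaks) - 1)) {
      labels <- c(labels, paste0(fmt_bp(breaks[i]), "-",
                                 fmt_bp(breaks[i + 1])))
    }
  }
  labels <- c(labels, paste0(">", fmt_bp(breaks[length(breaks)])))
  if (nrow(genes) == 0) {
    warning("no genes in annotation; all positions assigned to the ",
            "farthest bin")
    counts <- c(rep(0L, length(labels) - 1L), nrow(positions))
  } else {
    d <- gene_distances(positions, genes)
    inside <- attr(d, "inside")
    bin <- findInterval(d, c(0, breaks), left.open = TRUE) + 1L
    bin <- pmax(bin, 2L)  # distance-0 but outside a gene is the first band
    bin[inside] <- 1L
    bin <- pmin(bin, length(labels))
    counts <- tabulate(bin, nbins = length(labels))
  }
  data.frame(bin = labels, count = counts,
             fraction = if (sum(counts) > 0) counts / sum(counts)
                        else rep(NA_real_, length(labels)),
             stringsAsFactors = FALSE)
}

#' Compare two gene-context distributions
#'
#' Tests whether the bin occupancies of a sample distribution differ from
#' a null distribution, either bin-by-bin with Fisher's exact test
#' (Benjamini-Hochberg adjusted) or globally with a chi-square test.
#'
#' @param sample_ctx,null_ctx Outputs of [gene_context()] on the same
#'   bins.
#' @param method `"fisher"` (per bin) or `"chisq"` (global).
#' @param correction Adjustment across bins for the Fisher method.
#' @return For `"fisher"`, a `data.frame` with one row per bin; for
#'   `"chisq"`, the `htest` result of [stats::chisq.test()].
#' @export
compare_gene_context <- function(sample_ctx, null_ctx,
                                 method = c("fisher", "chisq"),
                                 correction = "BH") {
  method <- match.arg(method)
  stopifnot(identical(sample_ctx$bin, null_ctx$bin))
  if (method == "chisq") {
    return(stats::chisq.test(rbind(sample_ctx$count, null_ctx$count)))
  }
  ns <- sum(sample_ctx$count); nn <- sum(null_ctx$count)
  rows <- lapply(seq_len(nrow(sample_ctx)), function(i) {
    enrichment_row(sample_ctx$bin[i], sample_ctx$count[i],
                   ns - sample_ctx$count[i], null_ctx$count[i],
                   nn - null_ctx$count[i])
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = correction)
  out
}

#' Cancer-gene enrichment of integration sites
#'
#' Counts sample sites and null positions falling within cancer-flagged
#' gene spans (optionally extended by `extension` bp on both sides) and
#' tests the 2x2 table with Fisher's exact test.
#'
#' @param sites Site table (`chrom`, `pos`).
#' @param genes Gene table with a logical `cancer` column; at least one
#'   cancer-flagged gene is required.
#' @param null Null dataset from [random_null()].
#' @param extension Span extension in bp (default 0: the gene body only).
#' @return A one-row `data.frame` with counts, the in-cancer percentages
#'   of sample and null, the odds ratio and the two-sided p-value.
#' @export
cancer_gene_enrichment <- function(sites, genes, null, extension = 0) {
  cg <- genes[genes$cancer, , drop = FALSE]
  if (nrow(cg) == 0) stop("no cancer-flagged genes in annotation")
  count_in <- function(positions) {
    gr_pos <- GenomicRanges::GRanges(
      positions$chrom, IRanges::IRanges(positions$pos + 1L, width = 1L))
    gr_cg <- GenomicRanges::GRanges(
      cg$chrom, IRanges::IRanges(pmax(cg$start + 1L - extension, 1L),
                                 cg$end + extension))
    sum(GenomicRanges::countOverlaps(gr_pos, gr_cg,
                                     ignore.strand = TRUE) > 0)
  }
  a <- count_in(sites); b <- nrow(sites) - a
  cc <- count_in(null); d <- nrow(null) - cc
  out <- enrichment_row("cancer_genes", a, b, cc, d)
  out$sample_pct <- 100 * a / nrow(sites)
  out$null_pct <- 100 * cc / nrow(null)
  out
}
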