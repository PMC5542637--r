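#' Generate a toy reference genome with gene annotation
#'
#' Produces an i.i.d. random genome with a stated GC content plus a
#' non-overlapping gene annotation, a configurable fraction of which is
#' cancer-flagged. An optional exact duplication of a segment at a second
#' locus creates multi-mapping ground truth. Fully reproducible from the
#' seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths (recycled to
#'   `n_chrom` if length 1).
#' @param gc_content GC fraction in (0, 1).
#' @param n_genes Number of genes to place (non-overlapping).
#' @param cancer_fraction Fraction of genes to flag as cancer-related.
#' @param gene_length_range Range (min, max) of gene lengths in bp.
#' @param duplicated_segment Optional list with elements `src_chrom`,
#'   `src_start` (0-based), `length`, `dest_chrom`, `dest_start`; the
#'   destination is overwritten with an exact copy of the source segment.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and
#'   `genes` (a gene table as from [read_annotation()]).
#' @export
#' @examples
#' toy <- make_toy_genome(2, c(50000, 30000), n_genes = 5, seed = 1)
#' width(toy$genome)
make_toy_genome <- function(n_chrom = 2, lengths = c(1e6, 1e6),
                            gc_content = 0.41, n_genes = 60,
                            cancer_fraction = 0.3,
                            gene_length_range = c(5000, 15000),
                            duplicated_segment = NULL, seed = NULL) {
  lengths <- as.integer(rep_len(lengths, n_chrom))
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  with_seed(seed, {
    seqs <- vapply(lengths, random_dna, character(1), gc_content = gc_content)
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(n_chrom))
    if (!is.null(duplicated_segment)) {
      d <- duplicated_segment
      src <- as.character(Biostrings::subseq(
        genome[[d$src_chrom]], d$src_start + 1L, d$src_start + d$length))
      s <- as.character(genome[[d$dest_chrom]])
      substr(s, d$dest_start + 1L, d$dest_start + d$length) <- src
      genome[[d$dest_chrom]] <- Biostrings::DNAString(s)
    }
    genes <- place_genes(lengths, names(genome), n_genes,
                         cancer_fraction, gene_length_range)
    list(genome = genome, genes = genes)
  })
}

# Place n_genes non-overlapping genes by rejection sampling.
place_genes <- function(lengths, chrom_names, n_genes, cancer_fraction,
                        gene_length_range) {
  if (n_genes == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), cancer = logical(),
                      stringsAsFactors = FALSE))
  }
  glen <- as.integer(round(stats::runif(n_genes, gene_length_range[1],
                                        gene_length_range[2])))
  if (sum(glen) > 0.7 * sum(lengths)) {
    stop("requested genes exceed genome capacity (", sum(glen),
         " bp of genes for ", sum(lengths), " bp of genome)")
  }
  placed <- vector("list", length(lengths))
  chrom <- integer(n_genes); start <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      ci <- sample.int(length(lengths), 1, prob = lengths)
      if (lengths[ci] <= glen[i]) next
      s <- as.integer(floor(stats::runif(1, 0, lengths[ci] - glen[i])))
      e <- s + glen[i]
      prev <- placed[[ci]]
      if (is.null(prev) || all(e <= prev[, 1] | s >= prev[, 2])) {
        placed[[ci]] <- rbind(prev, c(s, e))
        chrom[i] <- ci; start[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place gene ", i,
                  " without overlap; genome too crowded")
  }
  genes <- data.frame(
    chrom = chrom_names[chrom],
    start = start,
    end = start + glen,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    name = sprintf("gene%03d", seq_len(n_genes)),
    cancer = FALSE,
    stringsAsFactors = FALSE
  )
  n_cancer <- round(cancer_fraction * n_genes)
  if (n_cancer > 0) {
    genes$cancer[sample.int(n_genes, n_cancer)] <- TRUE
  }
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}
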