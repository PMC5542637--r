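#' Read a reference genome from FASTA
#'
#' Loads a (toy or real) reference genome and validates the invariants the
#' pipeline relies on: unique record names, sequences restricted to
#' A/C/G/T/N, and a positive total length. Lowercase bases are normalised
#' to uppercase. Record names are truncated at the first whitespace, as is
#' conventional for sequence identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per chromosome.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGT"), fa)
#' g <- read_genome(fa)
#' width(g)
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    stop("FASTA format error: no records in ", path)
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("FASTA format error at line ", nonempty[1],
         ": expected a header line starting with '>'")
  }
  is_header <- startsWith(lines, ">")
  bad <- which(!is_header & nzchar(trimws(lines)) &
                 !grepl("^[ACGTNacgtn]+$", lines))
  if (length(bad)) {
    stop("FASTA format error at line ", bad[1],
         ": sequence contains characters outside A/C/G/T/N")
  }
  genome <- Biostrings::readDNAStringSet(path)
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  names(genome) <- sub("\\s.*$", "", names(genome))
  dup <- unique(names(genome)[duplicated(names(genome))])
  if (length(dup)) {
    stop("duplicate record name(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  if (sum(Biostrings::width(genome)) == 0) {
    stop("FASTA format error: total sequence length is zero")
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read gene annotation from BED or GFF3
#'
#' Produces the gene table used throughout the pipeline. Internally all
#' coordinates are 0-based half-open; BED input is taken as-is, GFF3 input
#' is converted from 1-based inclusive. An optional plain-text list of gene
#' names marks cancer-related genes (standing in for curated unions such as
#' the Cancer Gene Census and retroviral-tagged cancer gene databases).
#'
#' @param path Path to a BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param cancer_list_path Optional path to a text file with one gene name
#'   per line; matching genes get `cancer = TRUE`.
#' @param genome Optional genome (DNAStringSet or named lengths) used to
#'   validate feature bounds.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `name`, `cancer`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            cancer_list_path = NULL, genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer annotation format from extension '",
                          ext, "'; pass format explicitly"))
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  nm <- NULL
  for (col in c("name", "Name", "ID", "gene_id")) {
    if (col %in% names(S4Vectors::mcols(gr))) {
      cand <- as.character(S4Vectors::mcols(gr)[[col]])
      if (!all(is.na(cand))) { nm <- cand; break }
    }
  }
  if (is.null(nm)) nm <- paste0("feature", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  genes <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    name = nm,
    cancer = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    missing_chrom <- setdiff(genes$chrom, names(lens))
    if (length(missing_chrom)) {
      stop("annotation references chromosome(s) absent from genome: ",
           paste(missing_chrom, collapse = ", "))
    }
    oob <- genes$start < 0 | genes$end > lens[genes$chrom] |
      genes$start >= genes$end
    if (any(oob)) {
      stop("feature(s) out of chromosome bounds: ",
           paste(genes$name[oob], collapse = ", "))
    }
  }
  if (!is.null(cancer_list_path)) {
    genes$cancer <- genes$name %in% read_cancer_list(cancer_list_path)
  }
  genes
}

#' Read a cancer-gene name list
#'
#' One gene name per line; blank lines and `#` comments ignored.
#' @param path Path to the list.
#' @return Character vector of gene names.
#' @export
read_cancer_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write gene annotation as BED
#'
#' Emits 6-column BED (0-based half-open, matching the internal
#' convention), round-trippable through [read_annotation()].
#'
#' @param genes Gene table as returned by [read_annotation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$name,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Vector copy number per diploid cell
#'
#' Converts a measured vector copy count in a DNA aliquot into copies per
#' diploid cell, using the standard 6.6 pg of genomic DNA per diploid cell.
#'
#' @param measured_copies Vector genome copies measured (e.g. by qPCR).
#' @param dna_mass_pg Input DNA mass in picograms; must be positive.
#' @param pg_per_cell Genomic DNA mass per diploid cell (pg); default 6.6.
#' @return Copies per diploid cell.
#' @export
#' @examples
#' vcn_per_cell(1000, 66)   # 100 copies/cell
vcn_per_cell <- function(measured_copies, dna_mass_pg, pg_per_cell = 6.6) {
  if (any(dna_mass_pg <= 0)) stop("dna_mass_pg must be > 0")
  if (any(measured_copies < 0)) stop("measured_copies must be >= 0")
  measured_copies / (dna_mass_pg / pg_per_cell)
}
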