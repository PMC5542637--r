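#' Restriction enzyme definition
#'
#' A restriction enzyme is modelled by its recognition word and the cut
#' offset in bases from the start of the recognition site. LAM-PCR
#' amplicons are truncated at the first cut position downstream of the
#' vector-genome junction.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (A/C/G/T word).
#' @param cut_offset Cut position in bases from the recognition-site start;
#'   must lie in `[0, nchar(recognition)]`.
#' @return An object of class `restriction_enzyme`.
#' @export
#' @examples
#' restriction_enzyme("MseI", "TTAA", 1)   # T^TAA
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition) || !grepl("^[ACGT]+$", recognition)) {
    stop("recognition must be a non-empty A/C/G/T word")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    stop("cut_offset must be between 0 and the recognition length")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s (cut offset %d)\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

#' The LAM-PCR enzyme pair
#'
#' MseI (T^TAA) and MluCI (^AATT), the 4-cutters used for the restriction
#' digest that truncates LAM-PCR amplicons before adaptor ligation.
#'
#' @return A named list of two [restriction_enzyme()] objects.
#' @export
lam_enzymes <- function() {
  list(MseI = restriction_enzyme("MseI", "TTAA", 1L),
       MluCI = restriction_enzyme("MluCI", "AATT", 0L))
}

#' Vector construct model
#'
#' Describes the proviral construct seen by LAM-PCR: its sequence, the
#' vector-specific primer-proximal anchor expected at the 5' end of every
#' amplicon, and the terminus offset at which vector sequence gives way to
#' genomic flank in an integrated provirus. Coordinates are 0-based
#' half-open within the construct sequence.
#'
#' @param sequence Construct DNA sequence.
#' @param anchor_start,anchor_end Anchor span (0-based half-open); the
#'   anchor must be at least 15 nt long and lie within the sequence.
#' @param terminus_offset Position of the vector end at which genomic
#'   sequence begins; defaults to the construct length. Must satisfy
#'   `anchor_end <= terminus_offset <= nchar(sequence)`.
#' @return An object of class `vector_construct`.
#' @export
vector_construct <- function(sequence, anchor_start, anchor_end,
                             terminus_offset = nchar(sequence)) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]+$", sequence)) {
    stop("vector sequence must contain only A/C/G/T/N")
  }
  anchor_start <- as.integer(anchor_start)
  anchor_end <- as.integer(anchor_end)
  terminus_offset <- as.integer(terminus_offset)
  n <- nchar(sequence)
  if (anchor_start < 0 || anchor_end > n || anchor_start >= anchor_end) {
    stop("anchor span must lie within the construct sequence")
  }
  if (anchor_end - anchor_start < 15L) {
    stop("anchor must be at least 15 nt long")
  }
  if (terminus_offset < anchor_end || terminus_offset > n) {
    stop("terminus_offset must lie between anchor_end and the sequence end")
  }
  structure(list(sequence = sequence, anchor_start = anchor_start,
                 anchor_end = anchor_end, terminus_offset = terminus_offset),
            class = "vector_construct")
}

#' @export
print.vector_construct <- function(x, ...) {
  cat(sprintf(
    "<vector_construct> %d nt; anchor [%d,%d); terminus at %d\n",
    nchar(x$sequence), x$anchor_start, x$anchor_end, x$terminus_offset))
  invisible(x)
}

# The primer-proximal anchor sequence.
anchor_seq <- function(vc) {
  substr(vc$sequence, vc$anchor_start + 1L, vc$anchor_end)
}

# The vector segment present in every amplicon: anchor start .. terminus.
vector_segment <- function(vc) {
  substr(vc$sequence, vc$anchor_start + 1L, vc$terminus_offset)
}

#' Linker (ligated adaptor) model
#'
#' The adaptor ligated after restriction digest, expected at the 3' end of
#' full-length amplicons. Validated at load to share no exact substring of
#' 10 nt or more with the vector anchor, so that anchor and linker
#' detection cannot collide.
#'
#' @param sequence Linker DNA sequence.
#' @param vector Optional [vector_construct()]; when given, the
#'   distinguishability check against its anchor is run.
#' @return An object of class `linker_model`.
#' @export
linker_model <- function(sequence, vector = NULL) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || !grepl("^[ACGT]+$", sequence)) {
    stop("linker sequence must be a non-empty A/C/G/T word")
  }
  if (!is.null(vector)) {
    anc <- anchor_seq(vector)
    w <- 10L
    if (nchar(sequence) >= w) {
      for (i in seq_len(nchar(sequence) - w + 1L)) {
        sub <- substr(sequence, i, i + w - 1L)
        if (grepl(sub, anc, fixed = TRUE)) {
          stop("linker shares a >=10 nt substring with the vector anchor ('",
               sub, "'); choose distinguishable sequences")
        }
      }
    }
  }
  structure(list(sequence = sequence), class = "linker_model")
}

#' Shipped toy vector construct
#'
#' A fixed 240 nt construct used as the default in simulations and
#' examples. The final 20 nt form the primer anchor and the terminus
#' coincides with the construct end, so every amplicon begins with the
#' anchor followed directly by genomic flank. Real constructs (e.g.
#' scAAV cassettes) can be supplied through [vector_construct()].
#'
#' @return A `vector_construct`.
#' @export
toy_vector <- function() {
  seq <- paste0(
    "CTCTGCGGAGCGCCGTACGGGTGTCGACTGTATTGCCGATGCCCTAAGGGTCCGCTGAAC",
    "ATTGTTTACGTGCCGTCTATGCCATTAGCAGGATGGGACCAGTCAGTCTGGACTACGTCG",
    "GCCATAAGTCTCGAATGTACTACCTTCCGGGAGATACCATTGCACGAAGCAGGTTTACCA",
    "CCACGAGTGTGCCTGGAGGAAATAGGGAACGTGAGGCCCTGTCACTGAGCTGACACGATG")
  vector_construct(seq, anchor_start = 220L, anchor_end = 240L,
                   terminus_offset = 240L)
}

#' Shipped toy linker
#'
#' A fixed 30 nt adaptor, validated against the [toy_vector()] anchor.
#'
#' @return A `linker_model`.
#' @export
toy_linker <- function() {
  linker_model("TTAGGGGGGAACGGTACCACGGCTGGGTTC", vector = toy_vector())
}
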