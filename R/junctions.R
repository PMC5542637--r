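#' Junction-calling parameters
#'
#' @param max_mismatches Substitutions allowed when locating the vector
#'   anchor at the read 5' end.
#' @param k_vec Length of post-terminus sequence that must match the
#'   vector (either orientation) for a read to be called a concatemer.
#' @param concat_mismatches Mismatch budget for the concatemer match.
#'   The default of 0 keeps the chance of a random genomic fragment
#'   colliding with the 240 nt toy vector near 3e-5 per junction (a
#'   1-mismatch budget at k_vec = 12 inflates it to about 1e-3);
#'   concatemer reads carrying a sequencing error in this short window
#'   fall through to mapping and end up unmapped, not as false IS.
#' @param min_fragment Minimum genomic fragment (nt) for an IS call.
#' @param linker_prefix Length of the linker prefix searched at the
#'   fragment 3' end.
#' @param linker_mismatches Mismatch budget for linker detection.
#' @return An object of class `junction_params`.
#' @export
junction_params <- function(max_mismatches = 2, k_vec = 12,
                            concat_mismatches = 0, min_fragment = 20,
                            linker_prefix = 10, linker_mismatches = 1) {
  structure(list(max_mismatches = as.integer(max_mismatches),
                 k_vec = as.integer(k_vec),
                 concat_mismatches = as.integer(concat_mismatches),
                 min_fragment = as.integer(min_fragment),
                 linker_prefix = as.integer(linker_prefix),
                 linker_mismatches = as.integer(linker_mismatches)),
            class = "junction_params")
}

#' Quality-filter reads
#'
#' Retains reads that are long enough and not N-rich; rejected reads are
#' tallied by reason (a read failing the length check is counted as
#' "short" regardless of its N content).
#'
#' @param reads Read table (`read_id`, `sequence`, ...) or `lam_sim`.
#' @param min_length Minimum read length.
#' @param max_fraction_N Maximum tolerated fraction of N bases.
#' @return A list with `reads` (retained rows) and `log` (data.frame
#'   `reason`, `count` with reasons `short` and `n_rich`).
#' @export
filter_quality <- function(reads, min_length = 36, max_fraction_N = 0.1) {
  if (inherits(reads, "lam_sim")) reads <- reads$reads
  lens <- nchar(reads$sequence)
  n_count <- vapply(gregexpr("N", reads$sequence, fixed = TRUE),
                    function(m) if (m[1] == -1L) 0L else length(m),
                    integer(1))
  short <- lens < min_length
  n_rich <- !short & (n_count / pmax(lens, 1L)) > max_fraction_N
  list(reads = reads[!(short | n_rich), , drop = FALSE],
       log = data.frame(reason = c("short", "n_rich"),
                        count = c(sum(short), sum(n_rich)),
                        stringsAsFactors = FALSE))
}

#' Locate the vector anchor at a read 5' end
#'
#' Scans the read for the leftmost occurrence of the anchor allowing up to
#' `max_mismatches` substitutions.
#'
#' @param read Read sequence (character or DNAString).
#' @param vector_anchor Anchor sequence (character).
#' @param max_mismatches Substitution budget.
#' @return `NULL` if absent, else a list with `start`, `end` (0-based
#'   half-open read coordinates) and `mismatches`.
#' @export
find_vector_anchor <- function(read, vector_anchor, max_mismatches = 2) {
  read <- as.character(read)
  if (nchar(vector_anchor) > nchar(read)) {
    stop("anchor is longer than the read")
  }
  m <- Biostrings::matchPattern(vector_anchor, Biostrings::DNAString(read),
                                max.mismatch = max_mismatches)
  if (length(m) == 0) return(NULL)
  s <- BiocGenerics::start(m)[1]
  nmm <- Biostrings::neditStartingAt(Biostrings::DNAString(vector_anchor),
                                     Biostrings::DNAString(read),
                                     starting.at = s)
  list(start = s - 1L, end = s - 1L + nchar(vector_anchor),
       mismatches = as.integer(nmm))
}

#' Classify reads into junction categories
#'
#' Implements the LAM-PCR junction logic: reads without the vector anchor
#' are `unclassified`; anchored reads whose post-terminus sequence matches
#' the vector in either orientation are `concatemer` (vector-vector
#' junctions); otherwise the linker is trimmed from the 3' end and the
#' remaining genomic fragment yields an `IS` call if it reaches
#' `min_fragment`, else `internal`.
#'
#' @param reads Read table (`read_id`, `sequence`) or `lam_sim`.
#' @param vector A [vector_construct()].
#' @param linker A [linker_model()].
#' @param params A [junction_params()].
#' @return A `data.frame` of junction calls: `read_id`, `category`,
#'   `fragment`, `anchor_end`, `linker_found`.
#' @export
classify_reads <- function(reads, vector, linker,
                           params = junction_params()) {
  if (inherits(reads, "lam_sim")) reads <- reads$reads
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id,
                    category = rep("unclassified", n),
                    fragment = rep("", n),
                    anchor_end = rep(NA_integer_, n),
                    linker_found = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)

  # classify unique sequences once, then propagate
  useq <- unique(reads$sequence)
  umap <- match(reads$sequence, useq)
  ucls <- classify_unique(useq, vector, linker, params)
  out$category <- ucls$category[umap]
  out$fragment <- ucls$fragment[umap]
  out$anchor_end <- ucls$anchor_end[umap]
  out$linker_found <- ucls$linker_found[umap]
  out
}

classify_unique <- function(useq, vector, linker, params) {
  nu <- length(useq)
  category <- rep("unclassified", nu)
  fragment <- rep("", nu)
  anchor_end <- rep(NA_integer_, nu)
  linker_found <- rep(FALSE, nu)

  anc <- anchor_seq(vector)
  vseg <- vector_segment(vector)
  trim_extra <- nchar(vseg) - nchar(anc)  # vector bases between anchor end and terminus
  uset <- Biostrings::DNAStringSet(useq)
  am <- Biostrings::vmatchPattern(anc, uset,
                                  max.mismatch = params$max_mismatches)
  starts <- Biostrings::startIndex(am)
  astart <- vapply(starts, function(s) if (is.null(s)) NA_integer_
                   else min(s), integer(1))
  anchored <- which(!is.na(astart))
  if (!length(anchored)) {
    return(list(category = category, fragment = fragment,
                anchor_end = anchor_end, linker_found = linker_found))
  }
  trim_at <- astart[anchored] - 1L + nchar(anc) + trim_extra  # 0-based end of vector part
  anchor_end[anchored] <- trim_at
  remaining <- substr(useq[anchored], trim_at + 1L, nchar(useq[anchored]))

  # concatemer: first k_vec nt after the terminus match the vector in
  # either orientation within the mismatch budget
  vboth <- Biostrings::DNAStringSet(c(vector$sequence,
                                      revcomp(vector$sequence)))
  kmer <- substr(remaining, 1L, params$k_vec)
  long_enough <- nchar(kmer) == params$k_vec
  is_concat <- rep(FALSE, length(remaining))
  ukmer <- unique(kmer[long_enough])
  if (length(ukmer)) {
    hit <- vapply(ukmer, function(km) {
      sum(Biostrings::vcountPattern(
        km, vboth, max.mismatch = params$concat_mismatches)) > 0
    }, logical(1))
    is_concat[long_enough] <- hit[match(kmer[long_enough], ukmer)]
  }
  category[anchored[is_concat]] <- "concatemer"

  # IS / internal: strip linker prefix, measure the genomic fragment
  rest_idx <- which(!is_concat)
  if (length(rest_idx)) {
    rem <- remaining[rest_idx]
    lp <- substr(linker$sequence, 1L, params$linker_prefix)
    lm <- Biostrings::vmatchPattern(
      lp, Biostrings::DNAStringSet(ifelse(nzchar(rem), rem, "A")),
      max.mismatch = params$linker_mismatches)
    lstarts <- Biostrings::startIndex(lm)
    for (j in seq_along(rest_idx)) {
      i <- anchored[rest_idx[j]]
      r <- rem[j]
      s <- lstarts[[j]]
      if (!is.null(s) && nzchar(r)) {
        cutpos <- min(s) - 1L
        frag <- substr(r, 1L, cutpos)
        linker_found[i] <- TRUE
      } else {
        frag <- r
      }
      if (nchar(frag) >= params$min_fragment) {
        category[i] <- "IS"
        fragment[i] <- frag
      } else {
        category[i] <- "internal"
      }
    }
  }
  list(category = category, fragment = fragment,
       anchor_end = anchor_end, linker_found = linker_found)
}

#' Classify a single read
#'
#' Single-read convenience wrapper around [classify_reads()].
#'
#' @param read Read sequence (character).
#' @param vector,linker,params See [classify_reads()].
#' @param read_id Identifier used in the returned row.
#' @return A one-row junction-call `data.frame`.
#' @export
classify_read <- function(read, vector, linker,
                          params = junction_params(), read_id = "read1") {
  classify_reads(data.frame(read_id = read_id, sequence = as.character(read),
                            stringsAsFactors = FALSE),
                 vector, linker, params)
}

#' Write IS fragments as FASTA
#'
#' Emits the genomic fragments of IS calls for mapping.
#'
#' @param calls Junction-call table from [classify_reads()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_fragments_fasta <- function(calls, path) {
  is_calls <- calls[calls$category == "IS", , drop = FALSE]
  x <- Biostrings::DNAStringSet(is_calls$fragment)
  names(x) <- is_calls$read_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
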