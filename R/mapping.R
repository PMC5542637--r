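# Desk-scale seed-and-extend read mapping: an exact k-mer index over the
# reference plus ungapped extension, standing in for a full genome aligner
# at toy-genome scales.

base_code <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A")] <- 0L
  tab[utf8ToInt("C")] <- 1L
  tab[utf8ToInt("G")] <- 2L
  tab[utf8ToInt("T")] <- 3L
  tab
})

# Numeric 2-bit encodings of all k-mers of a sequence; NA where the
# window contains a non-ACGT base. k <= 26 keeps codes exact in doubles.
encode_kmers <- function(seq_chr, k) {
  v <- base_code[utf8ToInt(seq_chr)]
  n <- length(v)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  x <- numeric(m)
  for (j in 0:(k - 1L)) {
    x <- x + v[(1L + j):(m + j)] * 4^(k - 1L - j)
  }
  x
}

encode_one <- function(kmer) {
  v <- base_code[utf8ToInt(kmer)]
  if (anyNA(v)) return(NA_real_)
  sum(v * 4^(rev(seq_along(v)) - 1L))
}

#' Build an exact k-mer index over a genome
#'
#' Tabulates every k-mer position on the reference plus strand;
#' minus-strand occurrences are resolved at query time through the
#' reverse complement. Windows containing N are skipped.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param k Seed length; `11 <= k <= 26` and no longer than the shortest
#'   chromosome.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 16) {
  k <- as.integer(k)
  if (k < 11) stop("k must be >= 11")
  if (k > 26) stop("k must be <= 26 (codes must stay exact in doubles)")
  lens <- Biostrings::width(genome)
  if (k > min(lens)) {
    stop("k (", k, ") exceeds the shortest chromosome length (",
         min(lens), ")")
  }
  seqs <- as.character(genome)
  codes <- vector("list", length(seqs))
  chrom <- vector("list", length(seqs))
  pos <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    x <- encode_kmers(seqs[i], k)
    keep <- which(!is.na(x))
    codes[[i]] <- x[keep]
    chrom[[i]] <- rep.int(i, length(keep))
    pos[[i]] <- keep - 1L
  }
  code <- unlist(codes, use.names = FALSE)
  chrom <- unlist(chrom, use.names = FALSE)
  pos <- unlist(pos, use.names = FALSE)
  o <- order(code)
  structure(list(k = k, code = code[o], chrom = chrom[o], pos = pos[o],
                 seqnames = names(genome), seqlens = lens, seqs = seqs),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d over %d chromosome(s), %d indexed k-mers\n",
              x$k, length(x$seqnames), length(x$code)))
  invisible(x)
}

# Rows of the sorted index matching a numeric k-mer code.
lookup_code <- function(index, code) {
  if (is.na(code)) return(integer(0))
  rng <- findInterval(c(code - 0.5, code + 0.5), index$code)
  if (rng[2] <= rng[1]) return(integer(0))
  (rng[1] + 1L):rng[2]
}

#' Query a k-mer index
#'
#' Reports all occurrences of a k-mer on both strands: plus-strand hits
#' directly, minus-strand hits as the plus-strand position of the
#' reverse-complement occurrence.
#'
#' @param index A [build_index()] object.
#' @param kmer Query k-mer (length `k`).
#' @return A `data.frame` with `chrom`, `pos` (0-based), `strand`.
#' @export
query_index <- function(index, kmer) {
  if (nchar(kmer) != index$k) stop("query length must equal k")
  fwd <- lookup_code(index, encode_one(kmer))
  rc <- revcomp(kmer)
  rev <- if (rc == kmer) integer(0) else lookup_code(index, encode_one(rc))
  data.frame(
    chrom = index$seqnames[c(index$chrom[fwd], index$chrom[rev])],
    pos = c(index$pos[fwd], index$pos[rev]),
    strand = rep(c("+", "-"), c(length(fwd),
                                if (rc == kmer) 0L else length(rev))),
    stringsAsFactors = FALSE
  )
}

#' Mapping parameters
#'
#' @param min_identity Minimum alignment identity fraction.
#' @param min_aligned Minimum aligned length (nt).
#' @param score_margin Score difference below which co-optimal hits are
#'   treated as ties when resolving uniqueness.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(min_identity = 0.95, min_aligned = 20,
                           score_margin = 5) {
  structure(list(min_identity = min_identity,
                 min_aligned = as.integer(min_aligned),
                 score_margin = score_margin),
            class = "mapping_params")
}

#' Map a genomic fragment by seed-and-extend
#'
#' Seeds the fragment (both orientations) with tiled exact k-mers, then
#' extends each candidate locus ungapped over the full fragment length.
#' Hits reaching `min_identity` over at least `min_aligned` bases are
#' scored by identity times aligned length and sorted by score (ties by
#' chromosome then junction position). The reported `pos` is the junction
#' coordinate: the reference position of the fragment base adjacent to
#' the vector terminus (the fragment start for plus-strand placements,
#' the fragment end for minus-strand placements).
#'
#' @param fragment Genomic fragment (character).
#' @param index A [build_index()] object.
#' @param params A [mapping_params()].
#' @return A `data.frame` of hits: `chrom`, `start` (0-based alignment
#'   start), `pos` (junction coordinate), `strand`, `identity`,
#'   `aligned`, `score`.
#' @export
map_fragment <- function(fragment, index, params = mapping_params()) {
  k <- index$k
  len <- nchar(fragment)
  empty <- data.frame(chrom = character(), start = integer(),
                      pos = integer(), strand = character(),
                      identity = numeric(), aligned = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (len < k || len < params$min_aligned) return(empty)
  offsets <- unique(c(seq(0L, len - k, by = k), len - k))
  rows <- list()
  for (orient in c("+", "-")) {
    q <- if (orient == "+") fragment else revcomp(fragment)
    cand_chrom <- integer(0); cand_start <- integer(0)
    for (o in offsets) {
      code <- encode_one(substr(q, o + 1L, o + k))
      hit <- lookup_code(index, code)
      if (!length(hit)) next
      cand_chrom <- c(cand_chrom, index$chrom[hit])
      cand_start <- c(cand_start, index$pos[hit] - o)
    }
    if (!length(cand_start)) next
    keep <- !duplicated(cand_chrom * 2^33 + cand_start)
    cand_chrom <- cand_chrom[keep]; cand_start <- cand_start[keep]
    inb <- cand_start >= 0L & cand_start + len <= index$seqlens[cand_chrom]
    cand_chrom <- cand_chrom[inb]; cand_start <- cand_start[inb]
    for (j in seq_along(cand_start)) {
      ref <- substr(index$seqs[cand_chrom[j]], cand_start[j] + 1L,
                    cand_start[j] + len)
      mm <- count_mismatches(q, ref)
      identity <- (len - mm) / len
      if (identity < params$min_identity) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = index$seqnames[cand_chrom[j]],
        start = cand_start[j],
        pos = if (orient == "+") cand_start[j] else cand_start[j] + len - 1L,
        strand = orient,
        identity = identity,
        aligned = len,
        score = identity * len,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  hits[order(-hits$score, hits$chrom, hits$pos), , drop = FALSE]
}

#' Resolve a hit list into a mapped junction
#'
#' No hits give status `unmapped`; a single hit, or a best hit exceeding
#' the runner-up by at least `score_margin`, gives `unique`; otherwise
#' `multi` with `n_best` the number of hits within the margin of the best
#' score. The junction coordinate of the best hit is reported.
#'
#' @param hits Hit table from [map_fragment()] (sorted by score).
#' @param score_margin Tie margin on the score scale.
#' @param read_id Identifier carried into the result row.
#' @return A one-row `data.frame`: `read_id`, `chrom`, `pos`, `strand`,
#'   `score` (identity of the best hit), `n_best`, `status`.
#' @export
resolve_uniqueness <- function(hits, score_margin = 5, read_id = NA_character_) {
  if (nrow(hits) == 0) {
    return(data.frame(read_id = read_id, chrom = NA_character_,
                      pos = NA_integer_, strand = NA_character_,
                      score = NA_real_, n_best = 0L, status = "unmapped",
                      stringsAsFactors = FALSE))
  }
  unique_hit <- nrow(hits) == 1L ||
    hits$score[1] - hits$score[2] >= score_margin
  n_best <- sum(hits$score > hits$score[1] - score_margin)
  status <- if (unique_hit) "unique" else "multi"
  data.frame(read_id = read_id, chrom = hits$chrom[1], pos = hits$pos[1],
             strand = hits$strand[1], score = hits$identity[1],
             n_best = if (status == "unique") 1L else n_best,
             status = status, stringsAsFactors = FALSE)
}

#' Map all IS fragments of a junction-call table
#'
#' Deduplicates fragments, maps each unique fragment with
#' [map_fragment()], resolves uniqueness, and joins results back to
#' reads.
#'
#' @param calls Junction-call table from [classify_reads()].
#' @param index A [build_index()] object.
#' @param params A [mapping_params()].
#' @return A `data.frame` of mapped junctions, one row per IS read:
#'   `read_id`, `fragment`, `chrom`, `pos`, `strand`, `score`, `n_best`,
#'   `status`.
#' @export
map_fragments <- function(calls, index, params = mapping_params()) {
  is_calls <- calls[calls$category == "IS", , drop = FALSE]
  if (nrow(is_calls) == 0) {
    return(data.frame(read_id = character(), fragment = character(),
                      chrom = character(), pos = integer(),
                      strand = character(), score = numeric(),
                      n_best = integer(), status = character(),
                      stringsAsFactors = FALSE))
  }
  ufrag <- unique(is_calls$fragment)
  res <- lapply(ufrag, function(f) {
    resolve_uniqueness(map_fragment(f, index, params),
                       score_margin = params$score_margin)
  })
  res <- do.call(rbind, res)
  idx <- match(is_calls$fragment, ufrag)
  out <- res[idx, , drop = FALSE]
  out$read_id <- is_calls$read_id
  out$fragment <- is_calls$fragment
  rownames(out) <- NULL
  out[, c("read_id", "fragment", "chrom", "pos", "strand", "score",
          "n_best", "status")]
}

#' Export mapped junction positions as BED
#'
#' @param mapped Mapped-junction table from [map_fragments()].
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_junctions_bed <- function(mapped, path) {
  u <- mapped[mapped$status != "unmapped", , drop = FALSE]
  bed <- data.frame(u$chrom, u$pos, u$pos + 1L, u$read_id, 0L, u$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
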