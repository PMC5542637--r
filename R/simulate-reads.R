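#' Simulation configuration
#'
#' Bundles the tunable parameters of the LAM-PCR read simulator with
#' validation. Defaults describe a desk-scale study: 200 integration
#' events sequenced to a depth of 20,000 single-end 150 nt reads with a
#' low Illumina-like substitution error rate and a strongly skewed
#' (log-series) clone-size distribution.
#'
#' @param n_events Number of integration events to plant.
#' @param hotspot Optional list `(chrom, start, end, fraction)`: the stated
#'   fraction of events falls uniformly inside the window, the rest is
#'   genome-wide uniform.
#' @param abundance_model `"logseries"` (parameter `theta`) or `"uniform"`
#'   (all clones weight 1).
#' @param theta Log-series parameter in (0, 1); larger values give more
#'   skewed clonality.
#' @param error_rate Per-base substitution probability in `[0, 0.2]`.
#' @param read_length Read length in nt (>= 36).
#' @param max_flank Genomic flank searched for a restriction site (nt).
#' @param min_fragment Minimum genomic fragment considered mappable (nt).
#' @param depth Total number of reads to emit.
#' @param seed Integer seed for the simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_events = 200, hotspot = NULL,
                       abundance_model = c("logseries", "uniform"),
                       theta = 0.95, error_rate = 0.002, read_length = 150,
                       max_flank = 1000, min_fragment = 20,
                       depth = 20000, seed = NULL) {
  abundance_model <- match.arg(abundance_model)
  if (!is.null(hotspot)) {
    stopifnot(is.list(hotspot),
              all(c("chrom", "start", "end", "fraction") %in% names(hotspot)))
    if (hotspot$fraction < 0 || hotspot$fraction > 1) {
      stop("hotspot fraction must be in [0,1]")
    }
  }
  if (error_rate < 0 || error_rate > 0.2) {
    stop("error_rate must be in [0, 0.2]")
  }
  if (read_length < 36) stop("read_length must be >= 36")
  if (theta <= 0 || theta >= 1) stop("theta must be in (0,1)")
  structure(list(n_events = as.integer(n_events), hotspot = hotspot,
                 abundance_model = abundance_model, theta = theta,
                 error_rate = error_rate,
                 read_length = as.integer(read_length),
                 max_flank = as.integer(max_flank),
                 min_fragment = as.integer(min_fragment),
                 depth = as.integer(depth), seed = seed),
            class = "sim_config")
}

# Log-series clone sizes: P(k) proportional to theta^k / k.
r_logseries <- function(n, theta, kmax = 10000L) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = theta^k / k)
}

#' Plant integration events in a genome
#'
#' Samples event positions uniformly over the genome (chromosome chosen
#' proportional to eligible length), except for an optional hotspot
#' fraction placed uniformly within the hotspot window. A margin of
#' `max_flank` is kept from chromosome ends so the downstream flank is
#' always extractable. Orientation is a fair coin; clone abundances follow
#' the configured model.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named lengths vector).
#' @param config A [sim_config()].
#' @return A `data.frame` of events: `event_id`, `chrom`, `pos` (0-based
#'   first genomic base joined to the vector terminus), `orient`,
#'   `abundance`.
#' @export
plant_integrations <- function(genome, config) {
  lens <- chrom_lengths(genome)
  m <- config$max_flank
  elig <- pmax(lens - 2L * m, 0L)
  if (all(elig == 0)) stop("no chromosome long enough for max_flank margin")
  n <- config$n_events
  if (n == 0) {
    return(data.frame(event_id = character(), chrom = character(),
                      pos = integer(), orient = character(),
                      abundance = numeric(), stringsAsFactors = FALSE))
  }
  hs <- config$hotspot
  if (!is.null(hs)) {
    if (!hs$chrom %in% names(lens) || hs$start < 0 ||
        hs$end > lens[[hs$chrom]] || hs$start >= hs$end) {
      stop("hotspot window outside genome")
    }
  }
  with_seed(config$seed, {
    in_hs <- if (is.null(hs)) rep(FALSE, n) else stats::runif(n) < hs$fraction
    chrom <- character(n); pos <- integer(n)
    n_out <- sum(!in_hs)
    if (n_out > 0) {
      ci <- sample.int(length(lens), n_out, replace = TRUE, prob = elig)
      chrom[!in_hs] <- names(lens)[ci]
      pos[!in_hs] <- m + as.integer(floor(stats::runif(n_out) * elig[ci]))
    }
    n_in <- sum(in_hs)
    if (n_in > 0) {
      lo <- max(hs$start, m)
      hi <- min(hs$end, lens[[hs$chrom]] - m)
      if (lo >= hi) stop("hotspot window outside the plantable region")
      chrom[in_hs] <- hs$chrom
      pos[in_hs] <- as.integer(floor(stats::runif(n_in, lo, hi)))
    }
    abundance <- switch(config$abundance_model,
                        uniform = rep(1, n),
                        logseries = as.numeric(r_logseries(n, config$theta)))
    data.frame(event_id = sprintf("ev%04d", seq_len(n)),
               chrom = chrom, pos = pos,
               orient = sample(c("+", "-"), n, replace = TRUE),
               abundance = abundance, stringsAsFactors = FALSE)
  })
}

#' Concatemer junction set
#'
#' Describes the episomal vector-vector junction species co-amplified by
#' LAM-PCR, with relative abundances.
#'
#' @param kinds Character vector drawn from `"head_to_tail"`,
#'   `"head_to_head"`, `"tail_to_tail"`.
#' @param abundances Positive weights, one per kind.
#' @return A `data.frame` with columns `kind`, `abundance`.
#' @export
concatemer_junctions <- function(kinds = c("head_to_tail", "head_to_head",
                                           "tail_to_tail"),
                                 abundances = c(0.6, 0.2, 0.2)) {
  allowed <- c("head_to_tail", "head_to_head", "tail_to_tail")
  if (!all(kinds %in% allowed)) {
    stop("concatemer kind must be one of: ", paste(allowed, collapse = ", "))
  }
  if (length(abundances) != length(kinds) || any(abundances <= 0)) {
    stop("abundances must be positive, one per kind")
  }
  data.frame(kind = kinds, abundance = abundances, stringsAsFactors = FALSE)
}

#' Truncate a genomic flank at the nearest restriction site
#'
#' Scans the flank left to right for the nearest recognition site of any
#' provided enzyme starting within `max_flank` bases and returns the
#' retained fragment `flank[0 : site_start + cut_offset)` (0-based
#' half-open), i.e. the sequence retained on the vector side of the cut.
#' Returns `NA` when no site is found: such a junction yields no
#' ligatable amplicon.
#'
#' @param flank Genomic flank immediately downstream of the vector
#'   terminus, as a character string.
#' @param enzymes A [restriction_enzyme()] or list of them.
#' @param max_flank Maximum site-start offset searched.
#' @return The retained fragment, or `NA_character_` if no site is found.
#' @export
#' @examples
#' truncate_at_enzyme("ACGGTTAACC", lam_enzymes()$MseI)  # "ACGGT"
truncate_at_enzyme <- function(flank, enzymes, max_flank = 1000L) {
  if (!nzchar(flank)) stop("flank must be non-empty")
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  best_start <- Inf
  best_cut <- NA_integer_
  for (enz in enzymes) {
    hits <- gregexpr(enz$recognition, flank, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    starts0 <- hits - 1L
    starts0 <- starts0[starts0 < max_flank]
    if (!length(starts0)) next
    s <- starts0[1]
    if (s < best_start) {
      best_start <- s
      best_cut <- s + enz$cut_offset
    }
  }
  if (!is.finite(best_start)) return(NA_character_)
  substr(flank, 1L, best_cut)
}

# Extract the genomic flank downstream of a junction, on the amplicon
# strand. orient "+": plus-strand bases starting at pos; orient "-":
# reverse complement of the plus-strand bases ending at pos.
extract_flank <- function(genome, chrom, pos, orient, width) {
  len <- Biostrings::width(genome[chrom])
  if (orient == "+") {
    hi <- min(pos + width, len)
    as.character(Biostrings::subseq(genome[[chrom]], pos + 1L, hi))
  } else {
    lo <- max(pos - width + 1L, 0L)
    revcomp(as.character(Biostrings::subseq(genome[[chrom]], lo + 1L,
                                            pos + 1L)))
  }
}

# Concatemer continuation entering the downstream vector copy.
concatemer_continuation <- function(vc, kind, width) {
  vseq <- vc$sequence
  cont <- switch(kind,
    head_to_tail = vseq,
    head_to_head = revcomp(vseq),
    tail_to_tail = revcomp(substr(vseq, 1L, min(nchar(vseq), width))),
    stop("unknown concatemer kind: ", kind))
  substr(cont, 1L, width)
}

# Apply i.i.d. substitution errors to a character vector of reads.
mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, error_rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

#' Simulate LAM-PCR reads from planted events and concatemers
#'
#' Builds the amplicon for every event (vector segment from the primer
#' anchor to the terminus, genomic flank truncated at the first MseI/MluCI
#' site, then linker) and for every concatemer junction (vector segment
#' followed by the downstream vector copy per junction kind). Events with
#' no restriction site within `max_flank` yield no ligatable product and
#' emit no reads. Reads are allocated to amplicons multinomially by clone
#' abundance to the configured depth; each read is the first
#' `read_length` bases of its amplicon with i.i.d. substitution errors.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param events Event table from [plant_integrations()].
#' @param vector A [vector_construct()].
#' @param linker A [linker_model()].
#' @param enzymes List of [restriction_enzyme()]s (default [lam_enzymes()]).
#' @param config A [sim_config()].
#' @param concatemers Optional [concatemer_junctions()] table. Its
#'   abundances compete with event abundances on the same scale.
#' @return An object of class `lam_sim`: a list with `reads` (data.frame
#'   `read_id`, `sequence`, `quality`), `truth` (per-read ground truth:
#'   `read_id`, `source_type`, `source_id`, `chrom`, `pos`, `orient`,
#'   `recoverable`), and `events` (the event table with `recoverable` and
#'   `fragment_length` columns).
#' @export
lam_pcr_reads <- function(genome, events, vector, linker,
                          enzymes = lam_enzymes(), config = sim_config(),
                          concatemers = NULL) {
  vseg <- vector_segment(vector)
  if (nchar(vseg) >= config$read_length) {
    stop("vector anchor/segment (", nchar(vseg),
         " nt) must be shorter than read_length (", config$read_length, ")")
  }
  pad <- max(vapply(enzymes, function(e) nchar(e$recognition), integer(1)))
  amp <- character(0); src_type <- character(0); src_id <- character(0)
  src_chrom <- character(0); src_pos <- integer(0); src_orient <- character(0)
  src_recoverable <- logical(0); weight <- numeric(0)

  events$recoverable <- logical(nrow(events))
  events$fragment_length <- NA_integer_
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      fl <- extract_flank(genome, events$chrom[i], events$pos[i],
                          events$orient[i], config$max_flank + pad)
      frag <- truncate_at_enzyme(fl, enzymes, config$max_flank)
      if (is.na(frag)) next  # no site: no ligatable amplicon, no reads
      events$fragment_length[i] <- nchar(frag)
      events$recoverable[i] <- nchar(frag) >= config$min_fragment
      amp <- c(amp, paste0(vseg, frag, linker$sequence))
      src_type <- c(src_type, "IS")
      src_id <- c(src_id, events$event_id[i])
      src_chrom <- c(src_chrom, events$chrom[i])
      src_pos <- c(src_pos, events$pos[i])
      src_orient <- c(src_orient, events$orient[i])
      src_recoverable <- c(src_recoverable, events$recoverable[i])
      weight <- c(weight, events$abundance[i])
    }
  }
  if (!is.null(concatemers) && nrow(concatemers)) {
    for (i in seq_len(nrow(concatemers))) {
      cont <- concatemer_continuation(vector, concatemers$kind[i],
                                      config$read_length)
      amp <- c(amp, paste0(vseg, cont))
      src_type <- c(src_type, "concatemer")
      src_id <- c(src_id, concatemers$kind[i])
      src_chrom <- c(src_chrom, NA_character_)
      src_pos <- c(src_pos, NA_integer_)
      src_orient <- c(src_orient, NA_character_)
      src_recoverable <- c(src_recoverable, NA)
      weight <- c(weight, concatemers$abundance[i])
    }
  }
  if (!length(amp)) stop("no amplifiable junctions: every event lacks a ",
                         "restriction site within max_flank")
  with_seed(config$seed, {
    counts <- as.vector(stats::rmultinom(1, config$depth, weight))
    src <- rep.int(seq_along(amp), counts)
    seqs <- substr(amp[src], 1L, config$read_length)
    seqs <- mutate_reads(seqs, config$error_rate)
    ids <- sprintf("read%06d", seq_along(seqs))
    reads <- data.frame(read_id = ids, sequence = seqs,
                        quality = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids, source_type = src_type[src],
                        source_id = src_id[src], chrom = src_chrom[src],
                        pos = src_pos[src], orient = src_orient[src],
                        recoverable = src_recoverable[src],
                        stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth, events = events),
              class = "lam_sim")
  })
}

#' @export
print.lam_sim <- function(x, ...) {
  cat(sprintf(
    "<lam_sim> %d reads (%d IS, %d concatemer); %d/%d events recoverable\n",
    nrow(x$reads), sum(x$truth$source_type == "IS"),
    sum(x$truth$source_type == "concatemer"),
    sum(x$events$recoverable), nrow(x$events)))
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' @param reads Read table (`read_id`, `sequence`, `quality`) or a
#'   `lam_sim` object.
#' @param path Output FASTQ path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "lam_sim")) reads <- reads$reads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (optionally gzipped).
#' @return A `data.frame` with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
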