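# Collapsing mapped junctions into integration sites and quantifying
# clone sizes ("relative sequence counts" over uniquely mapped IS reads).

# Single-linkage clustering of sorted positions: a new cluster starts
# where the gap to the previous member exceeds window_bp.
cluster_positions <- function(chrom, strand, pos, window_bp) {
  o <- order(chrom, strand, pos)
  chrom <- chrom[o]; strand <- strand[o]; pos <- pos[o]
  newc <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
              strand[-1] != strand[-length(strand)] |
              diff(pos) > window_bp)
  list(order = o, cluster = cumsum(newc))
}

#' Collapse unique mapped junctions into integration sites
#'
#' Junctions on the same chromosome and strand within `window_bp` of each
#' other merge into one site (single linkage), absorbing alignment
#' jitter. The site position is the modal member position (ties to the
#' smallest) and the read count is the number of member junctions. Only
#' `unique`-status junctions are used.
#'
#' @param mapped Mapped-junction table from [map_fragments()].
#' @param window_bp Merge window in bp.
#' @return A `data.frame` of sites: `chrom`, `pos`, `strand`,
#'   `read_count`, sorted by chromosome and position.
#' @export
collapse_sites <- function(mapped, window_bp = 3) {
  u <- mapped[mapped$status == "unique", , drop = FALSE]
  if (nrow(u) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), read_count = integer(),
                      stringsAsFactors = FALSE))
  }
  cl <- cluster_positions(u$chrom, u$strand, u$pos, window_bp)
  u <- u[cl$order, , drop = FALSE]
  sites <- do.call(rbind, lapply(split(seq_len(nrow(u)), cl$cluster),
                                 function(ix) {
    p <- u$pos[ix]
    tab <- table(p)
    mode_pos <- min(as.integer(names(tab)[tab == max(tab)]))
    data.frame(chrom = u$chrom[ix[1]], pos = mode_pos,
               strand = u$strand[ix[1]], read_count = length(ix),
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
}

#' Quantify clonal abundance of integration sites
#'
#' Adds `relative_count`, the read count of each site relative to all
#' uniquely mapped IS reads -- the semiquantitative clone-size estimate.
#'
#' @param sites Site table from [collapse_sites()].
#' @return The site table with a `relative_count` column summing to 1.
#' @export
quantify_sites <- function(sites) {
  if (nrow(sites) == 0) stop("no sites to quantify")
  sites$relative_count <- sites$read_count / sum(sites$read_count)
  sites
}

#' Top clonal integration sites
#'
#' The n most prominent sites ranked by read count (ties broken by
#' chromosome then position).
#'
#' @param sites Site table (quantified or not).
#' @param n Number of sites to return.
#' @return The ranked subset.
#' @export
top_sites <- function(sites, n = 10) {
  if (nrow(sites) == 0) stop("no sites")
  o <- order(-sites$read_count, sites$chrom, sites$pos)
  utils::head(sites[o, , drop = FALSE], n)
}

#' Annotate sites with the nearest gene
#'
#' Adds `nearest_gene`, `distance_to_gene` (signed bp: 0 inside the gene,
#' negative upstream of the gene start, positive downstream of the gene
#' end, on reference coordinates) and `in_gene`.
#'
#' @param sites Site table.
#' @param genes Gene table.
#' @return The annotated site table.
#' @export
annotate_sites <- function(sites, genes) {
  sites$nearest_gene <- NA_character_
  sites$distance_to_gene <- NA_integer_
  sites$in_gene <- FALSE
  if (nrow(sites) == 0 || nrow(genes) == 0) return(sites)
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  near <- GenomicRanges::nearest(gr_sites, gr_genes, ignore.strand = TRUE,
                                 select = "arbitrary")
  found <- which(!is.na(near))
  for (i in found) {
    g <- near[i]
    sites$nearest_gene[i] <- genes$name[g]
    p <- sites$pos[i]
    if (p >= genes$start[g] && p < genes$end[g]) {
      sites$distance_to_gene[i] <- 0L
      sites$in_gene[i] <- TRUE
    } else if (p < genes$start[g]) {
      sites$distance_to_gene[i] <- p - genes$start[g]
    } else {
      sites$distance_to_gene[i] <- p - (genes$end[g] - 1L)
    }
  }
  sites
}

#' Summarise a sample's junction composition
#'
#' Produces the per-sample accounting used in serial-biopsy tables: read
#' counts per junction category, site counts (unique and multi), and the
#' IS / concatemer percentages of vector-positive reads.
#'
#' @param calls Junction-call table from [classify_reads()].
#' @param mapped Mapped-junction table from [map_fragments()] (may be
#'   `NULL` when no IS reads exist).
#' @param sites Site table from [collapse_sites()].
#' @param sample_id,time_point Sample labels.
#' @param dna_mass_ug Optional input DNA mass; when given, `is_per_ug` is
#'   reported as total sites per microgram.
#' @param window_bp Merge window used to count multi-mapped site clusters.
#' @return A one-row `data.frame` (`sample_summary`).
#' @export
summarize_sample <- function(calls, mapped = NULL, sites = NULL,
                             sample_id = "sample", time_point = NA,
                             dna_mass_ug = NULL, window_bp = 3) {
  total_is <- sum(calls$category == "IS")
  conc <- sum(calls$category == "concatemer")
  internal <- sum(calls$category == "internal")
  unclass <- sum(calls$category == "unclassified")
  vector_positive <- total_is + conc
  if (vector_positive > 0) {
    pct_is <- 100 * total_is / vector_positive
    pct_conc <- 100 * conc / vector_positive
  } else {
    pct_is <- NA_real_
    pct_conc <- NA_real_
  }
  n_unique <- if (is.null(sites)) 0L else nrow(sites)
  n_multi <- 0L
  if (!is.null(mapped)) {
    mm <- mapped[mapped$status == "multi" & !is.na(mapped$pos), ,
                 drop = FALSE]
    if (nrow(mm)) {
      cl <- cluster_positions(mm$chrom, mm$strand, mm$pos, window_bp)
      n_multi <- max(cl$cluster)
    }
  }
  data.frame(sample_id = sample_id, time_point = time_point,
             total_is_reads = total_is, concatemer_reads = conc,
             internal_reads = internal, unclassified_reads = unclass,
             n_sites_total = n_unique + n_multi,
             n_sites_unique = n_unique, n_sites_multi = n_multi,
             pct_is = pct_is, pct_concatemer = pct_conc,
             is_per_ug = if (is.null(dna_mass_ug)) NA_real_ else
               (n_unique + n_multi) / dna_mass_ug,
             stringsAsFactors = FALSE)
}

#' Track integration-site persistence across serial samples
#'
#' Pools site tables from two or more time points and reports, for every
#' distinct site (same chromosome and strand, positions within
#' `window_bp`), the time points where it appears. Sites seen at two or
#' more time points are flagged persistent.
#'
#' @param site_list Named list of site tables, one per time point (names
#'   are the time-point labels).
#' @param window_bp Merge window in bp.
#' @return A `data.frame` with `chrom`, `pos`, `strand`, `n_timepoints`,
#'   `timepoints` (comma-separated), `persistent`.
#' @export
serial_persistence <- function(site_list, window_bp = 3) {
  if (length(site_list) < 2) stop(">=2 time points required")
  tps <- names(site_list)
  if (is.null(tps)) tps <- as.character(seq_along(site_list))
  pooled <- do.call(rbind, lapply(seq_along(site_list), function(i) {
    s <- site_list[[i]]
    if (nrow(s) == 0) return(NULL)
    data.frame(chrom = s$chrom, pos = s$pos, strand = s$strand,
               tp = tps[i], stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_timepoints = integer(),
                      timepoints = character(), persistent = logical(),
                      stringsAsFactors = FALSE))
  }
  cl <- cluster_positions(pooled$chrom, pooled$strand, pooled$pos, window_bp)
  pooled <- pooled[cl$order, , drop = FALSE]
  out <- do.call(rbind, lapply(split(seq_len(nrow(pooled)), cl$cluster),
                               function(ix) {
    tp <- sort(unique(pooled$tp[ix]))
    data.frame(chrom = pooled$chrom[ix[1]], pos = min(pooled$pos[ix]),
               strand = pooled$strand[ix[1]],
               n_timepoints = length(tp),
               timepoints = paste(tp, collapse = ","),
               persistent = length(tp) >= 2L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Export integration sites as BED
#'
#' @param sites Site table.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$pos, sites$pos + 1L,
                    sprintf("site%04d", seq_len(nrow(sites))),
                    sites$read_count, sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
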