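# End-to-end orchestration: staged pipeline with a validated plain-text
# configuration, per-stage manifests, and report tables.

pipeline_defaults <- function() {
  list(
    outdir = "lamis_out",
    seed = 42L,
    sample_id = "sample1",
    time_point = "t1",
    # toy genome
    n_chrom = 2L, chrom_lengths = c(1e6, 1e6), gc_content = 0.41,
    n_genes = 60L, cancer_fraction = 0.3,
    gene_length_min = 5000L, gene_length_max = 15000L,
    # simulation
    n_events = 200L, depth = 20000L, read_length = 150L,
    error_rate = 0.002, abundance_model = "logseries", theta = 0.95,
    max_flank = 1000L, min_fragment = 20L,
    concatemer_abundance = 0.1,
    hotspot_chrom = NA_character_, hotspot_start = NA_integer_,
    hotspot_end = NA_integer_, hotspot_fraction = 0,
    # junction calling
    min_read_length = 36L, max_fraction_N = 0.1,
    max_mismatches = 2L, k_vec = 12L,
    # mapping
    k = 16L, min_identity = 0.95, min_aligned = 20L, score_margin = 5,
    # clonality
    window_bp = 3L, top_n = 10L,
    # null statistics
    null_size = 8628L, null_mode = "uniform", alpha = 0.05,
    correction = "BH"
  )
}

#' Pipeline configuration
#'
#' Builds a validated configuration from the defaults, overridden by
#' `...` or by a YAML file. Unknown keys are errors, not warnings.
#'
#' @param ... Named overrides of the default parameters.
#' @param file Optional YAML file of overrides.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  overrides <- list(...)
  if (!is.null(file)) {
    overrides <- utils::modifyList(yaml::read_yaml(file), overrides)
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, overrides)
  if (cfg$hotspot_fraction < 0 || cfg$hotspot_fraction > 1) {
    stop("hotspot_fraction must be in [0,1]")
  }
  structure(cfg, class = "pipeline_config")
}

stage_artifacts <- list(
  simulate = c("genome.fasta", "genes.bed", "cancer_genes.txt",
               "reads.fastq", "truth.tsv", "events.tsv"),
  call = c("junctions.tsv", "is_fragments.fasta", "filter_log.tsv"),
  map = "mapped.tsv",
  quantify = c("sites.tsv", "sites.bed", "top_sites.tsv",
               "sample_summary.tsv"),
  test = c("null.tsv", "hotspots.tsv", "gene_context.tsv",
           "cancer_enrichment.tsv"),
  report = "report.txt"
)

stage_deps <- list(simulate = character(0), call = "simulate",
                   map = "call", quantify = "map", test = "quantify",
                   report = "test")

check_stage_inputs <- function(cfg, stage) {
  for (dep in stage_deps[[stage]]) {
    missing <- !file.exists(file.path(cfg$outdir, stage_artifacts[[dep]]))
    if (any(missing)) {
      stop("stage '", stage, "' needs outputs of stage '", dep,
           "'; run ", dep, " first (missing: ",
           paste(stage_artifacts[[dep]][missing], collapse = ", "), ")")
    }
  }
}

write_manifest <- function(cfg, stage, outputs) {
  paths <- file.path(cfg$outdir, outputs)
  params <- unclass(cfg)
  params$outdir <- NULL  # location is not content
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("lamis")),
    seed = cfg$seed,
    parameters = params,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(paths)), outputs))
  )
  jsonlite::write_json(manifest,
                       file.path(cfg$outdir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the integration-site pipeline
#'
#' Chains the module stages `simulate -> call -> map -> quantify -> test
#' -> report`, writing each stage's artifacts plus a manifest (parameter
#' values, seed, package version, output checksums) into the configured
#' output directory. Each stage is deterministic under the configured
#' seed: re-running with unchanged inputs reproduces artifacts
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param stage One of `"simulate"`, `"call"`, `"map"`, `"quantify"`,
#'   `"test"`, `"report"`, or `"all"` to chain every stage.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), stage = "all") {
  stages <- c("simulate", "call", "map", "quantify", "test", "report")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  for (st in todo) {
    check_stage_inputs(config, st)
    t0 <- proc.time()[["elapsed"]]
    written[[st]] <- switch(st,
      simulate = stage_simulate(config),
      call = stage_call(config),
      map = stage_map(config),
      quantify = stage_quantify(config),
      test = stage_test(config),
      report = stage_report(config))
    write_manifest(config, st, stage_artifacts[[st]])
    message(sprintf("[lamis] stage %-8s done in %.1fs", st,
                    proc.time()[["elapsed"]] - t0))
  }
  invisible(written)
}

out_path <- function(cfg, name) file.path(cfg$outdir, name)

stage_simulate <- function(cfg) {
  toy <- make_toy_genome(
    n_chrom = cfg$n_chrom, lengths = cfg$chrom_lengths,
    gc_content = cfg$gc_content, n_genes = cfg$n_genes,
    cancer_fraction = cfg$cancer_fraction,
    gene_length_range = c(cfg$gene_length_min, cfg$gene_length_max),
    seed = cfg$seed)
  write_genome(toy$genome, out_path(cfg, "genome.fasta"))
  write_annotation(toy$genes, out_path(cfg, "genes.bed"))
  writeLines(toy$genes$name[toy$genes$cancer],
             out_path(cfg, "cancer_genes.txt"))
  hotspot <- NULL
  if (!is.na(cfg$hotspot_chrom) && cfg$hotspot_fraction > 0) {
    hotspot <- list(chrom = cfg$hotspot_chrom, start = cfg$hotspot_start,
                    end = cfg$hotspot_end, fraction = cfg$hotspot_fraction)
  }
  sc <- sim_config(n_events = cfg$n_events, hotspot = hotspot,
                   abundance_model = cfg$abundance_model, theta = cfg$theta,
                   error_rate = cfg$error_rate,
                   read_length = cfg$read_length,
                   max_flank = cfg$max_flank,
                   min_fragment = cfg$min_fragment, depth = cfg$depth,
                   seed = cfg$seed + 1L)
  events <- plant_integrations(toy$genome, sc)
  conc <- NULL
  if (cfg$concatemer_abundance > 0) {
    total_ab <- sum(events$abundance)
    share <- cfg$concatemer_abundance /
      max(1 - cfg$concatemer_abundance, 1e-9) * total_ab
    conc <- concatemer_junctions(
      abundances = share * c(0.6, 0.2, 0.2))
  }
  sim <- lam_pcr_reads(toy$genome, events, toy_vector(), toy_linker(),
                       lam_enzymes(), sc, concatemers = conc)
  write_fastq(sim, out_path(cfg, "reads.fastq"))
  write_tsv(sim$truth, out_path(cfg, "truth.tsv"))
  write_tsv(sim$events, out_path(cfg, "events.tsv"))
  stage_artifacts$simulate
}

stage_call <- function(cfg) {
  reads <- read_fastq(out_path(cfg, "reads.fastq"))
  fq <- filter_quality(reads, min_length = cfg$min_read_length,
                       max_fraction_N = cfg$max_fraction_N)
  params <- junction_params(max_mismatches = cfg$max_mismatches,
                            k_vec = cfg$k_vec,
                            min_fragment = cfg$min_fragment)
  calls <- classify_reads(fq$reads, toy_vector(), toy_linker(), params)
  write_tsv(calls, out_path(cfg, "junctions.tsv"))
  write_tsv(fq$log, out_path(cfg, "filter_log.tsv"))
  write_fragments_fasta(calls, out_path(cfg, "is_fragments.fasta"))
  stage_artifacts$call
}

stage_map <- function(cfg) {
  genome <- read_genome(out_path(cfg, "genome.fasta"))
  calls <- read_tsv(out_path(cfg, "junctions.tsv"),
                    colClasses = c(fragment = "character"))
  calls$fragment[is.na(calls$fragment)] <- ""
  index <- build_index(genome, k = cfg$k)
  params <- mapping_params(min_identity = cfg$min_identity,
                           min_aligned = cfg$min_aligned,
                           score_margin = cfg$score_margin)
  mapped <- map_fragments(calls, index, params)
  write_tsv(mapped, out_path(cfg, "mapped.tsv"))
  stage_artifacts$map
}

stage_quantify <- function(cfg) {
  calls <- read_tsv(out_path(cfg, "junctions.tsv"))
  mapped <- read_tsv(out_path(cfg, "mapped.tsv"))
  genes <- read_annotation(out_path(cfg, "genes.bed"), format = "bed",
                           cancer_list_path = out_path(cfg,
                                                       "cancer_genes.txt"))
  sites <- collapse_sites(mapped, window_bp = cfg$window_bp)
  if (nrow(sites) > 0) {
    sites <- quantify_sites(sites)
    sites <- annotate_sites(sites, genes)
  }
  write_tsv(sites, out_path(cfg, "sites.tsv"))
  write_sites_bed(sites, out_path(cfg, "sites.bed"))
  write_tsv(if (nrow(sites)) top_sites(sites, cfg$top_n) else sites,
            out_path(cfg, "top_sites.tsv"))
  summary <- summarize_sample(calls, mapped, sites,
                              sample_id = cfg$sample_id,
                              time_point = cfg$time_point,
                              window_bp = cfg$window_bp)
  write_tsv(summary, out_path(cfg, "sample_summary.tsv"))
  stage_artifacts$quantify
}

stage_test <- function(cfg) {
  genome <- read_genome(out_path(cfg, "genome.fasta"))
  genes <- read_annotation(out_path(cfg, "genes.bed"), format = "bed",
                           cancer_list_path = out_path(cfg,
                                                       "cancer_genes.txt"))
  sites <- read_tsv(out_path(cfg, "sites.tsv"))
  null <- random_null(genome, size = cfg$null_size, mode = cfg$null_mode,
                      enzymes = lam_enzymes(), seed = cfg$seed + 2L)
  write_tsv(null, out_path(cfg, "null.tsv"))
  hs <- chrom_hotspot_scan(sites, null, alpha = cfg$alpha,
                           correction = cfg$correction)
  write_tsv(hs, out_path(cfg, "hotspots.tsv"))
  ctx_sites <- gene_context(sites, genes)
  ctx_null <- gene_context(null, genes)
  ctx <- data.frame(bin = ctx_sites$bin,
                    sites_count = ctx_sites$count,
                    sites_fraction = ctx_sites$fraction,
                    null_count = ctx_null$count,
                    null_fraction = ctx_null$fraction)
  write_tsv(ctx, out_path(cfg, "gene_context.tsv"))
  enr <- cancer_gene_enrichment(sites, genes, null)
  write_tsv(enr, out_path(cfg, "cancer_enrichment.tsv"))
  stage_artifacts$test
}

stage_report <- function(cfg) {
  summary <- read_tsv(out_path(cfg, "sample_summary.tsv"))
  top <- read_tsv(out_path(cfg, "top_sites.tsv"))
  hs <- read_tsv(out_path(cfg, "hotspots.tsv"))
  ctx <- read_tsv(out_path(cfg, "gene_context.tsv"))
  enr <- read_tsv(out_path(cfg, "cancer_enrichment.tsv"))
  con <- file(out_path(cfg, "report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# lamis integration-site report", "",
    "## Sample summary (IS vs concatemer composition)")
  w(utils::capture.output(print(summary, row.names = FALSE)))
  w("", "## Top clonal integration sites")
  w(utils::capture.output(print(top, row.names = FALSE)))
  w("", "## Chromosomal distribution vs synthetic random dataset")
  w(utils::capture.output(print(hs, row.names = FALSE)))
  w("", "## Gene-context distribution (sites vs null)")
  w(utils::capture.output(print(ctx, row.names = FALSE)))
  w("", "## Cancer-gene enrichment")
  w(utils::capture.output(print(enr, row.names = FALSE)))
  stage_artifacts$report
}
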