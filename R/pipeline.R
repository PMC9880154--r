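## Orchestration: a single run configuration drives simulate -> call ->
## islands -> scan-tfbs -> stats, writing every output plus a replayable log
## into one run directory.

#' Build a run configuration
#'
#' Returns the default configuration, optionally overridden by a YAML file
#' and/or a named list. The default mode simulates the full study design:
#' three stages x three animals, a 1080 bp promoter with 32 CpGs and a
#' planted ~120 bp islet, two overlapping sequencing amplicons per sample,
#' pooled molecule traces, and a triplicate qPCR plate.
#'
#' @param config_file optional YAML file with overrides.
#' @param overrides optional named list of overrides (applied last).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, overrides = list()) {
  cfg <- list(
    mode = "simulate",
    seed = 1L,
    out = "methylotrace_run",
    promoter = list(total_len = 1080L, islet_span = c(-200L, -80L),
                    islet_gc = 0.578, islet_oe = 0.70,
                    background_cpg_per_100bp = 2.3),
    cohort = list(animal_sd = 0.04),
    pool = list(n_molecules = 10000L, conversion_rate = 0.99),
    trace = list(peak_spacing = 10L, peak_sd = 2, noise_sd = 5,
                 amplitude = 1000),
    amplicons = list(c(1L, 600L), c(481L, 1080L)),
    calling = list(secondary_threshold = 0.33, min_identity = 0.8),
    islands = list(window = 100L, minlen = 100L, min_oe = 0.6, min_gc = 50),
    tfbs = list(motifs = NULL, annotation = NULL, deficit = 0.15,
                strands = "+", min_ntpm = 1),
    qpcr = list(replicates = 3L, ct_noise_sd = 0.15,
                target_gene = "target", reference_gene = "reference"),
    paths = list())
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("no such config file: ", config_file)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(config_file))
  }
  cfg <- utils::modifyList(cfg, overrides)
  if (is.null(cfg$tfbs$motifs))
    cfg$tfbs$motifs <- system.file("extdata", "example_motifs.jaspar",
                                   package = "methylotrace")
  if (is.null(cfg$tfbs$annotation))
    cfg$tfbs$annotation <- system.file("extdata",
                                       "synthetic_regulators.tsv",
                                       package = "methylotrace")
  class(cfg) <- c("run_config", "list")
  cfg
}

.validate_config <- function(cfg) {
  if (!cfg$mode %in% c("simulate", "replicate"))
    stop("config error: mode must be 'simulate' or 'replicate'")
  for (p in c("motifs", "annotation")) {
    path <- cfg$tfbs[[p]]
    if (is.null(path) || !nzchar(path) || !file.exists(path))
      stop("config error: tfbs$", p, " path does not exist: ", path)
  }
  if (cfg$mode == "replicate") {
    for (p in c("reference", "catalog", "traces_manifest", "ct_table")) {
      path <- cfg$paths[[p]]
      if (is.null(path) || !file.exists(path))
        stop("config error: paths$", p, " does not exist")
    }
  }
  invisible(TRUE)
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes simulate (in simulate mode) -> call -> islands -> scan-tfbs ->
#' stats and writes every output into `config$out`: the reference FASTA and
#' CpG catalog, per-sample traces (simulate mode), merged methylation
#' profiles, conversion QC, island calls, TFBS hits and regulator summary,
#' site-wise tests, region ANOVA, expression and correlation tables, and a
#' log recording the seed, parameters and config hash. Re-running with the
#' same config is bit-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with all in-memory results.
#' @export
run_all <- function(config = run_config()) {
  cfg <- config
  .validate_config(cfg)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat(sprintf("methylotrace run (mode=%s, seed=%d, config md5=%s)\n",
              cfg$mode, cfg$seed, .config_hash(cfg)),
      file = log_path)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out, "config.yaml"))
  seed <- as.integer(cfg$seed)
  stage_name <- "setup"
  result <- tryCatch({
    if (cfg$mode == "simulate") {
      stage_name <- "simulate"
      logf("stage simulate: building promoter and cohort")
      promoter <- make_promoter_sequence(
        total_len = cfg$promoter$total_len,
        islet_span = cfg$promoter$islet_span,
        islet_gc = cfg$promoter$islet_gc,
        islet_oe = cfg$promoter$islet_oe,
        background_cpg_per_100bp = cfg$promoter$background_cpg_per_100bp,
        seed = seed)
      catalog <- assign_regions(promoter$catalog)
      design <- default_cohort_design(animal_sd = cfg$cohort$animal_sd)
      write_reference_fasta(promoter$sequence,
                            file.path(cfg$out, "reference.fa"))
      write_cpg_catalog(catalog, file.path(cfg$out, "cpg_catalog.tsv"))
      truth <- simulate_methylome(catalog, design, seed = seed + 1L)
      write.table(truth, file.path(cfg$out, "truth_methylome.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ct_table <- simulate_qpcr(design, replicates = cfg$qpcr$replicates,
                                ct_noise_sd = cfg$qpcr$ct_noise_sd,
                                seed = seed + 2L,
                                target_gene = cfg$qpcr$target_gene,
                                reference_gene = cfg$qpcr$reference_gene)
      write.table(ct_table, file.path(cfg$out, "qpcr.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ref_ctx <- reference_context(promoter$sequence, promoter$tss_abs_pos,
                                   catalog)
      trace_dir <- file.path(cfg$out, "traces")
      dir.create(trace_dir, showWarnings = FALSE)
      manifest <- list()
      samples <- unique(truth[, c("sample_id", "stage")])
      k <- 10L
      for (i in seq_len(nrow(samples))) {
        sid <- samples$sample_id[i]
        tr <- truth[truth$sample_id == sid, , drop = FALSE]
        mm_all <- data.frame(abs_pos = catalog$abs_pos,
                             fraction = tr$true_fraction[
                               match(catalog$cpg_id, tr$cpg_id)])
        for (a in seq_along(cfg$amplicons)) {
          span <- cfg$amplicons[[a]]
          subref <- substr(promoter$sequence, span[1], span[2])
          inside <- mm_all$abs_pos >= span[1] &
            mm_all$abs_pos + 1L <= span[2]
          mm <- data.frame(abs_pos = mm_all$abs_pos[inside] - span[1] + 1L,
                           fraction = mm_all$fraction[inside])
          pool <- bisulfite_convert_pool(
            subref, mm, n_molecules = cfg$pool$n_molecules,
            conversion_rate = cfg$pool$conversion_rate,
            seed = seed + k, sample_id = sprintf("%s_amp%d", sid, a))
          trace <- render_trace(pool, peak_spacing = cfg$trace$peak_spacing,
                                peak_sd = cfg$trace$peak_sd,
                                noise_sd = cfg$trace$noise_sd,
                                seed = seed + k + 1L,
                                amplitude = cfg$trace$amplitude)
          k <- k + 2L
          path <- file.path(trace_dir, sprintf("%s_amp%d.tsv", sid, a))
          write_trace_tsv(trace, path)
          manifest[[length(manifest) + 1L]] <- data.frame(
            sample_id = sid, stage = samples$stage[i], amplicon = a,
            path = path, format = "tsv", stringsAsFactors = FALSE)
        }
      }
      manifest <- do.call(rbind, manifest)
      write.table(manifest, file.path(cfg$out, "traces_manifest.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      logf("stage simulate: %d CpGs, %d samples, %d traces",
           nrow(catalog), nrow(samples), nrow(manifest))
    } else {
      stage_name <- "load"
      logf("stage load: reading user inputs")
      ref_set <- Biostrings::readDNAStringSet(cfg$paths$reference)
      catalog <- read_cpg_catalog(cfg$paths$catalog)
      tss <- cfg$paths$tss_abs_pos
      if (is.null(tss))
        stop("config error: paths$tss_abs_pos required in replicate mode")
      ref_ctx <- reference_context(as.character(ref_set[[1]]), tss, catalog)
      promoter <- list(sequence = ref_ctx$reference,
                       tss_abs_pos = ref_ctx$tss_abs_pos,
                       islet_abs_span = NULL)
      manifest <- read.delim(cfg$paths$traces_manifest,
                             stringsAsFactors = FALSE)
      ct_table <- read.delim(cfg$paths$ct_table, stringsAsFactors = FALSE)
      truth <- NULL
    }

    stage_name <- "call"
    logf("stage call: base calling, alignment, methylation")
    profiles <- list(); qc_rows <- list()
    for (sid in unique(manifest$sample_id)) {
      rows <- manifest[manifest$sample_id == sid, , drop = FALSE]
      amp_profiles <- list()
      for (i in seq_len(nrow(rows))) {
        trace <- if (identical(rows$format[i], "ab1"))
          read_ab1(rows$path[i], sample_id = sid)
        else read_trace_tsv(rows$path[i], sample_id = sid)
        calls <- call_bases(trace,
                            secondary_threshold =
                              cfg$calling$secondary_threshold)
        aln <- align_read(calls$primary, ref_ctx,
                          min_identity = cfg$calling$min_identity)
        amp_profiles[[i]] <- call_methylation(calls, aln, ref_ctx,
                                              stage = rows$stage[i])
        qc <- conversion_qc(calls, aln, ref_ctx)
        qc_rows[[length(qc_rows) + 1L]] <- data.frame(
          sample_id = sid, amplicon = rows$amplicon[i],
          identity = aln$identity, conversion_rate = qc$rate,
          n_sites = qc$n_sites, status = qc$status,
          stringsAsFactors = FALSE)
      }
      profiles[[length(profiles) + 1L]] <- merge_amplicons(amp_profiles)
    }
    profiles <- do.call(rbind, profiles)
    qc <- do.call(rbind, qc_rows)
    write_profiles(profiles, file.path(cfg$out, "profiles.tsv"))
    write.table(qc, file.path(cfg$out, "qc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    stage_name <- "islands"
    logf("stage islands: sliding-window detection")
    islands <- find_cpg_islands(promoter$sequence,
                                window = cfg$islands$window,
                                minlen = cfg$islands$minlen,
                                min_oe = cfg$islands$min_oe,
                                min_gc = cfg$islands$min_gc)
    write_island_bed(islands, file.path(cfg$out, "islands.tsv"))

    stage_name <- "scan-tfbs"
    logf("stage scan-tfbs: PWM scan of the islet")
    scan_span <- if (!is.null(promoter$islet_abs_span))
      promoter$islet_abs_span
    else if (nrow(islands)) c(islands$start[1], islands$end[1])
    else c(1L, nchar(promoter$sequence))
    islet_seq <- substr(promoter$sequence, scan_span[1], scan_span[2])
    pwms <- read_jaspar(cfg$tfbs$motifs)
    hits <- scan_sequence(pwms, islet_seq, deficit = cfg$tfbs$deficit,
                          strands = cfg$tfbs$strands)
    annotation <- read_regulator_annotation(cfg$tfbs$annotation)
    regulators <- classify_regulators(hits, annotation,
                                      min_ntpm = cfg$tfbs$min_ntpm)
    write.table(hits, file.path(cfg$out, "tfbs_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_factors = regulators$n_factors,
           counts = as.list(regulators$counts),
           expressed_repressors = regulators$expressed_repressors,
           unannotated = regulators$unannotated),
      file.path(cfg$out, "regulators.json"), auto_unbox = TRUE, digits = NA)

    stage_name <- "stats"
    logf("stage stats: site-wise, region ANOVA, expression, correlation")
    sitewise <- sitewise_tests(profiles)
    regions <- region_anova(profiles)
    expression <- ddct_expression(ct_table,
                                  target_gene = cfg$qpcr$target_gene,
                                  reference_gene = cfg$qpcr$reference_gene)
    correlation <- region_expression_correlation(profiles, expression)
    write.table(sitewise, file.path(cfg$out, "stats_sitewise.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(regions$omnibus, file.path(cfg$out, "stats_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(regions$posthoc, file.path(cfg$out, "stats_posthoc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(expression$samples, file.path(cfg$out, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(correlation, file.path(cfg$out, "correlation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logf("run complete")
    list(promoter = promoter, catalog = ref_ctx$catalog, truth = truth,
         profiles = profiles, qc = qc, islands = islands, hits = hits,
         regulators = regulators, sitewise = sitewise, regions = regions,
         expression = expression, correlation = correlation,
         out = cfg$out)
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage_name, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage_name,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
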