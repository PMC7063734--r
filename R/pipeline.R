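# Pipeline orchestration: filter -> stereotype scan -> clonal clustering ->
# collapse to representatives -> SHM -> frequency/statistics, as one
# reproducible run, plus the command-line entry points.

config_or_default <- function(config) {
  if (is.null(config)) return(structure(list(), class = c("stereorep_config",
                                                          "list")))
  if (is.character(config)) return(read_config(config))
  config
}

criteria_from_config <- function(cfg) {
  f <- cfg$filter
  filter_criteria(
    require_productive = f$require_productive %||% TRUE,
    allowed_v_families = as.character(f$allowed_v_families %||% "IGHV1"),
    allowed_isotypes = as.character(f$allowed_isotypes %||%
                                      c("IGHM", "IGHG")))
}

groups_from_config <- function(cfg) {
  if (is.null(cfg$similarity_groups)) return(default_similarity_groups())
  validate_similarity_groups(lapply(cfg$similarity_groups, as.character))
}

clans_from_config <- function(cfg) {
  if (is.null(cfg$clan_table)) return(default_clan_table())
  unlist(cfg$clan_table)
}

#' Run the full detection pipeline
#'
#' Stage order mirrors the study design: record filtering, stereotype
#' scanning of all retained sequences, clonal-family inference with a
#' per-sample/per-population distance threshold, collapse to one
#' representative per clonal family, SHM status, then clone-level
#' frequency tables and statistics. All outputs are plain-text and byte
#' stable for fixed inputs and seed.
#'
#' @param input Path to an AIRR rearrangement TSV.
#' @param germline Optional path to a germline V FASTA (needed only when
#'   records lack `v_identity` and carry `v_sequence`).
#' @param config Path to a YAML configuration, a config list, or `NULL`
#'   for defaults. The `subsets` section is required for stereotype
#'   scanning.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the Monte Carlo statistics.
#' @param scan_representatives_only If `TRUE`, stereotype scanning is
#'   applied after clonal collapse instead of to all sequences.
#' @return The run manifest (list), invisibly; files written:
#'   `annotated.tsv`, `thresholds.tsv`, `frequencies_by_subset.tsv`,
#'   `frequencies_by_population.tsv`, `stats.json`, `manifest.json`,
#'   `run.log`.
#' @export
run_pipeline <- function(input, germline = NULL, config = NULL, out_dir,
                         seed = 1L, scan_representatives_only = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg <- config_or_default(config)

  records <- stage("read", read_rearrangements(
    input, column_map = do.call(airr_column_map,
                                as.list(cfg$column_map %||% list()))))
  say("read: ", nrow(records), " records")

  criteria <- criteria_from_config(cfg)
  filtered <- stage("filter", filter_records(records, criteria))
  tally <- attr(filtered, "rejection_tally")
  say("filter: ", nrow(filtered), " kept (",
      paste(names(tally), tally, sep = "=", collapse = ", "), ")")

  defs <- stage("subsets", {
    if (is.null(cfg$subsets)) stop("configuration has no subsets section")
    read_subset_definitions(cfg)
  })
  groups <- groups_from_config(cfg)
  clans <- clans_from_config(cfg)

  if (nrow(filtered) == 0L) {
    say("no records after filtering; writing empty reports")
    manifest <- write_outputs(out_dir, filtered, NULL, list(), cfg, input,
                              seed, counts = list(input = nrow(records),
                                                  filtered = 0L,
                                                  clones = 0L,
                                                  representatives = 0L,
                                                  cbs_clones = 0L))
    writeLines(log_lines, log_path)
    return(invisible(manifest))
  }

  if (!scan_representatives_only) {
    filtered <- stage("stereotype_scan",
                      assign_stereotypes(filtered, defs, clans = clans,
                                         groups = groups))
    say("stereotype scan: ", sum(!is.na(filtered$subset_id)),
        " of ", nrow(filtered), " sequences matched a subset")
  }

  clust_cfg <- cfg$clustering %||% list()
  clustered <- stage("clonal_clustering", infer_clones(
    filtered,
    threshold = clust_cfg$fixed_threshold,
    bandwidth = clust_cfg$bandwidth %||% 0.02,
    min_distances = clust_cfg$min_distances %||% 50,
    fallback = clust_cfg$fallback %||% 0.15))
  thresholds <- attr(clustered, "thresholds")
  n_clones <- length(unique(clustered$clone_id))
  say("clonal clustering: ", n_clones, " clonal families")

  reps <- clustered[clustered$is_representative, , drop = FALSE]
  if (scan_representatives_only) {
    reps <- stage("stereotype_scan",
                  assign_stereotypes(reps, defs, clans = clans,
                                     groups = groups))
    clustered <- reps
  }
  say("collapse: ", nrow(reps), " representatives")

  germ <- if (!is.null(germline)) read_germline_fasta(germline) else NULL
  shm_cfg <- cfg$shm %||% list()
  reps <- stage("shm", annotate_shm(reps,
                                    cutoff_pct = shm_cfg$cutoff_pct %||% 1.0,
                                    germline = germ))
  say("shm: ", sum(reps$shm_status == "unmutated"), " unmutated of ",
      nrow(reps), " representatives")

  stats <- stage("statistics",
                 pipeline_statistics(reps, n_clones, seed,
                                     iterations = cfg$statistics$iterations
                                     %||% 10000L))
  say("statistics: ", length(stats$tests), " test(s) run")

  manifest <- write_outputs(out_dir, clustered, thresholds, stats, cfg,
                            input, seed,
                            counts = list(input = nrow(records),
                                          filtered = nrow(filtered),
                                          clones = n_clones,
                                          representatives = nrow(reps),
                                          cbs_clones =
                                            sum(!is.na(reps$subset_id))),
                            reps = reps)
  writeLines(log_lines, log_path)
  invisible(manifest)
}

# clone-level frequency reports and the cohort tests that are feasible on
# the data at hand
pipeline_statistics <- function(reps, n_clones, seed, iterations = 10000L) {
  out <- list(tests = list())
  if (nrow(reps) == 0L || n_clones == 0L) return(out)
  out$by_subset <- frequency_table(reps, n_clones, "by_subset", decimals = 3L)
  out$by_population <- frequency_table(reps, n_clones, "by_population",
                                       decimals = 3L)
  # CD5+ vs CD5- enrichment of stereotyped clones, when both fractions exist
  cd5 <- reps$population_label %in% c("CD5pos", "CD5neg")
  if (length(unique(reps$population_label[cd5])) == 2L) {
    tab <- table(factor(reps$population_label[cd5],
                        levels = c("CD5pos", "CD5neg")),
                 factor(!is.na(reps$subset_id[cd5]),
                        levels = c(TRUE, FALSE)))
    tab <- as.matrix(tab)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      out$tests$cd5_fisher <- fisher_exact_2x2(tab)
  }
  # subset distribution across populations (Monte Carlo Fisher) when the
  # stereotyped clones span >= 2 populations and >= 2 subsets
  cbs <- reps[!is.na(reps$subset_id), , drop = FALSE]
  if (nrow(cbs) > 0L) {
    tab <- table(cbs$subset_id, cbs$population_label)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) >= 2L && ncol(tab) >= 2L)
      out$tests$subset_by_population_fisher_mc <-
        fisher_exact_mc(as.matrix(unclass(tab)), iterations = iterations,
                        seed = seed)
  }
  out
}

write_outputs <- function(out_dir, annotated, thresholds, stats, cfg, input,
                          seed, counts, reps = NULL) {
  write_rearrangements(annotated, file.path(out_dir, "annotated.tsv"))
  if (is.null(thresholds))
    thresholds <- data.frame(group = character(), value = numeric(),
                             method = character(), n_distances = integer())
  utils::write.table(thresholds, file.path(out_dir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  freq_or_empty <- function(x) {
    if (is.null(x)) data.frame(group = character(), count = integer(),
                               percent = numeric())
    else as.data.frame(x)
  }
  utils::write.table(freq_or_empty(stats$by_subset),
                     file.path(out_dir, "frequencies_by_subset.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(freq_or_empty(stats$by_population),
                     file.path(out_dir, "frequencies_by_population.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tests <- lapply(stats$tests %||% list(), unclass)
  jsonlite::write_json(tests, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), cfg_tmp)
  manifest <- list(
    package = "stereorep",
    version = as.character(utils::packageVersion("stereorep")),
    seed = as.integer(seed),
    input_md5 = unname(tools::md5sum(input)),
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    stage_counts = counts,
    thresholds = thresholds)
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a synthetic repertoire and its truth sidecar),
#' `run` (full pipeline), `evaluate` (score predictions against truth).
#' Shared flags: `--config`, `--seed`, `--out`, `--log-level`. Designed to
#' be called from an Rscript wrapper (see `inst/bin/stereorep`).
#'
#' @param argv Character vector of command-line arguments (first element:
#'   the verb).
#' @return Exit status 0, invisibly; errors propagate (non-zero exit under
#'   Rscript).
#' @export
stereorep_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv))
    stop("usage: stereorep <simulate|run|evaluate> [options]")
  verb <- argv[1]
  rest <- argv[-1]
  opts <- list(
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--germline", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--truth", type = "character", default = NULL),
    optparse::make_option("--predictions", type = "character",
                          default = NULL),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                              args = rest)
  quiet <- identical(opt$log_level, "quiet")
  run <- function(expr) if (quiet) suppressMessages(expr) else expr
  switch(verb,
    simulate = {
      cfg <- if (!is.null(opt$config)) read_config(opt$config) else NULL
      sim_args <- as.list(cfg$simulation %||% list())
      sim_args$seed <- opt$seed
      scfg <- do.call(simulation_config, sim_args)
      defs <- if (!is.null(cfg$subsets)) read_subset_definitions(cfg)
              else list()
      sim <- generate_repertoire(scfg, defs)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_rearrangements(sim$records,
                           file.path(opt$out, "simulated.tsv"))
      write_truth(sim$truth, file.path(opt$out, "truth.tsv"))
    },
    run = {
      if (is.null(opt$input)) stop("run requires --input")
      run(run_pipeline(opt$input, germline = opt$germline,
                       config = opt$config, out_dir = opt$out,
                       seed = opt$seed))
    },
    evaluate = {
      if (is.null(opt$predictions) || is.null(opt$truth))
        stop("evaluate requires --predictions and --truth")
      pred <- read_rearrangements(opt$predictions)
      ann <- utils::read.delim(opt$predictions, sep = "\t",
                               colClasses = "character", quote = "")
      pred$subset_id <- ann$subset_id[match(pred$sequence_id,
                                            ann$sequence_id)]
      pred$subset_id[pred$subset_id == ""] <- NA_character_
      if ("clone_id" %in% names(ann))
        pred$clone_id <- ann$clone_id[match(pred$sequence_id,
                                            ann$sequence_id)]
      truth <- utils::read.delim(opt$truth, sep = "\t",
                                 colClasses = "character", quote = "")
      truth$subset_id[truth$subset_id %in% c("", "NA")] <- NA_character_
      metrics <- evaluate_recovery(pred, truth)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(metrics, file.path(opt$out, "recovery.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    stop("unknown verb: ", verb))
  invisible(0L)
}
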