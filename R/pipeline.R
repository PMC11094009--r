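## End-to-end orchestration: consensus construction -> allelic filters ->
## ratio time course -> decay fits and halftimes -> persistent/depleted
## classification -> TF-binding enrichment contrast. Configured by a nested
## list (YAML-loadable) validated fail-fast against the known key schema.

pipeline_defaults <- function() {
  list(
    preset = "atac",
    seed = 1L,
    output_dir = "xcikinetics_out",
    paths = list(peaks = NULL, blacklist = NULL, tss = NULL,
                 tf_peaks = NULL, counts_total = NULL,
                 counts_genome1 = NULL, counts_genome2 = NULL,
                 design = NULL),
    consensus = list(min_support = 2L, min_len = 50, max_len = 10000),
    filters = list(min_allelic = NULL, min_sample_frac = NULL,
                   ar0_low = NULL, ar0_high = NULL,
                   min_allelic_strict = NULL),
    ratios = list(aggregation = "mean_of_replicates"),
    kinetics = list(t_threshold_days = 5.4, biallelic_npc = 0.20,
                    halftime_variant = "derived", fit_points = "replicates",
                    fit_mode = "free_yf"),
    enrichment = list(tf_label = "YY1")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) {
        stop("config key ", full, " must be a mapping", call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected before any computation (fail-fast). Filter
#' thresholds left `NULL` are resolved from the preset (`atac`: >= 10
#' allelic fragments in > 80% of samples, day-0 ratio in (0.15, 0.85);
#' `chip_yy1` / `chip_oct4`: day-0 bounds (0.2, 0.8); `chrrna` uses the
#' `atac` thresholds).
#'
#' @param ... overrides of the default keys (nested lists for `paths`,
#'   `consensus`, `filters`, `ratios`, `kinetics`, `enrichment`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(pipeline_defaults(), user)
  if (!cfg$preset %in% c("atac", "chip_yy1", "chip_oct4", "chrrna")) {
    stop("unknown preset: ", cfg$preset, call. = FALSE)
  }
  preset <- allelic_filter_preset(
    if (cfg$preset %in% c("chip_yy1", "chip_oct4")) "chip" else "atac")
  for (key in names(preset)) {
    if (is.null(cfg$filters[[key]])) cfg$filters[[key]] <- preset[[key]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file of config keys (same schema as
#'   [pipeline_config()]).
#' @param ... further overrides applied on top.
#' @export
read_pipeline_config <- function(path, ...) {
  user <- yaml::read_yaml(path)
  overrides <- list(...)
  do.call(pipeline_config, modifyList(user, overrides))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full kinetics pipeline
#'
#' Stages: (1) consensus regulatory-element construction from replicate
#' peak files (length filter, blacklist subtraction); (2) count/design
#' loading, restricted to features overlapping the consensus set when one
#' was built; (3) allelic filters; (4) per-timepoint allelic-ratio matrix;
#' (5) exponential decay fits, halftimes and persistent/depleted
#' classification (NPC ratio = mean of final-timepoint replicate ratios);
#' (6) TF-binding annotation and persistent-vs-depleted Fisher enrichment
#' when TF peaks are supplied. All result tables, the consensus BED, a run
#' log and the resolved configuration are written into
#' `config$output_dir`; every output stays inside that directory.
#'
#' @param config `pipeline_config` object.
#' @return Invisibly, a list with `consensus`, `counts`, `design`,
#'   `filter_report`, `ratios`, `cohort`, `classification`, `enrichment`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- c(sprintf("xcikinetics %s",
                         as.character(utils::packageVersion("xcikinetics"))),
                 sprintf("R %s", R.version.string),
                 sprintf("preset=%s seed=%d", config$preset, config$seed))

  consensus <- NULL
  if (!is.null(config$paths$peaks)) {
    consensus <- stage("consensus", {
      reps <- lapply(config$paths$peaks, read_intervals, format = "bed")
      cs <- build_consensus(reps, min_support = config$consensus$min_support)
      cs <- filter_by_length(cs, config$consensus$min_len,
                             config$consensus$max_len)
      if (!is.null(config$paths$blacklist)) {
        bl <- read_intervals(config$paths$blacklist, format = "bed")
        cs <- subtract_blacklist(cs, bl)
      }
      write_bed(cs, file.path(out_dir, "consensus.bed"))
      cs
    })
    log_lines <- c(log_lines, sprintf("consensus: %d regions", nrow(consensus)))
  }

  loaded <- stage("counts", {
    p <- config$paths
    if (is.null(p$counts_total)) stop("no count tables configured")
    read_count_matrix(p$counts_total, p$counts_genome1, p$counts_genome2,
                      p$design)
  })
  counts <- loaded$counts; design <- loaded$design
  if (!is.null(consensus)) {
    keep <- overlaps_any(data.frame(chrom = counts$features$chrom,
                                    start = counts$features$start,
                                    end = counts$features$end),
                         consensus)
    counts <- subset_counts(counts, features = which(keep))
  }

  filt <- stage("filters", {
    f <- config$filters
    apply_allelic_filters(counts, design, min_allelic = f$min_allelic,
                          min_sample_frac = f$min_sample_frac,
                          ar0_low = f$ar0_low, ar0_high = f$ar0_high,
                          min_allelic_strict = f$min_allelic_strict)
  })
  write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))
  log_lines <- c(log_lines,
                 sprintf("filters: min_allelic=%g (strict=%s) frac>%g ar0=(%g,%g); %d/%d retained",
                         config$filters$min_allelic,
                         config$filters$min_allelic_strict,
                         config$filters$min_sample_frac,
                         config$filters$ar0_low, config$filters$ar0_high,
                         length(filt$keep), nrow(counts$total)))
  counts_f <- subset_counts(counts, features = filt$keep)

  ratios <- stage("ratios", {
    ratio_timecourse(counts_f, design,
                     aggregation = config$ratios$aggregation)
  })
  ratio_df <- data.frame(feature_id = rownames(ratios$ratio),
                         ratios$ratio, check.names = FALSE)
  write_tsv(ratio_df, file.path(out_dir, "allelic_ratios.tsv"))

  kin <- config$kinetics
  cohort <- stage("fit", {
    fit_decay_cohort(ratios, fit_mode = kin$fit_mode,
                     halftime_variant = kin$halftime_variant,
                     fit_points = kin$fit_points,
                     counts = counts_f, design = design)
  })
  classification <- stage("classify", {
    final_day <- max(ratios$days)
    npc <- ratios$ratio[, as.character(final_day)]
    classify_persistence(cohort, npc, t_threshold = kin$t_threshold_days,
                         biallelic_npc = kin$biallelic_npc)
  })
  fits_out <- merge(cohort$table,
                    classification[, c("feature_id", "label", "basis",
                                       "npc_ratio")],
                    by = "feature_id", sort = FALSE)
  fits_out$fit_mode <- kin$fit_mode
  write_tsv(fits_out, file.path(out_dir, "decay_fits.tsv"))
  log_lines <- c(log_lines, sprintf(
    "kinetics: %d fitted, %d halftimes, %d persistent / %d depleted / %d unclassified",
    sum(cohort$table$fittable), sum(!is.na(cohort$table$t_half)),
    sum(classification$label == "persistent"),
    sum(classification$label == "depleted"),
    sum(classification$label == "unclassified")))

  enrichment <- NULL
  if (!is.null(config$paths$tf_peaks)) {
    enrichment <- stage("enrich", {
      tf <- read_intervals(config$paths$tf_peaks, format = "bed")
      feats <- counts_f$features
      bound <- flag_overlap(data.frame(chrom = feats$chrom,
                                       start = feats$start,
                                       end = feats$end,
                                       name = feats$feature_id), tf,
                            label = config$enrichment$tf_label)
      lab <- classification$label[match(feats$feature_id,
                                        classification$feature_id)]
      fg <- lab == "persistent"; bg <- lab == "depleted"
      res <- fisher_enrichment(sum(bound & fg), sum(!bound & fg),
                               sum(bound & bg), sum(!bound & bg),
                               label = config$enrichment$tf_label)
      write_tsv(res, file.path(out_dir, "enrichment.tsv"))
      res
    })
  }

  yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(consensus = consensus, counts = counts_f, design = design,
                 filter_report = filt$report, ratios = ratios,
                 cohort = cohort, classification = classification,
                 enrichment = enrichment))
}
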