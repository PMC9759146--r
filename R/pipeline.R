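#' Load and validate a pipeline configuration
#'
#' Configurations are nested key-value lists (typically YAML on disk) with
#' blocks `simulation`, `preprocessing`, `connectivity`, `gt` and `stats`.
#' Every threshold defaults to the published value: 6 pT artifact exclusion,
#' 60 s analysis segment, edge significance p < .01, seven analysis bands.
#'
#' @param config A path to a YAML file or a nested list.
#' @return A validated list of class `meg_pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    out_dir = "megnet_out",
    simulation = list(
      n_per_group = 4, fs = 200, duration = 150,
      bands = c("alpha", "beta", "gamma"),
      spike_rate_per_min = 0.5, spike_amplitude_pt = 7
    ),
    preprocessing = list(
      notch_hz = 50, artifact_threshold_pt = 6, spike_z = 6,
      segment_length_s = 60
    ),
    connectivity = list(alpha = 0.01, use_effective_k = FALSE),
    gt = list(edge_policy = "positive"),
    stats = list(
      parameters = c("SA", "DA", "LA", "CA"),
      fc_regions = c("frontal", "pcc"),
      sig_threshold = 0.05
    )
  )
  cfg <- utils::modifyList(defaults, config)
  bands <- meg_bands(cfg$simulation$bands)
  if (cfg$simulation$fs <= 2 * max(bands$hi)) {
    abort("simulation$fs too low for the configured bands")
  }
  if (cfg$preprocessing$segment_length_s > cfg$simulation$duration) {
    abort("Segment length exceeds recording duration")
  }
  structure(cfg, class = c("meg_pipeline_config", "list"))
}

pipeline_log <- function(cfg, ...) {
  msg <- sprintf("[megnet %s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(msg)
  log_file <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) cat(msg, "\n", file = log_file, append = TRUE)
  invisible(msg)
}

require_stage <- function(cfg, path, stage) {
  if (!file.exists(path)) {
    abort(sprintf(
      "Missing upstream artifact '%s': run %s first", path, stage
    ))
  }
  invisible(path)
}

#' Pipeline stages
#'
#' Each stage is a pure function of (inputs, config, seed) and is idempotent:
#' rerunning with the same inputs overwrites identical outputs.
#' `run_simulate()` writes a synthetic cohort of recordings and a manifest;
#' `run_preprocess()` notch-filters each recording, flags artifacts (6 pT
#' rule) and spikes, and extracts the earliest clean 60 s segment;
#' `run_connect()` band-filters each segment and writes a thresholded
#' weighted edge list per subject and band; `run_metrics()` computes the
#' graph metrics table; `run_stats()` produces the band-wise group
#' comparisons, ROC analyses and a JSON report; `run_all()` chains them.
#'
#' @param config A `meg_pipeline_config`, list, or YAML path.
#' @return Each stage invisibly returns the path(s) of its main output;
#'   `run_stats()` returns the report as a list.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
run_simulate <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(file.path(cfg$out_dir, "recordings"), recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$simulation
  base <- default_sim_config(
    fs = sim$fs, duration = sim$duration, bands = meg_bands(sim$bands),
    seed = cfg$seed
  )
  pipeline_log(
    cfg, "simulate: %d subjects/group, fs=%g Hz, %g s, bands [%s], seed %d",
    sim$n_per_group, sim$fs, sim$duration,
    paste(sim$bands, collapse = ", "), cfg$seed
  )
  cohort <- generate_cohort(base, sim$n_per_group, seed = cfg$seed)
  cohort$file <- sprintf("sub-%02d.bin", cohort$subject_id)
  for (k in seq_len(nrow(cohort))) {
    rec <- cohort$recording[[k]]
    if (sim$spike_rate_per_min > 0) {
      rec <- inject_spikes(rec, sim$spike_rate_per_min, sim$spike_amplitude_pt,
        seed = cohort$seed[k] + 17L
      )
    }
    write_recording(rec, file.path(cfg$out_dir, "recordings", cohort$file[k]))
  }
  manifest <- cohort[, c("subject_id", "group", "seed", "file")]
  readr::write_csv(manifest, file.path(cfg$out_dir, "manifest.csv"), progress = FALSE)
  invisible(file.path(cfg$out_dir, "manifest.csv"))
}

#' @rdname pipeline-stages
#' @export
run_preprocess <- function(config) {
  cfg <- pipeline_config(config)
  manifest_path <- require_stage(cfg, file.path(cfg$out_dir, "manifest.csv"), "run_simulate")
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  dir.create(file.path(cfg$out_dir, "segments"), showWarnings = FALSE)
  pp <- cfg$preprocessing
  pipeline_log(
    cfg, "preprocess: notch %g Hz, artifact > %g pT, spike z > %g, %g s segment",
    pp$notch_hz, pp$artifact_threshold_pt, pp$spike_z, pp$segment_length_s
  )
  starts <- purrr::map_dbl(seq_len(nrow(manifest)), function(k) {
    rec <- read_recording(file.path(cfg$out_dir, "recordings", manifest$file[k]))
    flags <- dplyr::bind_rows(
      detect_artifacts(rec, threshold = pp$artifact_threshold_pt),
      flag_spikes(rec, z_thresh = pp$spike_z)
    )
    if (pp$notch_hz < rec$fs / 2) rec <- notch_filter(rec, pp$notch_hz)
    seg <- select_clean_segment(rec, flags, length_s = pp$segment_length_s)
    seg_rec <- meg_recording(seg$data, seg$fs,
      node_labels = seg$node_labels, node_roles = seg$node_roles
    )
    write_recording(seg_rec, file.path(cfg$out_dir, "segments", manifest$file[k]))
    readr::write_tsv(flags, file.path(
      cfg$out_dir, "segments",
      sub("\\.bin$", "_flags.tsv", manifest$file[k])
    ), progress = FALSE)
    seg$start_s
  })
  manifest$segment_start_s <- starts
  readr::write_csv(manifest, file.path(cfg$out_dir, "segments", "manifest.csv"),
    progress = FALSE
  )
  invisible(file.path(cfg$out_dir, "segments", "manifest.csv"))
}

#' @rdname pipeline-stages
#' @export
run_connect <- function(config) {
  cfg <- pipeline_config(config)
  manifest_path <- require_stage(
    cfg, file.path(cfg$out_dir, "segments", "manifest.csv"), "run_preprocess"
  )
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  dir.create(file.path(cfg$out_dir, "networks"), showWarnings = FALSE)
  bands <- meg_bands(cfg$simulation$bands)
  pipeline_log(
    cfg, "connect: alpha %g, effective K %s",
    cfg$connectivity$alpha, cfg$connectivity$use_effective_k
  )
  for (k in seq_len(nrow(manifest))) {
    seg_rec <- read_recording(file.path(cfg$out_dir, "segments", manifest$file[k]))
    seg <- select_clean_segment(seg_rec, NULL,
      length_s = nrow(seg_rec$data) / seg_rec$fs
    )
    for (b in seq_len(nrow(bands))) {
      cm <- pairwise_correlation(
        segment_bandpass(seg, bands[b, ]),
        effective_k = cfg$connectivity$use_effective_k
      )
      net <- threshold_network(cm,
        alpha = cfg$connectivity$alpha,
        use_effective_k = cfg$connectivity$use_effective_k
      )
      write_network(net, file.path(
        cfg$out_dir, "networks",
        sprintf("sub-%02d_%s.tsv", manifest$subject_id[k], bands$band[b])
      ))
    }
  }
  invisible(file.path(cfg$out_dir, "networks"))
}

#' @rdname pipeline-stages
#' @export
run_metrics <- function(config) {
  cfg <- pipeline_config(config)
  net_dir <- file.path(cfg$out_dir, "networks")
  if (!dir.exists(net_dir) || !length(list.files(net_dir))) {
    abort("Missing upstream artifacts in 'networks/': run run_connect first")
  }
  manifest <- readr::read_csv(file.path(cfg$out_dir, "manifest.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  pipeline_log(cfg, "metrics: edge policy '%s'", cfg$gt$edge_policy)
  files <- sort(list.files(net_dir, pattern = "\\.tsv$", full.names = TRUE))
  metrics <- purrr::map_dfr(files, function(f) {
    sid <- as.integer(sub("sub-(\\d+)_.*", "\\1", basename(f)))
    graph_metrics(read_network(f),
      edge_policy = cfg$gt$edge_policy, subject_id = sid
    )
  }) |>
    dplyr::left_join(manifest[, c("subject_id", "group")], by = "subject_id")
  readr::write_csv(metrics, file.path(cfg$out_dir, "metrics.csv"), progress = FALSE)
  invisible(file.path(cfg$out_dir, "metrics.csv"))
}

#' @rdname pipeline-stages
#' @export
run_stats <- function(config) {
  cfg <- pipeline_config(config)
  metrics_path <- require_stage(cfg, file.path(cfg$out_dir, "metrics.csv"), "run_metrics")
  metrics <- readr::read_csv(metrics_path, show_col_types = FALSE, progress = FALSE)
  n_groups <- length(unique(metrics$group))
  n_bands <- length(unique(metrics$band))
  params <- cfg$stats$parameters
  m_fc <- correction_count(n_groups, n_bands)
  m_gt <- correction_count(n_groups, n_bands, length(params))
  pipeline_log(cfg, "stats: Bonferroni m_fc=%d, m_gt=%d", m_fc, m_gt)
  order_groups <- intersect(c("fsiq_lt80", "fsiq_gt80", "hc"), unique(metrics$group))
  fc_cols <- paste0("fc_", cfg$stats$fc_regions)
  fc_tbl <- purrr::map_dfr(
    intersect(fc_cols, names(metrics)),
    function(v) compare_bands(metrics, v, m = m_fc, group_order = order_groups)
  )
  gt_tbl <- purrr::map_dfr(
    params,
    function(v) compare_bands(metrics, v, m = m_gt, group_order = order_groups)
  )
  readr::write_csv(fc_tbl, file.path(cfg$out_dir, "comparison_fc.csv"), progress = FALSE)
  readr::write_csv(gt_tbl, file.path(cfg$out_dir, "comparison_gt.csv"), progress = FALSE)

  # ROC over the patient groups only, for GT parameters whose corrected
  # ANOVA is significant (mirrors the discrimination analysis design).
  patients <- metrics[metrics$group %in% c("fsiq_lt80", "fsiq_gt80"), ]
  sig <- gt_tbl[
    !is.na(gt_tbl$p_bonferroni) &
      gt_tbl$p_bonferroni < cfg$stats$sig_threshold,
  ]
  roc_tbl <- purrr::map_dfr(seq_len(nrow(sig)), function(k) {
    d <- patients[patients$band == sig$band[k], ]
    if (length(unique(d$group)) < 2) {
      return(NULL)
    }
    roc <- roc_analysis(
      d[[sig$parameter[k]]], d$group == "fsiq_lt80",
      name = sprintf("%s, %s", sig$band[k], sig$parameter[k])
    )
    glance(roc)
  })
  if (!nrow(roc_tbl)) {
    roc_tbl <- tibble::tibble(
      indicator = character(), auc = numeric(), sensitivity = numeric(),
      specificity = numeric(), accuracy = numeric(), cutoff = numeric()
    )
  }
  readr::write_csv(roc_tbl, file.path(cfg$out_dir, "roc.csv"), progress = FALSE)
  report <- list(
    seed = cfg$seed,
    thresholds = list(
      artifact_pt = cfg$preprocessing$artifact_threshold_pt,
      segment_s = cfg$preprocessing$segment_length_s,
      edge_alpha = cfg$connectivity$alpha,
      bonferroni_fc = m_fc, bonferroni_gt = m_gt
    ),
    fc_comparisons = fc_tbl, gt_comparisons = gt_tbl, roc = roc_tbl
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(report)
}

#' @rdname pipeline-stages
#' @export
run_all <- function(config) {
  cfg <- pipeline_config(config)
  run_simulate(cfg)
  run_preprocess(cfg)
  run_connect(cfg)
  run_metrics(cfg)
  run_stats(cfg)
}

#' Path to the packaged demo pipeline configuration
#'
#' A reduced problem size (8 of the 12 nodes' bands, 200 Hz, 4 subjects per
#' group) so the full pipeline smoke-runs in well under a minute.
#'
#' @return Path to the YAML file.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "megnet")
}
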