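#' Build a validated run configuration
#'
#' Every default equals the study-standard parameter: sparsity grid
#' 0.10-0.50 in steps of 0.01, pass band 0.01-0.08 Hz, 10 discarded
#' volumes, motion limits 2 mm / 2 degrees (rotations stored in radians),
#' 10,000 permutations, FDR q = 0.05, NBS primary threshold t = 3.40 on
#' Fisher-z edges.
#'
#' @param design_path path to the design TSV.
#' @param timeseries_dir directory of per-subject `<subject>_ts.tsv` files.
#' @param motion_dir directory of per-subject `rp_<subject>.txt` traces
#'   (`NULL` skips motion QC).
#' @param output_dir directory for all result tables.
#' @param node_table_path node/parcellation TSV (`NULL` = the packaged
#'   90-region table).
#' @param s_min,s_max,s_step sparsity grid.
#' @param band_low,band_high pass band in Hz.
#' @param discard_volumes initial volumes to drop.
#' @param tr repetition time in seconds.
#' @param max_translation_mm,max_rotation_deg motion exclusion limits.
#' @param rotation_units units of the motion-file rotation columns.
#' @param n_perm permutations for all permutation tests.
#' @param seed integer seed (mandatory, drives every random draw).
#' @param fdr_q FDR level for nodal inference.
#' @param nbs_t_primary,nbs_transform,nbs_direction NBS settings;
#'   `nbs_direction` may name several one-sided runs.
#' @param contrasts list of group-label pairs for pairwise tests and NBS
#'   (`NULL` = all pairs found in the design).
#' @param infer_thresholds sparsity levels at which nodal inference runs
#'   (`NULL` = the full grid; the study reports nodal tables at 0.35).
#' @return a `run_config` list.
#' @export
run_config <- function(design_path, timeseries_dir, motion_dir = NULL,
                       output_dir, node_table_path = NULL,
                       s_min = 0.10, s_max = 0.50, s_step = 0.01,
                       band_low = 0.01, band_high = 0.08,
                       discard_volumes = 10, tr = 2,
                       max_translation_mm = 2, max_rotation_deg = 2,
                       rotation_units = "rad",
                       n_perm = 10000, seed = NULL, fdr_q = 0.05,
                       nbs_t_primary = 3.40, nbs_transform = "fisher_z",
                       nbs_direction = c("greater", "less"),
                       contrasts = NULL, infer_thresholds = 0.35) {
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  cfg <- list(design_path = design_path, timeseries_dir = timeseries_dir,
              motion_dir = motion_dir, output_dir = output_dir,
              node_table_path = node_table_path,
              s_min = s_min, s_max = s_max, s_step = s_step,
              band_low = band_low, band_high = band_high,
              discard_volumes = discard_volumes, tr = tr,
              max_translation_mm = max_translation_mm,
              max_rotation_deg = max_rotation_deg,
              rotation_units = rotation_units,
              n_perm = n_perm, seed = as.integer(seed), fdr_q = fdr_q,
              nbs_t_primary = nbs_t_primary, nbs_transform = nbs_transform,
              nbs_direction = nbs_direction, contrasts = contrasts,
              infer_thresholds = infer_thresholds)
  validate_config(cfg)
}

#' @rdname run_config
#' @param cfg a configuration list to validate.
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$s_min > 0, cfg$s_max <= 1, cfg$s_min <= cfg$s_max,
            cfg$s_step > 0, cfg$band_low > 0,
            cfg$band_high < 1 / (2 * cfg$tr),
            cfg$band_low < cfg$band_high,
            cfg$n_perm >= 1, cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$nbs_t_primary > 0,
            cfg$max_translation_mm > 0, cfg$max_rotation_deg > 0)
  if (!cfg$rotation_units %in% c("rad", "deg"))
    stop("rotation_units must be 'rad' or 'deg'", call. = FALSE)
  if (!all(cfg$nbs_direction %in% c("greater", "less", "two_sided")))
    stop("unknown NBS direction", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Flat key-value YAML; keys match the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full group-comparison pipeline
#'
#' Stages: load design and node table; motion QC (excluded subjects are
#' logged, a group collapsing below 2 subjects aborts the run); preprocess
#' time series (discard, detrend, band-pass); Pearson connectivity with
#' negative clipping; nested sparsity sweep; graph metrics; demographics
#' report; global and nodal permutation inference with FDR; NBS per
#' contrast and direction. All tables are written under
#' `cfg$output_dir` together with a run log carrying the config hash.
#'
#' @param cfg a [run_config()] object.
#' @param cache_connectivity reuse matrices found in
#'   `output_dir/connectivity/` instead of recomputing them.
#' @return (invisibly) a list with every result table.
#' @export
run_pipeline <- function(cfg, cache_connectivity = FALSE) {
  cfg <- validate_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  hash <- config_hash(cfg)
  log_msg("run_pipeline start: config hash %s, seed %d", hash, cfg$seed)

  design <- load_design(cfg$design_path)
  node_table <- if (is.null(cfg$node_table_path)) aal90_node_table() else
    load_node_table(cfg$node_table_path)
  log_msg("design: %d subjects in groups [%s]; node table: %d regions",
          nrow(design), paste(levels(design$group), collapse = ", "),
          nrow(node_table))

  # ---- motion QC ----
  if (!is.null(cfg$motion_dir)) {
    keep <- vapply(design$subject_id, function(sid) {
      path <- file.path(cfg$motion_dir, paste0("rp_", sid, ".txt"))
      if (!file.exists(path))
        stop("missing motion file for subject ", sid, call. = FALSE)
      mo <- read_motion_trace(path, sid, cfg$rotation_units)
      qc <- qc_motion(mo, cfg$max_translation_mm, cfg$max_rotation_deg)
      if (qc$decision == "exclude")
        log_msg("exclude %s: |%s| = %.3g %s at volume %d", sid,
                qc$offending$axis[1], qc$offending$value[1],
                qc$offending$unit[1], qc$offending$volume[1])
      qc$decision == "keep"
    }, TRUE)
    design <- design[keep, , drop = FALSE]
    design$group <- droplevels(design$group)
    if (any(table(design$group) < 2))
      stop("a group collapsed below 2 subjects after motion QC", call. = FALSE)
    log_msg("motion QC: %d subjects retained", nrow(design))
  }
  design <- validate_cohort_design(design)

  # ---- connectivity ----
  conn_dir <- file.path(out_dir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  connectomes <- lapply(design$subject_id, function(sid) {
    cache <- file.path(conn_dir, paste0(sid, "_conn.txt"))
    if (cache_connectivity && file.exists(cache))
      return(read_connectivity(cache, sid, clipped = FALSE))
    path <- file.path(cfg$timeseries_dir, paste0(sid, "_ts.tsv"))
    if (!file.exists(path))
      stop("missing time-series file for subject ", sid, call. = FALSE)
    ts <- read_timeseries_tsv(path, sid, cfg$tr)
    ts <- preprocess_timeseries(ts, cfg$discard_volumes,
                                c(cfg$band_low, cfg$band_high))
    C <- correlation_matrix(ts)
    write_connectivity(C, cache)
    C
  })
  names(connectomes) <- design$subject_id
  log_msg("connectivity: %d matrices of %d x %d", length(connectomes),
          nrow(connectomes[[1]]$values), ncol(connectomes[[1]]$values))

  # ---- sparsity sweep and metrics ----
  stacks <- lapply(connectomes, function(C)
    threshold_sweep(clip_negative(C), cfg$s_min, cfg$s_max, cfg$s_step))
  metrics <- metrics_for_cohort(stacks)
  write_metric_table(metrics, file.path(out_dir, "metrics.tsv"))
  log_msg("metrics: %d thresholds, %d records",
          length(stacks[[1]]$thresholds), nrow(metrics))

  # ---- demographics ----
  demo <- demographics_report(design)
  utils::write.table(demo, file.path(out_dir, "demographics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- inference ----
  glob <- global_inference(metrics, design, n_perm = cfg$n_perm,
                           seed = cfg$seed, q = cfg$fdr_q)
  utils::write.table(glob, file.path(out_dir, "global_inference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodal <- nodal_inference(metrics, design, n_perm = cfg$n_perm,
                           seed = cfg$seed, q = cfg$fdr_q,
                           thresholds = cfg$infer_thresholds)
  n_nodes <- max(nodal$node) + 1L
  if (n_nodes != nrow(node_table))
    log_msg("note: %d regions in the data but %d in the node table; check node_table_path",
            n_nodes, nrow(node_table))
  nodal$region <- node_table$name[nodal$node + 1L]
  utils::write.table(nodal, file.path(out_dir, "nodal_inference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("inference: %d global rows, %d nodal rows", nrow(glob), nrow(nodal))

  # ---- NBS ----
  contrasts <- cfg$contrasts %||% combn(levels(design$group), 2,
                                        simplify = FALSE)
  nbs_results <- list()
  for (ct in contrasts) for (dir_k in cfg$nbs_direction) {
    res <- nbs_test(connectomes, design$group, unlist(ct),
                    t_primary = cfg$nbs_t_primary, n_perm = cfg$n_perm,
                    seed = cfg$seed, transform = cfg$nbs_transform,
                    direction = dir_k)
    write_nbs_result(res, file.path(out_dir, "nbs"))
    key <- paste0(paste(unlist(ct), collapse = "-"), "_", dir_k)
    nbs_results[[key]] <- res
    log_msg("NBS %s: %d component(s)%s", key, length(res$components),
            if (length(res$components))
              sprintf(", smallest FWER p = %.4g",
                      min(vapply(res$components, `[[`, 0.0, "fwer_p")))
            else "")
  }

  log_msg("run_pipeline done")
  writeLines(c(paste0("# config hash: ", hash), log_lines),
             file.path(out_dir, "run_log.txt"))
  invisible(list(design = design, node_table = node_table,
                 metrics = metrics, demographics = demo,
                 global_inference = glob, nodal_inference = nodal,
                 nbs = nbs_results, log = log_lines, config_hash = hash))
}
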