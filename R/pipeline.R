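#' Pipeline configuration
#'
#' Bundles every tunable of the analysis: motion QC thresholds, backbone
#' target degree, null-model settings, statistical options and the master
#' seed.
#'
#' @param qc A [qc_thresholds()].
#' @param backbone A [backbone_config()].
#' @param ensemble_size Rewired networks per subject for the small-world
#'   assessment (default 100).
#' @param n_swap_per_edge Attempted swaps per edge when rewiring
#'   (default 10).
#' @param small_world_margin Threshold on the local-efficiency ratio
#'   (default 1).
#' @param run_null_models Compute the rewired-ensemble small-world
#'   assessment per subject (default `TRUE`; the slowest stage).
#' @param var_equal Pooled-variance t-tests if `TRUE` (default), Welch
#'   otherwise.
#' @param p_adjust Multiple-testing adjustment (default `"none"`,
#'   uncorrected).
#' @param alpha Significance level used for reporting and for selecting
#'   features for onset-age correlations (default 0.05).
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            backbone = backbone_config(),
                            ensemble_size = 100L,
                            n_swap_per_edge = 10,
                            small_world_margin = 1,
                            run_null_models = TRUE,
                            var_equal = TRUE,
                            p_adjust = "none",
                            alpha = 0.05,
                            seed = 1L) {
  if (!inherits(qc, "qc_thresholds")) stop("`qc` must be qc_thresholds")
  if (!inherits(backbone, "backbone_config"))
    stop("`backbone` must be backbone_config")
  if (!.is_count(ensemble_size))
    .stop_field("ensemble_size", "must be a positive integer")
  structure(list(qc = qc, backbone = backbone,
                 ensemble_size = as.integer(ensemble_size),
                 n_swap_per_edge = n_swap_per_edge,
                 small_world_margin = small_world_margin,
                 run_null_models = isTRUE(run_null_models),
                 var_equal = isTRUE(var_equal), p_adjust = p_adjust,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file with any subset of the fields of
#' [pipeline_config()]; QC thresholds and backbone degree may be given as
#' `qc: {max_translation, max_rotation}` and `backbone: {k}`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$qc))
    args$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$backbone))
    args$backbone <- do.call(backbone_config, y$backbone)
  for (f in c("ensemble_size", "n_swap_per_edge", "small_world_margin",
              "run_null_models", "var_equal", "p_adjust", "alpha", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(pipeline_config, args)
}

#' @noRd
.stage <- function(name, detail, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed (%s): %s", name, detail,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full structural-network group analysis
#'
#' Executes, in order: motion QC screening (scans exceeding the thresholds
#' are dropped; subjects with no surviving scan are excluded with a logged
#' warning), voxel-normalized weight matrices per surviving scan, per-subject
#' averaging, backbone extraction, nodal and global graph metrics, the
#' rewired-ensemble small-world assessment, and two-group comparisons of
#' nodal and global features. For nodal features significant at `alpha`, the
#' correlation with training-onset age is computed within the musician
#' group. A run log records parameters, seeds and every exclusion.
#'
#' When both `"musician"` and `"control"` group labels are present, the
#' musician group is group 1, so positive `T` means musician > control.
#'
#' @param cohort A `tract_cohort` (from [generate_cohort()] or
#'   [read_cohort()]), or a path to a manifest CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage's output is
#'   written there (CSV/JSON/delimited text, no timestamps, so a fixed seed
#'   gives byte-identical bundles).
#' @return An object of class `connectome_study`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(cohort))
    cohort <- .stage("read", cohort, read_cohort(cohort))
  if (!inherits(cohort, "tract_cohort"))
    stop("`cohort` must be a tract_cohort or a manifest path", call. = FALSE)
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config object", call. = FALSE)
  log <- c(sprintf("config: seed=%d k=%g qc=%.3gmm/%.3gdeg ensemble=%d swaps/edge=%g",
                   config$seed, config$backbone$k,
                   config$qc$max_translation, config$qc$max_rotation,
                   config$ensemble_size, config$n_swap_per_edge))

  # -- stage 1: motion QC ---------------------------------------------------
  qc_rows <- list()
  kept_subjects <- list()
  for (sub in cohort$subjects) {
    survivors <- list()
    for (scan in sub$scans) {
      dec <- .stage("qc", sprintf("%s scan %d", sub$subject_id,
                                  scan$motion$scan_id),
                    screen_motion(scan$motion, config$qc))
      qc_rows[[length(qc_rows) + 1L]] <-
        data.frame(subject_id = sub$subject_id,
                   scan_id = scan$motion$scan_id, keep = dec$keep,
                   reason = if (dec$keep) "" else dec$reason,
                   max_translation = dec$max_translation,
                   max_rotation = dec$max_rotation,
                   stringsAsFactors = FALSE)
      if (dec$keep) survivors[[length(survivors) + 1L]] <- scan
      else log <- c(log, sprintf("qc: excluded %s scan %d (%s)",
                                 sub$subject_id, scan$motion$scan_id,
                                 dec$reason))
    }
    if (length(survivors)) {
      sub$scans <- survivors
      kept_subjects[[length(kept_subjects) + 1L]] <- sub
    } else {
      msg <- sprintf("subject %s excluded: no scan passed motion QC",
                     sub$subject_id)
      warning(msg)
      log <- c(log, paste("qc:", msg))
    }
  }
  qc_table <- do.call(rbind, qc_rows)
  if (length(kept_subjects) < 4L)
    stop("fewer than 4 subjects survived QC; cannot compare groups",
         call. = FALSE)

  groups_chr <- vapply(kept_subjects, `[[`, "", "group")
  lev <- if (all(c("musician", "control") %in% groups_chr))
    c("musician", "control") else unique(groups_chr)
  groups <- factor(groups_chr, levels = lev)

  # -- stages 2-4: networks, backbone, metrics ------------------------------
  backbones <- vector("list", length(kept_subjects))
  nodal <- vector("list", length(kept_subjects))
  globals <- vector("list", length(kept_subjects))
  sw <- vector("list", length(kept_subjects))
  for (s in seq_along(kept_subjects)) {
    sub <- kept_subjects[[s]]
    nets <- lapply(sub$scans, function(scan)
      .stage("weight-matrix", sub$subject_id,
             build_weight_matrix(scan$counts)))
    avg <- .stage("average", sub$subject_id, average_networks(nets))
    bb <- .stage("backbone", sub$subject_id,
                 extract_backbone(avg, config$backbone))
    backbones[[s]] <- bb
    sp <- shortest_paths(bb)
    nodal[[s]] <- .stage("metrics", sub$subject_id, nodal_metrics(bb, sp))
    gm <- .stage("metrics", sub$subject_id, global_metrics(bb, sp))
    if (config$run_null_models) {
      res <- .stage("null-models", sub$subject_id,
                    small_world_assessment(
                      bb, ensemble_size = config$ensemble_size,
                      n_swap_per_edge = config$n_swap_per_edge,
                      margin = config$small_world_margin,
                      seed = .substream_seed(config$seed, "smallworld",
                                             sub$subject_id)))
      sw[[s]] <- res
      globals[[s]] <- c(unclass(gm), list(eloc_ratio = res$eloc_ratio,
                                          eglob_ratio = res$eglob_ratio))
    } else {
      globals[[s]] <- unclass(gm)
    }
  }
  log <- c(log, sprintf("networks: %d subjects analyzed (%s)",
                        length(kept_subjects),
                        paste(sprintf("%d %s", table(groups), levels(groups)),
                              collapse = ", ")))

  # -- stage 5: group statistics --------------------------------------------
  cmp_nodal <- .stage("group-stats", "nodal",
                      compare_nodal_metrics(nodal, groups,
                                            var_equal = config$var_equal,
                                            p_adjust = config$p_adjust))
  cmp_global <- .stage("group-stats", "global",
                       compare_global_metrics(globals, groups,
                                              var_equal = config$var_equal,
                                              p_adjust = config$p_adjust))

  # -- stage 6: onset-age correlations for significant nodal features -------
  onset <- vapply(kept_subjects, `[[`, 0, "onset_age")
  mus <- groups_chr == "musician" & is.finite(onset)
  correlations <- NULL
  sig <- which(!is.na(cmp_nodal$p) & cmp_nodal$p < config$alpha)
  if (sum(mus) >= 3L && length(sig)) {
    rows <- lapply(sig, function(r) {
      met <- cmp_nodal$feature[r]
      nodelab <- cmp_nodal$node[r]
      v <- vapply(nodal[mus], function(tb) tb[[met]][tb$label == nodelab], 0)
      ct <- tryCatch(correlate_onset(v, onset[mus]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n = sum(mus)))
      data.frame(feature = met, node = nodelab, r = ct$r, p = ct$p,
                 n = ct$n, stringsAsFactors = FALSE)
    })
    correlations <- do.call(rbind, rows)
  }

  study <- structure(list(
    config = config, qc = qc_table, groups = groups,
    subject_ids = vapply(kept_subjects, `[[`, "", "subject_id"),
    onset_ages = onset, backbones = backbones, nodal_metrics = nodal,
    global_metrics = globals, small_world = sw,
    comparison_nodal = cmp_nodal, comparison_global = cmp_global,
    onset_correlations = correlations, log = log),
    class = "connectome_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Write a study's report bundle to disk
#'
#' Writes QC decisions, per-subject backbone matrices, nodal metric tables,
#' global metrics and small-world results (JSON), both comparison tables,
#' onset correlations and the run log. All files are plain text without
#' timestamps: re-running with the same seed reproduces the bundle
#' byte-for-byte.
#'
#' @param study A `connectome_study`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  if (!inherits(study, "connectome_study"))
    stop("`study` must be a connectome_study object", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
  utils::write.csv(study$qc, file.path(out_dir, "qc.csv"),
                   row.names = FALSE)
  for (s in seq_along(study$subject_ids)) {
    write_matrix(study$backbones[[s]],
                 file.path(out_dir, "networks",
                           sprintf("%s_backbone.txt", study$subject_ids[s])))
    utils::write.csv(study$nodal_metrics[[s]],
                     file.path(out_dir, "networks",
                               sprintf("%s_nodal.csv", study$subject_ids[s])),
                     row.names = FALSE)
  }
  glob <- lapply(seq_along(study$subject_ids), function(s)
    c(list(subject_id = study$subject_ids[s],
           group = as.character(study$groups[s])),
      study$global_metrics[[s]]))
  jsonlite::write_json(glob, file.path(out_dir, "global_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (any(!vapply(study$small_world, is.null, TRUE))) {
    swl <- lapply(seq_along(study$subject_ids), function(s)
      c(list(subject_id = study$subject_ids[s]),
        unclass(study$small_world[[s]])))
    jsonlite::write_json(swl, file.path(out_dir, "small_world.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  utils::write.csv(study$comparison_nodal,
                   file.path(out_dir, "report_nodal.csv"), row.names = FALSE)
  utils::write.csv(study$comparison_global,
                   file.path(out_dir, "report_global.csv"), row.names = FALSE)
  if (!is.null(study$onset_correlations))
    utils::write.csv(study$onset_correlations,
                     file.path(out_dir, "onset_correlations.csv"),
                     row.names = FALSE)
  writeLines(study$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.connectome_study <- function(x, ...) {
  cat("Structural-network group analysis\n")
  cat(sprintf("  %d subjects (%s), %d excluded scan(s)\n",
              length(x$subject_ids),
              paste(sprintf("%d %s", table(x$groups), levels(x$groups)),
                    collapse = ", "),
              sum(!x$qc$keep)))
  if (any(!vapply(x$small_world, is.null, TRUE))) {
    elr <- vapply(x$small_world, `[[`, 0, "eloc_ratio")
    egr <- vapply(x$small_world, `[[`, 0, "eglob_ratio")
    cat(sprintf("  small-world: mean E_loc ratio %.3g, mean E_glob ratio %.3g (%d/%d subjects classified small-world)\n",
                mean(elr), mean(egr),
                sum(vapply(x$small_world, `[[`, TRUE, "is_small_world")),
                length(x$small_world)))
  }
  nsig <- sum(!is.na(x$comparison_nodal$p) &
                x$comparison_nodal$p < x$config$alpha)
  cat(sprintf("  nodal features with p < %.3g (uncorrected): %d of %d\n",
              x$config$alpha, nsig, nrow(x$comparison_nodal)))
  invisible(x)
}

#' @export
summary.connectome_study <- function(object, ...) {
  print(object)
  cat("\nNodal comparison:\n")
  print(object$comparison_nodal, alpha = object$config$alpha)
  cat("\nGlobal comparison:\n")
  gl <- object$comparison_global
  gl$T <- round(gl$T, 2)
  gl$p <- signif(gl$p, 3)
  print.data.frame(gl, row.names = FALSE)
  if (!is.null(object$onset_correlations)) {
    cat("\nOnset-age correlations (musicians, significant nodal features):\n")
    oc <- object$onset_correlations
    oc$r <- round(oc$r, 3)
    oc$p <- signif(oc$p, 3)
    print.data.frame(oc, row.names = FALSE)
  }
  invisible(object)
}
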