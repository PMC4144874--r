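#' Specification of a synthetic two-group tractography cohort
#'
#' Describes the study design emulated by [generate_cohort()]: two groups of
#' subjects (controls and musicians), each scanned one to three times, with
#' directed streamline-count matrices over a fixed parcellation. Counts are
#' overdispersed (negative binomial) around an expected-count matrix whose
#' support and magnitude decay with inter-regional distance; a group effect is
#' injected as a multiplicative increase of expected counts on all edges
#' incident to chosen nodes in the second group.
#'
#' @param n_per_group Subjects per group (default 16, the study design).
#' @param n_nodes Number of parcellation regions (default 90).
#' @param n_scans Repeated acquisitions per subject, 1--3 (default 3).
#' @param base_density Expected fraction of node pairs with a structural
#'   connection, in `[0, 1]` (default 0.3).
#' @param mean_count Expected directed streamline count on a present
#'   connection (default 100).
#' @param dispersion Negative-binomial size parameter; counts have variance
#'   `mu + mu^2 / dispersion`, so smaller values mean more overdispersion
#'   (default 5).
#' @param voxel_range Integer interval for region voxel counts
#'   (default `c(400, 4000)`).
#' @param effect_nodes Character vector of node labels receiving the group
#'   effect (default none).
#' @param effect_multiplier Multiplier applied to expected counts of edges
#'   incident to `effect_nodes` in group 2 ("musician"); 1 means the two
#'   groups are drawn from identical distributions (default 1). Either a
#'   scalar or one value per effect node (an edge joining two effect nodes
#'   gets the larger of the two).
#' @param motion_sd Per-volume increment scale of the rigid-body motion
#'   random walk, in mm and degrees (default 0.05).
#' @param qc_fail_rate Fraction of scans forced to exceed the motion QC
#'   thresholds, to exercise exclusion logic (default 0).
#' @param onset_age_range Interval (years) for musicians' training-onset
#'   ages, drawn uniformly (default `c(4, 12)`).
#' @param mask_type `"distance"` (default) for a spatially embedded mask in
#'   which connection probability and expected count decay with
#'   inter-regional distance, or `"erdos-renyi"` for a flat random mask.
#' @param distance_decay Length scale (unit-box coordinates) of the
#'   exponential distance decay (default 0.25); ignored for
#'   `mask_type = "erdos-renyi"`.
#' @param labels Node labels; defaults to the 90 AAL abbreviations when
#'   `n_nodes = 90`, else `R001, R002, ...`.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @param geometry_seed Optional integer seed for the cohort-level template
#'   structure (node coordinates, connection mask, expected counts, voxel
#'   counts). Defaults to `seed`. Giving several cohorts the same
#'   `geometry_seed` but different `seed`s emulates replicate studies of
#'   the same population template with fresh subjects.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [expected_weight_matrix()]
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = 4, n_nodes = 20, seed = 1)
#' spec
cohort_spec <- function(n_per_group = 16L,
                        n_nodes = 90L,
                        n_scans = 3L,
                        base_density = 0.3,
                        mean_count = 100,
                        dispersion = 5,
                        voxel_range = c(400L, 4000L),
                        effect_nodes = character(0),
                        effect_multiplier = 1,
                        motion_sd = 0.05,
                        qc_fail_rate = 0,
                        onset_age_range = c(4, 12),
                        mask_type = c("distance", "erdos-renyi"),
                        distance_decay = 0.25,
                        labels = NULL,
                        seed = 1L,
                        geometry_seed = NULL) {
  mask_type <- match.arg(mask_type)
  if (!.is_count(n_per_group) || n_per_group < 2)
    .stop_field("n_per_group", "must be an integer >= 2")
  if (!.is_count(n_nodes) || n_nodes < 3)
    .stop_field("n_nodes", "must be an integer >= 3")
  if (!.is_count(n_scans) || !(n_scans %in% 1:3))
    .stop_field("n_scans", "must be 1, 2 or 3")
  if (!.is_number(base_density) || base_density < 0 || base_density > 1)
    .stop_field("base_density", "must be a fraction in [0, 1]")
  if (!.is_number(mean_count) || mean_count <= 0)
    .stop_field("mean_count", "must be a positive real")
  if (!.is_number(dispersion) || dispersion <= 0)
    .stop_field("dispersion", "must be a positive real")
  if (length(voxel_range) != 2L || any(!is.finite(voxel_range)) ||
      voxel_range[1] < 1 || voxel_range[2] < voxel_range[1])
    .stop_field("voxel_range", "must be an increasing positive integer interval")
  if (!is.numeric(effect_multiplier) || any(!is.finite(effect_multiplier)) ||
      any(effect_multiplier <= 0) ||
      !(length(effect_multiplier) %in% c(1L, length(effect_nodes))))
    .stop_field("effect_multiplier",
                "must be positive, scalar or one value per effect node")
  if (!.is_number(motion_sd) || motion_sd < 0)
    .stop_field("motion_sd", "must be a non-negative real")
  if (!.is_number(qc_fail_rate) || qc_fail_rate < 0 || qc_fail_rate > 1)
    .stop_field("qc_fail_rate", "must be a fraction in [0, 1]")
  if (length(onset_age_range) != 2L || any(!is.finite(onset_age_range)) ||
      onset_age_range[2] < onset_age_range[1])
    .stop_field("onset_age_range", "must be an increasing real interval")
  if (!.is_number(distance_decay) || distance_decay <= 0)
    .stop_field("distance_decay", "must be a positive real")
  if (is.null(labels)) labels <- .default_labels(as.integer(n_nodes))
  labels <- as.character(labels)
  if (length(labels) != n_nodes || anyDuplicated(labels))
    .stop_field("labels", "must be n_nodes unique node labels")
  effect_nodes <- as.character(effect_nodes)
  if (!all(effect_nodes %in% labels))
    .stop_field("effect_nodes",
                paste("unknown node label(s):",
                      paste(setdiff(effect_nodes, labels), collapse = ", ")))
  if (!.is_count(abs(seed) + 1))
    .stop_field("seed", "must be a finite integer")
  if (is.null(geometry_seed)) geometry_seed <- seed
  if (!.is_count(abs(geometry_seed) + 1))
    .stop_field("geometry_seed", "must be a finite integer")
  structure(list(
    n_per_group = as.integer(n_per_group),
    n_nodes = as.integer(n_nodes),
    n_scans = as.integer(n_scans),
    base_density = base_density,
    mean_count = mean_count,
    dispersion = dispersion,
    voxel_range = as.integer(round(voxel_range)),
    effect_nodes = effect_nodes,
    effect_multiplier = as.numeric(effect_multiplier),
    motion_sd = motion_sd,
    qc_fail_rate = qc_fail_rate,
    onset_age_range = as.numeric(onset_age_range),
    mask_type = mask_type,
    distance_decay = distance_decay,
    labels = labels,
    seed = as.integer(seed),
    geometry_seed = as.integer(geometry_seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d subjects/group, %d nodes, %d scan(s)/subject\n",
              x$n_per_group, x$n_nodes, x$n_scans))
  cat(sprintf("  density %.2f (%s mask), mean count %g, dispersion %g\n",
              x$base_density, x$mask_type, x$mean_count, x$dispersion))
  if (length(x$effect_nodes))
    cat(sprintf("  effect: x%s at %s\n",
                paste(signif(x$effect_multiplier, 3), collapse = "/"),
                paste(x$effect_nodes, collapse = ", ")))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
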