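#' Directed streamline-count data for one scan
#'
#' Container for the raw output of probabilistic tractography at the
#' count-matrix level: entry `(i, j)` is the number of sampled streamlines
#' seeded in region `i` that reached region `j`, together with the number of
#' seed voxels per region. Self-connections (the diagonal) are excluded from
#' all downstream weights.
#'
#' @param counts N x N non-negative integer matrix of directed streamline
#'   counts.
#' @param voxels Length-N strictly positive integer vector of seed-voxel
#'   counts per region.
#' @param subject_id,scan_id Identifiers.
#' @param labels Optional node labels (defaults to the dimnames of `counts`).
#' @return An object of class `tract_counts`.
#' @export
tract_counts <- function(counts, voxels, subject_id = "sub", scan_id = 1L,
                         labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    .stop_field("counts", "must be a square matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    .stop_field("counts", "must be finite and non-negative")
  if (length(voxels) != nrow(counts))
    .stop_field("voxels", "length must equal the matrix dimension")
  if (any(!is.finite(voxels)) || any(voxels <= 0))
    .stop_field("voxels", "must be strictly positive")
  if (is.null(labels)) labels <- rownames(counts)
  if (is.null(labels)) labels <- .default_labels(nrow(counts))
  dimnames(counts) <- list(labels, labels)
  structure(list(counts = counts, voxels = as.numeric(voxels),
                 subject_id = as.character(subject_id),
                 scan_id = as.integer(scan_id), labels = labels),
            class = "tract_counts")
}

#' Rigid-body head-motion parameters for one scan
#'
#' Six parameters per acquired volume: three translations (mm) and three
#' rotations (degrees), in the column layout of FSL/SPM realignment `.par`
#' files.
#'
#' @param params Matrix with one row per volume and 6 columns
#'   (trans_x, trans_y, trans_z, rot_x, rot_y, rot_z).
#' @param subject_id,scan_id Identifiers.
#' @return An object of class `motion_log`.
#' @export
motion_log <- function(params, subject_id = "sub", scan_id = 1L) {
  params <- as.matrix(params)
  if (nrow(params) < 1L)
    .stop_field("params", "must contain at least one volume")
  if (ncol(params) != 6L)
    .stop_field("params", "must have 6 columns (3 translations, 3 rotations)")
  if (any(!is.finite(params)))
    .stop_field("params", "must be finite")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(list(params = params, subject_id = as.character(subject_id),
                 scan_id = as.integer(scan_id)),
            class = "motion_log")
}

# Cohort-level latent structure: node coordinates, connection mask,
# expected-count matrix and region voxel counts. Deterministic given the
# spec. The mask is redrawn (bounded retries) until its positive graph is
# connected, since per-subject structural networks are connected in practice
# and backbone extraction requires it.
#' @noRd
.cohort_geometry <- function(spec) {
  n <- spec$n_nodes
  .with_seed(.substream_seed(spec$geometry_seed, "geometry"), {
    # mirrored hemisphere coordinates: consecutive (L, R) pairs share a
    # template position reflected through the midline x = 0
    npair <- n %/% 2L
    base <- cbind(stats::runif(npair, 0.1, 1), stats::runif(npair),
                  stats::runif(npair))
    coords <- matrix(0, n, 3L)
    coords[2L * seq_len(npair) - 1L, ] <- cbind(-base[, 1], base[, 2:3])
    coords[2L * seq_len(npair), ] <- base
    if (n %% 2L == 1L)
      coords[n, ] <- c(0, stats::runif(1), stats::runif(1))
    rownames(coords) <- spec$labels
    D <- as.matrix(stats::dist(coords))

    off <- upper.tri(D)
    if (spec$mask_type == "distance") {
      e <- exp(-D / spec$distance_decay)
      if (spec$base_density > 0) {
        f <- function(cc) mean(pmin(1, cc * e[off])) - spec$base_density
        cc <- if (f(1 / max(e[off])) >= 0) 1 / max(e[off]) else
          stats::uniroot(f, c(1e-12, 1e12), tol = 1e-12)$root
        p <- pmin(cc * e, 1)
      } else p <- matrix(0, n, n)
      mu <- spec$mean_count * e / (sum(p[off] * e[off]) / max(sum(p[off]), 1e-12))
      if (spec$base_density == 0) mu <- matrix(0, n, n)
    } else {
      p <- matrix(spec$base_density, n, n)
      mu <- matrix(spec$mean_count, n, n)
    }
    diag(p) <- 0

    mask <- matrix(FALSE, n, n)
    if (spec$base_density > 0) {
      for (try in seq_len(100L)) {
        draw <- stats::runif(sum(off)) < p[off]
        mask[off] <- draw
        mask <- mask | t(mask)
        if (max(.components(mask * 1)) == 1L) break
        if (try == 100L)
          warning("connection mask remained disconnected after 100 redraws")
        mask[] <- FALSE
      }
    }

    voxels <- sample(seq(spec$voxel_range[1], spec$voxel_range[2]), n,
                     replace = TRUE)
    list(coords = coords, p = p, mu = mu, mask = mask, voxels = voxels)
  })
}

# Multiplier matrix for the injected group effect: an edge incident to one
# effect node is scaled by that node's multiplier; an edge joining two
# effect nodes is scaled once, by the larger of the two (never compounded).
#' @noRd
.effect_matrix <- function(spec) {
  n <- spec$n_nodes
  mv <- rep(1, n)
  idx <- match(spec$effect_nodes, spec$labels)
  if (length(idx)) mv[idx] <- spec$effect_multiplier
  eff <- seq_len(n) %in% idx
  Mi <- matrix(mv, n, n)  # column-filled: Mi[i, j] = mv[i]
  Mj <- t(Mi)
  Ei <- matrix(eff, n, n)
  Ej <- t(Ei)
  m <- matrix(1, n, n)
  m[Ei & !Ej] <- Mi[Ei & !Ej]
  m[!Ei & Ej] <- Mj[!Ei & Ej]
  m[Ei & Ej] <- pmax(Mi, Mj)[Ei & Ej]
  diag(m) <- 1
  m
}

#' Generate a synthetic two-group tractography cohort
#'
#' Draws a cohort of control and musician subjects under the design described
#' by [cohort_spec()]: a shared spatially embedded connection mask and
#' expected-count matrix, per-subject-and-scan directed streamline counts
#' (negative binomial, overdispersed), region voxel counts, per-scan
#' rigid-body motion logs (cumulative Gaussian random walks), and uniform
#' training-onset ages for the musician group. The group effect multiplies
#' expected counts on edges incident to `effect_nodes` for musicians.
#'
#' The cohort is a deterministic function of the spec (including its seed);
#' each subject and scan uses its own derived random stream, so subsets are
#' reproducible.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `tract_cohort`: a list with elements `spec`,
#'   `geometry` (latent coordinates, mask, expected counts, voxels) and
#'   `subjects`, a list of records with `subject_id`, `group`
#'   (`"control"` or `"musician"`), `onset_age` (`NA` for controls) and
#'   `scans`, a list of `(counts, motion)` pairs.
#' @seealso [expected_weight_matrix()], [write_cohort()]
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 3, n_nodes = 12, seed = 7))
#' coh
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must be a cohort_spec object", call. = FALSE)
  geom <- .cohort_geometry(spec)
  n <- spec$n_nodes
  eff <- .effect_matrix(spec)
  n_volumes <- 21L  # one b0 plus 20 diffusion-weighted volumes

  subjects <- vector("list", 2L * spec$n_per_group)
  k <- 0L
  for (g in c("control", "musician")) {
    for (s in seq_len(spec$n_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s%02d", if (g == "control") "ctrl" else "mus", s)
      onset <- if (g == "musician") {
        .with_seed(.substream_seed(spec$seed, "onset", g, s),
                   stats::runif(1, spec$onset_age_range[1],
                                spec$onset_age_range[2]))
      } else NA_real_
      mu <- geom$mu * (if (g == "musician") eff else 1)
      scans <- vector("list", spec$n_scans)
      for (sc in seq_len(spec$n_scans)) {
        counts <- .with_seed(.substream_seed(spec$seed, "counts", g, s, sc), {
          cm <- matrix(0, n, n)
          idx <- which(geom$mask & upper.tri(geom$mask))
          if (length(idx)) {
            muv <- mu[idx]
            # directions i->j and j->i drawn independently around the same mean
            cm[idx] <- stats::rnbinom(length(idx), size = spec$dispersion,
                                      mu = muv)
            rev <- matrix(0, n, n)
            rev[idx] <- stats::rnbinom(length(idx), size = spec$dispersion,
                                       mu = muv)
            cm <- cm + t(rev)
          }
          cm
        })
        motion <- .with_seed(.substream_seed(spec$seed, "motion", g, s, sc), {
          inc <- matrix(stats::rnorm(n_volumes * 6L, sd = spec$motion_sd),
                        n_volumes, 6L)
          walk <- apply(inc, 2L, cumsum)
          if (spec$qc_fail_rate > 0 &&
              stats::runif(1) < spec$qc_fail_rate) {
            # force a clear threshold violation on one translation axis
            walk[sample.int(n_volumes, 1L), 1L] <- 1.5
          }
          walk
        })
        scans[[sc]] <- list(
          counts = tract_counts(counts, geom$voxels, subject_id = sid,
                                scan_id = sc, labels = spec$labels),
          motion = motion_log(motion, subject_id = sid, scan_id = sc))
      }
      subjects[[k]] <- list(subject_id = sid, group = g, onset_age = onset,
                            scans = scans)
    }
  }
  structure(list(spec = spec, geometry = geom, subjects = subjects),
            class = "tract_cohort")
}

#' @export
print.tract_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("Synthetic tractography cohort: %d subjects (%s), %d nodes, %d scan(s)\n",
              length(x$subjects),
              paste(sprintf("%d %s", table(groups), names(table(groups))),
                    collapse = ", "),
              x$spec$n_nodes, x$spec$n_scans))
  cat(sprintf("  connection mask: %d edges (density %.3f)\n",
              sum(x$geometry$mask) / 2,
              sum(x$geometry$mask) / (x$spec$n_nodes * (x$spec$n_nodes - 1))))
  invisible(x)
}

#' Analytic expectation of a group's averaged weight matrix
#'
#' Returns the expected symmetric connection-weight matrix produced by
#' [build_weight_matrix()] (and unchanged by scan averaging) for one group of
#' a synthetic cohort, conditional on the cohort-level structure (connection
#' mask and voxel counts) realized from the spec's seed. For a present
#' connection with expected directed count `m` and endpoint voxel counts
#' `v1`, `v2`, the expected weight is `m/v1 + m/v2`; edges incident to
#' `effect_nodes` are scaled by `effect_multiplier` for the musician group.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"musician"`.
#' @return An N x N numeric matrix with node labels as dimnames.
#' @export
expected_weight_matrix <- function(spec, group = c("control", "musician")) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must be a cohort_spec object", call. = FALSE)
  if (!is.character(group) || !(group[1] %in% c("control", "musician")))
    stop(sprintf("unknown group label: %s", group[1]), call. = FALSE)
  group <- group[1]
  geom <- .cohort_geometry(spec)
  mu <- geom$mu * geom$mask * (if (group == "musician") .effect_matrix(spec) else 1)
  iv <- 1 / geom$voxels
  w <- mu * outer(iv, iv, "+")  # mu_ij * (1/v_i + 1/v_j); mu symmetric
  diag(w) <- 0
  dimnames(w) <- list(spec$labels, spec$labels)
  w
}
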