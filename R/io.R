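#' Write a matrix as delimited text
#'
#' Writes a numeric matrix as whitespace-delimited text, optionally preceded
#' by a header row of node labels. The on-disk layout is plain text so that
#' every intermediate of the pipeline stays inspectable.
#'
#' @param m Numeric matrix or [weighted_network()].
#' @param path Output file.
#' @param header Write a node-label header row (default `TRUE` when labels
#'   are available).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, header = TRUE) {
  if (inherits(m, "weighted_network")) m <- m$weights
  labs <- colnames(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (header && !is.null(labs))
    writeLines(paste(labs, collapse = " "), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a delimited text matrix
#'
#' Accepts whitespace- or comma-delimited square matrices with an optional
#' first row of node labels (auto-detected: a first row that does not parse
#' as numbers is taken as the header).
#'
#' @param path Input file.
#' @param labels Optional labels overriding any header (matrices without a
#'   header are interpreted in node-table order).
#' @return A numeric matrix, with dimnames when labels are known.
#' @export
read_matrix <- function(path, labels = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                   skip = if (has_header) 1L else 0L))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in %s is not square (%d x %d)", path,
                 nrow(m), ncol(m)), call. = FALSE)
  if (is.null(labels) && has_header) labels <- toks
  if (!is.null(labels)) {
    if (length(labels) != nrow(m))
      stop("label count does not match matrix dimension", call. = FALSE)
    dimnames(m) <- list(labels, labels)
  }
  m
}

#' Write a motion log in 6-column text layout
#'
#' One row per volume, six whitespace-separated columns (three translations
#' in mm, three rotations in degrees) — the layout of FSL-style `.par`
#' realignment files.
#'
#' @param log A [motion_log()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motion_log <- function(log, path) {
  if (!inherits(log, "motion_log"))
    stop("`log` must be a motion_log object", call. = FALSE)
  utils::write.table(format(log$params, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a 6-column motion log
#'
#' @param path Input `.par`-style file.
#' @param subject_id,scan_id Identifiers attached to the returned log.
#' @return A [motion_log()].
#' @export
read_motion_log <- function(path, subject_id = "sub", scan_id = 1L) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_log(m, subject_id = subject_id, scan_id = scan_id)
}

#' Write a synthetic cohort to disk
#'
#' Writes one counts matrix per (subject, scan), one voxel-count file and
#' one motion log per scan per subject, and a `manifest.csv` listing
#' `subject_id`, `group`, `onset_age` and relative file paths. Everything is
#' plain delimited text.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "tract_cohort"))
    stop("`cohort` must be a tract_cohort object", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(sub) {
    cfiles <- character(0)
    mfiles <- character(0)
    vfile <- sprintf("%s_voxels.txt", sub$subject_id)
    writeLines(format(sub$scans[[1]]$counts$voxels, trim = TRUE),
               file.path(dir, vfile))
    for (sc in seq_along(sub$scans)) {
      cf <- sprintf("%s_scan%d_counts.txt", sub$subject_id, sc)
      mf <- sprintf("%s_scan%d_motion.par", sub$subject_id, sc)
      write_matrix(sub$scans[[sc]]$counts$counts, file.path(dir, cf))
      write_motion_log(sub$scans[[sc]]$motion, file.path(dir, mf))
      cfiles <- c(cfiles, cf)
      mfiles <- c(mfiles, mf)
    }
    data.frame(subject_id = sub$subject_id, group = sub$group,
               onset_age = sub$onset_age, voxels_file = vfile,
               counts_files = paste(cfiles, collapse = ";"),
               motion_files = paste(mfiles, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = TRUE)
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' Reconstructs the per-subject scan data written by [write_cohort()]. File
#' paths in the manifest are resolved relative to the manifest's directory.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @param labels Optional node labels for matrices without headers.
#' @return An object of class `tract_cohort` (without the generator's
#'   latent geometry).
#' @export
read_cohort <- function(manifest_path, labels = NULL) {
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  want <- c("subject_id", "group", "onset_age", "voxels_file",
            "counts_files", "motion_files")
  if (!all(want %in% names(mf)))
    stop(sprintf("manifest must contain columns: %s",
                 paste(want, collapse = ", ")), call. = FALSE)
  base <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(mf)), function(r) {
    voxels <- as.numeric(readLines(file.path(base, mf$voxels_file[r])))
    cfiles <- strsplit(mf$counts_files[r], ";", fixed = TRUE)[[1]]
    mfiles <- strsplit(mf$motion_files[r], ";", fixed = TRUE)[[1]]
    scans <- lapply(seq_along(cfiles), function(sc) {
      cm <- read_matrix(file.path(base, cfiles[sc]), labels = labels)
      list(counts = tract_counts(cm, voxels,
                                 subject_id = mf$subject_id[r],
                                 scan_id = sc),
           motion = read_motion_log(file.path(base, mfiles[sc]),
                                    subject_id = mf$subject_id[r],
                                    scan_id = sc))
    })
    list(subject_id = mf$subject_id[r], group = mf$group[r],
         onset_age = mf$onset_age[r], scans = scans)
  })
  structure(list(spec = NULL, geometry = NULL, subjects = subjects),
            class = "tract_cohort")
}
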