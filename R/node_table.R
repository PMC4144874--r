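# The 45 cortical and sub-cortical regions of the Automated Anatomical
# Labeling (AAL) parcellation used as network nodes, expanded to left/right
# hemispheres (90 regions, 45 per hemisphere).
.AAL_REGIONS <- data.frame(
  name = c(
    "Superior frontal gyrus, dorsolateral",
    "Superior frontal gyrus, orbital",
    "Superior frontal gyrus, medial",
    "Superior frontal gyrus, medial orbital",
    "Middle frontal gyrus",
    "Middle frontal gyrus, orbital",
    "Inferior frontal gyrus, opercular",
    "Inferior frontal gyrus, triangular",
    "Inferior frontal gyrus, orbital",
    "Gyrus rectus",
    "Anterior cingulate gyrus",
    "Olfactory cortex",
    "Precentral gyrus",
    "Supplementary motor area",
    "Rolandic operculum",
    "Median- and para-cingulate gyrus",
    "Calcarine fissure and surrounding cortex",
    "Cuneus",
    "Lingual gyrus",
    "Superior occipital gyrus",
    "Middle occipital gyrus",
    "Inferior occipital gyrus",
    "Fusiform gyrus",
    "Superior parietal gyrus",
    "Paracentral lobule",
    "Postcentral gyrus",
    "Inferior parietal gyrus",
    "Supramarginal gyrus",
    "Angular gyrus",
    "Precuneus",
    "Posterior cingulate gyrus",
    "Insula",
    "Thalamus",
    "Superior temporal gyrus",
    "Superior temporal gyrus, temporal pole",
    "Middle temporal gyrus",
    "Middle temporal gyrus, temporal pole",
    "Inferior temporal gyrus",
    "Heschl gyrus",
    "Hippocampus",
    "Parahippocampal gyrus",
    "Amygdala",
    "Caudate nucleus",
    "Lenticular nucleus, putamen",
    "Lenticular nucleus, pallidum"),
  abbreviation = c(
    "SFGdor", "SFGorb", "SFGmed", "SFGmorb", "MFG", "MFGorb", "IFGoper",
    "IFGtri", "IFGorb", "REG", "ACC", "OLF", "PreCG", "SMA", "ROL", "MCC",
    "CAL", "CUN", "LING", "SOG", "MOG", "IOG", "FG", "SPG", "PCL", "PoCG",
    "IPG", "SMG", "ANG", "PCNU", "PCC", "INS", "THA", "STG", "STGp", "MTG",
    "MTGp", "ITG", "HES", "HIP", "PHIP", "AMYG", "CAU", "PUT", "PAL"),
  stringsAsFactors = FALSE)

#' Default 90-region AAL node table
#'
#' The 45 AAL cortical/sub-cortical regions expanded to both hemispheres
#' (suffixes `_L` / `_R`, left first), giving the 90 network nodes in their
#' canonical order. This order is the coordinate convention for all matrices
#' without header rows.
#'
#' @return A data.frame with columns `index`, `name`, `abbreviation`,
#'   `hemisphere` (90 rows, 45 per hemisphere).
#' @export
#' @examples
#' nt <- aal_node_table()
#' nrow(nt)                       # 90
#' c("SMA_L", "SMA_R") %in% nt$abbreviation
aal_node_table <- function() {
  nr <- nrow(.AAL_REGIONS)
  idx <- rep(seq_len(nr), each = 2L)
  hemi <- rep(c("L", "R"), nr)
  data.frame(index = seq_len(2L * nr),
             name = .AAL_REGIONS$name[idx],
             abbreviation = paste(.AAL_REGIONS$abbreviation[idx], hemi,
                                  sep = "_"),
             hemisphere = hemi,
             stringsAsFactors = FALSE)
}

#' Read a node table from CSV
#'
#' @param path CSV file with columns `index`, `name`, `abbreviation`,
#'   `hemisphere`; `NULL` (default) returns [aal_node_table()].
#' @return A node table data.frame.
#' @export
read_node_table <- function(path = NULL) {
  if (is.null(path)) return(aal_node_table())
  nt <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("index", "name", "abbreviation", "hemisphere")
  if (!identical(names(nt), want))
    stop(sprintf("node table must have columns %s (got %s)",
                 paste(want, collapse = ", "),
                 paste(names(nt), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(nt$abbreviation))
    stop(sprintf("duplicate abbreviation(s): %s",
                 paste(unique(nt$abbreviation[duplicated(nt$abbreviation)]),
                       collapse = ", ")), call. = FALSE)
  nt
}

#' Write a node table to CSV
#'
#' @param nt A node table data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(nt, path) {
  utils::write.csv(nt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
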