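#' @importFrom stats cor pt pnorm rnorm var setNames
#' @importFrom utils read.csv write.csv
NULL

#' Structure codes of the cortico-basal ganglia-thalamic parcellation
#'
#' The six brain structures covered by the shipped 176-ROI parcellation:
#' caudoputamen (CP), substantia nigra pars reticulata (SNr), globus pallidus
#' externus (GPe), motor cortex (MOTOR), prefrontal cortex (PFC) and thalamic
#' nuclei (TH).
#'
#' @export
CBT_STRUCTURES <- c("CP", "SNr", "GPe", "MOTOR", "PFC", "TH")

registry_columns <- c("roi_id", "structure", "subdivision", "domain_label", "bregma_mm")

new_roi_registry <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("roi_registry", "data.frame"))
}

validate_registry <- function(df, file = "<registry>") {
  missing_cols <- setdiff(registry_columns, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("registry '%s' lacks required column(s): %s",
                 file, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dup <- df$roi_id[duplicated(df$roi_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate roi_id in '%s': %s",
                 file, paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  bad_struct <- setdiff(unique(df$structure), CBT_STRUCTURES)
  if (length(bad_struct) > 0) {
    bad_rows <- which(df$structure %in% bad_struct)
    stop(sprintf("unknown structure code(s) in '%s': %s (row %s)",
                 file, paste(bad_struct, collapse = ", "),
                 paste(bad_rows, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(df$bregma_mm) || any(!is.finite(df$bregma_mm))) {
    stop(sprintf("non-finite bregma_mm in '%s'", file), call. = FALSE)
  }
  invisible(df)
}

#' Load an ROI registry
#'
#' Reads a parcellation table mapping each region of interest (ROI) to its
#' structure, atlas subdivision, connectome domain label, and bregma level.
#' The registry fixes the node identity and ordering used by every matrix in
#' the pipeline: ROIs are kept in file order, which for the shipped default
#' is grouped by structure and arranged rostral to caudal within structure.
#'
#' @param path Path to a registry CSV with columns
#'   \code{roi_id,structure,subdivision,domain_label,bregma_mm}, or a JSON
#'   file holding an array of such records. Defaults to the shipped
#'   176-ROI parcellation.
#' @return A \code{roi_registry} data frame.
#' @export
load_registry <- function(path = default_registry_path()) {
  if (!file.exists(path)) stop(sprintf("registry file '%s' not found", path), call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  validate_registry(df, path)
  new_roi_registry(df[, registry_columns])
}

#' Path to the shipped 176-ROI registry
#' @return File path of the default parcellation CSV.
#' @export
default_registry_path <- function() {
  system.file("extdata", "roi_registry_176.csv", package = "metaconn", mustWork = TRUE)
}

#' The shipped 176-ROI cortico-basal ganglia-thalamic registry
#'
#' Loads the default parcellation: 176 ROIs over six structures with 66
#' caudoputamen and 21 thalamic ROIs; the remaining structures hold 25 (SNr),
#' 27 (GPe), 18 (motor cortex) and 19 (PFC) ROIs, counts implied exactly by
#' the within-structure pair arithmetic of the connectivity-density tables.
#'
#' @return A \code{roi_registry} of 176 rows.
#' @export
default_registry <- function() load_registry(default_registry_path())

#' Write a registry to CSV or JSON
#'
#' @param registry A \code{roi_registry}.
#' @param path Output path; a \code{.json} suffix selects JSON, anything else CSV.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  df <- as.data.frame(registry)[, registry_columns]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' ROIs per structure
#'
#' @param registry A \code{roi_registry}.
#' @return Named integer vector of ROI counts in canonical structure order.
#' @export
structure_counts <- function(registry) {
  present <- intersect(CBT_STRUCTURES, unique(registry$structure))
  vapply(setNames(present, present),
         function(s) sum(registry$structure == s), integer(1))
}

#' Number of unordered ROI pairs within or between structures
#'
#' The denominator of connectivity density. Within a structure of k ROIs
#' there are k(k-1)/2 unordered pairs (no self-pairs); between two distinct
#' structures with k_a and k_b ROIs there are k_a * k_b pairs. For the
#' shipped registry, \code{pair_count(reg, "CP", "CP")} is 2145 and
#' \code{pair_count(reg, "CP", "TH")} is 1386.
#'
#' @param registry A \code{roi_registry}.
#' @param structure_a,structure_b Structure codes present in the registry.
#' @return Integer pair count.
#' @export
pair_count <- function(registry, structure_a, structure_b) {
  for (s in c(structure_a, structure_b)) {
    if (!s %in% registry$structure) {
      stop(sprintf("structure code '%s' not present in registry", s), call. = FALSE)
    }
  }
  ka <- sum(registry$structure == structure_a)
  if (structure_a == structure_b) return(as.integer(ka * (ka - 1) / 2))
  kb <- sum(registry$structure == structure_b)
  as.integer(ka * kb)
}
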