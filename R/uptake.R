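#' Construct a subjects-by-ROI uptake table
#'
#' Container for one group's regional uptake measurements: one row per
#' subject, one column per ROI in registry order. Values are mean regional
#' uptake in arbitrary optical-density units; Pearson correlation downstream
#' is invariant to a common rescaling but not to per-subject rescaling,
#' which is exactly what \code{\link{global_scale}} manipulates.
#'
#' @param values Numeric matrix, subjects x ROIs.
#' @param subject_ids Unique subject identifiers (defaults to rownames).
#' @param roi_ids ROI identifiers matching a registry (defaults to colnames).
#' @param group_name Label for the group.
#' @return An \code{uptake_table} object.
#' @export
uptake_table <- function(values, subject_ids = rownames(values),
                         roi_ids = colnames(values), group_name = "group") {
  values <- as.matrix(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(roi_ids)) stop("roi_ids required", call. = FALSE)
  if (length(subject_ids) != nrow(values) || length(roi_ids) != ncol(values)) {
    stop("dimension mismatch between values and subject/ROI ids", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  dimnames(values) <- list(subject_ids, roi_ids)
  tab <- structure(list(group_name = group_name,
                        subject_ids = subject_ids,
                        roi_ids = roi_ids,
                        values = values),
                   class = "uptake_table")
  validate_uptake(tab)
  tab
}

validate_uptake <- function(tab, check_variance = TRUE) {
  v <- tab$values
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)
    cells <- apply(bad, 1, function(ix) sprintf("(%s,%s)", rownames(v)[ix[1]], colnames(v)[ix[2]]))
    stop(sprintf("missing values in uptake table '%s' at cell(s): %s",
                 tab$group_name, paste(cells, collapse = ", ")), call. = FALSE)
  }
  if (check_variance && nrow(v) > 1) {
    cv <- apply(v, 2, var)
    if (any(cv == 0)) {
      stop(sprintf("zero-variance ROI column(s) in '%s': %s (Pearson correlation undefined)",
                   tab$group_name, paste(colnames(v)[cv == 0], collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(tab)
}

#' @export
print.uptake_table <- function(x, ...) {
  cat(sprintf("uptake_table '%s': %d subjects x %d ROIs\n",
              x$group_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a group uptake table from CSV
#'
#' Expects a header row with \code{subject_id} first and one column per ROI.
#' Columns are re-indexed to registry order; missing ROI columns or
#' zero-variance columns are errors.
#'
#' @param path CSV file path.
#' @param registry \code{roi_registry} defining the expected ROI set and order.
#' @param group_name Group label; defaults to the file name without extension.
#' @return An \code{uptake_table}.
#' @export
read_uptake <- function(path, registry, group_name = NULL) {
  if (is.null(group_name)) group_name <- sub("\\.[^.]*$", "", basename(path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "subject_id") {
    stop(sprintf("'%s': first column must be 'subject_id'", path), call. = FALSE)
  }
  missing_rois <- setdiff(registry$roi_id, names(df))
  if (length(missing_rois) > 0) {
    stop(sprintf("'%s' is missing ROI column(s): %s",
                 path, paste(missing_rois, collapse = ", ")), call. = FALSE)
  }
  values <- as.matrix(df[, registry$roi_id, drop = FALSE])
  uptake_table(values, subject_ids = as.character(df$subject_id),
               roi_ids = registry$roi_id, group_name = group_name)
}

#' Write an uptake table to CSV
#' @param tab An \code{uptake_table}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_uptake <- function(tab, path) {
  df <- data.frame(subject_id = tab$subject_ids, tab$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Global (proportional) scaling of subject uptake
#'
#' Rescales each subject's row so that its mean uptake equals
#' \code{target_mean}, the tabular analogue of proportional scaling of
#' whole-brain optical density: global uptake is assumed constant across
#' animals, so between-subject differences in overall signal are treated as
#' nuisance gain. The operation is idempotent, and because it rescales
#' subjects individually it can change inter-regional Pearson correlations
#' when subject means differ (this is intentional).
#'
#' @param tab An \code{uptake_table} with strictly positive subject means.
#' @param target_mean Positive constant every subject mean is mapped to.
#' @return Rescaled \code{uptake_table}.
#' @export
global_scale <- function(tab, target_mean = 100) {
  stopifnot(target_mean > 0)
  m <- rowMeans(tab$values)
  if (any(m <= 0)) {
    stop(sprintf("non-positive subject mean(s): %s",
                 paste(tab$subject_ids[m <= 0], collapse = ", ")), call. = FALSE)
  }
  tab$values <- tab$values * (target_mean / m)
  tab
}
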