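#' Fisher r-to-z transformation
#'
#' \code{z = atanh(r) = 0.5 * log((1 + r) / (1 - r))}; an odd, strictly
#' increasing map that makes correlation coefficients approximately normal
#' with variance 1/(n - 3).
#'
#' @param r Correlation coefficient(s), each strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
r_to_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("r_to_z is defined only for |r| < 1", call. = FALSE)
  }
  atanh(r)
}

# two-sided p for a Pearson coefficient from n paired observations,
# via t = r * sqrt((n-2)/(1-r^2)) on n-2 df; |r| = 1 gives p = 0
cor_pvalue <- function(r, n) {
  p <- matrix(0, nrow = NROW(r), ncol = NCOL(r))
  inside <- abs(r) < 1
  tt <- r[inside] * sqrt((n - 2) / (1 - r[inside]^2))
  p[inside] <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  if (is.matrix(r)) dimnames(p) <- dimnames(r) else p <- as.vector(p)
  p
}

#' Within-group inter-regional correlation matrix
#'
#' Pearson product-moment correlations between all ROI pairs, computed
#' across the subjects of one group — the cross-subject ("metabolic
#' connectivity") analogue of functional connectivity, taken at a single
#' time point. Each coefficient gets a two-sided p-value from the t
#' distribution with n - 2 degrees of freedom, and a Fisher z transform for
#' display. Diagonal entries of \code{z} and \code{p} are \code{NA}: the
#' self-correlation is not an edge.
#'
#' @param tab An \code{uptake_table} with at least 4 subjects and no
#'   constant ROI column.
#' @return A \code{correlation_result}: list with symmetric \code{r},
#'   \code{z}, \code{p} matrices (ROI-labelled), and sample size \code{n}.
#' @export
pearson_matrix <- function(tab) {
  validate_uptake(tab)
  n <- nrow(tab$values)
  if (n < 4) stop("pearson_matrix requires at least 4 subjects", call. = FALSE)
  r <- cor(tab$values)
  r <- pmin(pmax(r, -1), 1)
  p <- cor_pvalue(r, n)
  z <- suppressWarnings(atanh(pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)))
  diag(p) <- NA_real_
  diag(z) <- NA_real_
  diag(r) <- 1
  structure(list(r = r, z = z, p = p, n = n, group_name = tab$group_name),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result '%s': %d ROIs, n = %d subjects\n",
              x$group_name, nrow(x$r), x$n))
  invisible(x)
}

edge_upper_indices <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

new_edge_set <- function(df, provenance, alpha) {
  rownames(df) <- NULL
  structure(df, class = c("edge_set", "data.frame"),
            provenance = provenance, alpha = alpha)
}

#' Construct an edge set directly
#'
#' Builds an \code{edge_set} from explicit ROI pairs, e.g. to replay a
#' published edge count through the density machinery. Pairs must be
#' unordered and distinct.
#'
#' @param roi_i,roi_j ROI id vectors of equal length.
#' @param sign "+" or "-" per edge (recycled).
#' @param r_full Optional full-sample coefficient per edge.
#' @param provenance "within_group" or "group_difference".
#' @param alpha Significance level associated with the set.
#' @return An \code{edge_set} data frame.
#' @export
edge_set <- function(roi_i, roi_j, sign = "+", r_full = NA_real_,
                     provenance = "within_group", alpha = 0.05) {
  stopifnot(length(roi_i) == length(roi_j), all(sign %in% c("+", "-")))
  if (any(roi_i == roi_j)) stop("self-edges are not allowed", call. = FALSE)
  df <- data.frame(roi_i = as.character(roi_i), roi_j = as.character(roi_j),
                   sign = rep_len(sign, length(roi_i)),
                   r_full = rep_len(r_full, length(roi_i)),
                   stringsAsFactors = FALSE)
  key <- paste(pmin(df$roi_i, df$roi_j), pmax(df$roi_i, df$roi_j))
  if (anyDuplicated(key)) stop("duplicate (parallel) edges are not allowed", call. = FALSE)
  new_edge_set(df, provenance = provenance, alpha = alpha)
}

#' Jackknife-reliable within-group edges
#'
#' Guards the large number of simultaneous correlations against spurious
#' hits with a leave-one-subject-out jackknife: for a group of n subjects,
#' the correlation matrix is recomputed n times with one subject dropped,
#' and an ROI pair is accepted as an edge only if its correlation is
#' significant (p < \code{alpha}) with a consistent sign in every one of
#' the n iterations. The edge's sign is that of the full-sample coefficient.
#'
#' @param tab An \code{uptake_table} with at least 5 subjects.
#' @param alpha Per-iteration significance level (default 0.05).
#' @param strict_full_sample If \code{TRUE}, additionally require the
#'   full-sample correlation itself to reach p < \code{alpha} (the
#'   reliability criterion alone is the default).
#' @return An \code{edge_set} data frame with columns \code{roi_i},
#'   \code{roi_j}, \code{sign} ("+" or "-") and \code{r_full}, ordered with
#'   \code{roi_i} before \code{roi_j} in registry order. Per-edge jackknife
#'   diagnostics (max p and min |r| across iterations) are kept in the
#'   \code{"diagnostics"} attribute.
#' @export
reliable_edges_jackknife <- function(tab, alpha = 0.05, strict_full_sample = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  n <- nrow(tab$values)
  if (n < 5) stop("jackknife reliability requires at least 5 subjects", call. = FALSE)
  full <- pearson_matrix(tab)
  p_rois <- ncol(tab$values)
  all_sig <- matrix(TRUE, p_rois, p_rois)
  sign_ref <- NULL
  sign_ok <- matrix(TRUE, p_rois, p_rois)
  p_max <- matrix(-Inf, p_rois, p_rois)
  r_absmin <- matrix(Inf, p_rois, p_rois)
  for (k in seq_len(n)) {
    sub <- tab
    sub$values <- tab$values[-k, , drop = FALSE]
    sub$subject_ids <- tab$subject_ids[-k]
    cv <- apply(sub$values, 2, var)
    if (any(cv == 0)) {
      stop(sprintf("jackknife iteration %d yields constant ROI column(s): %s",
                   k, paste(colnames(sub$values)[cv == 0], collapse = ", ")),
           call. = FALSE)
    }
    r_k <- cor(sub$values)
    p_k <- cor_pvalue(r_k, n - 1)
    all_sig <- all_sig & (p_k < alpha)
    if (is.null(sign_ref)) sign_ref <- sign(r_k) else sign_ok <- sign_ok & (sign(r_k) == sign_ref)
    p_max <- pmax(p_max, p_k)
    r_absmin <- pmin(r_absmin, abs(r_k))
  }
  keep <- all_sig & sign_ok
  if (strict_full_sample) keep <- keep & (full$p < alpha)
  idx <- edge_upper_indices(p_rois)
  sel <- idx[keep[idx], , drop = FALSE]
  rois <- colnames(tab$values)
  r_full <- full$r[sel]
  df <- data.frame(roi_i = rois[sel[, 1]], roi_j = rois[sel[, 2]],
                   sign = ifelse(r_full >= 0, "+", "-"),
                   r_full = r_full, stringsAsFactors = FALSE)
  es <- new_edge_set(df, provenance = "within_group", alpha = alpha)
  attr(es, "diagnostics") <- data.frame(
    roi_i = df$roi_i, roi_j = df$roi_j,
    p_max = p_max[sel], r_abs_min = r_absmin[sel], stringsAsFactors = FALSE)
  attr(es, "n") <- n
  es
}

#' Write an edge set to CSV
#' @param edges An \code{edge_set}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_edge_set <- function(edges, path) {
  write.csv(as.data.frame(edges), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labelled square matrix (r, z, p, or Z) to CSV
#' @param m Matrix with ROI dimnames.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(roi_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
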