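# The expression container used throughout: a log2-scale genes x samples
# matrix plus per-sample batch / tumor annotations. Deliberately lightweight
# (list-based S3) -- every downstream operation works on the numeric matrix.

#' Construct an annotated expression matrix
#'
#' @param values numeric matrix, genes in rows, samples in columns, log2
#'   scale. Row and column names are required and must be unique.
#' @param batch optional character vector of batch/cohort labels, one per
#'   sample (recycled if length 1).
#' @param tumor optional logical vector flagging tumor (vs normal) samples.
#' @return An object of class `m5c_expr` with elements `values` (the matrix)
#'   and `samples` (a data.frame with `sample_id`, `batch`, `tumor`).
#' @export
expr_matrix <- function(values, batch = NULL, tumor = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop2("`values` must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop2("duplicate gene IDs")
  if (anyDuplicated(colnames(values))) stop2("duplicate sample IDs")
  if (!all(is.finite(values))) stop2("non-finite expression values")
  n <- ncol(values)
  batch <- as.character(rep_len(batch %||% NA_character_, n))
  tumor <- as.logical(rep_len(tumor %||% NA, n))
  structure(
    list(values = values,
         samples = data.frame(sample_id = colnames(values),
                              batch = batch, tumor = tumor,
                              stringsAsFactors = FALSE)),
    class = "m5c_expr")
}

#' @export
print.m5c_expr <- function(x, ...) {
  cat("m5c_expr: ", nrow(x$values), " genes x ", ncol(x$values), " samples\n",
      sep = "")
  cat("  batches: ", paste(unique(x$samples$batch), collapse = ", "), "\n",
      sep = "")
  if (!all(is.na(x$samples$tumor))) {
    cat("  tumor/normal: ", sum(x$samples$tumor, na.rm = TRUE), "/",
        sum(!x$samples$tumor, na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.m5c_expr <- function(x) dim(x$values)

# Accept either an m5c_expr or a bare genes x samples matrix.
as_values <- function(expr) {
  if (inherits(expr, "m5c_expr")) return(expr$values)
  if (is.matrix(expr) && is.numeric(expr)) return(expr)
  stop2("expected an `m5c_expr` or a numeric genes x samples matrix")
}

sample_info <- function(expr) {
  if (inherits(expr, "m5c_expr")) return(expr$samples)
  data.frame(sample_id = colnames(as_values(expr)),
             batch = NA_character_, tumor = NA, stringsAsFactors = FALSE)
}

# Subset an m5c_expr by genes and/or samples, preserving annotations.
subset_expr <- function(expr, genes = NULL, samples = NULL) {
  x <- as_values(expr)
  info <- sample_info(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing) == length(genes)) stop2("none of the requested genes are present")
    x <- x[intersect(genes, rownames(x)), , drop = FALSE]
  }
  if (!is.null(samples)) {
    x <- x[, samples, drop = FALSE]
    info <- info[match(samples, info$sample_id), , drop = FALSE]
  }
  expr_matrix(x, batch = info$batch[match(colnames(x), info$sample_id)],
              tumor = info$tumor[match(colnames(x), info$sample_id)])
}

#' Validate a clinical table
#'
#' Checks the column contract used throughout the package: unique
#' `sample_id`, nonnegative `os_time`, `os_event` in \{0, 1\}, logical
#' `tumor`, character `batch`, optional `response` in CR/PR/SD/PD.
#'
#' @param clinical a data.frame.
#' @return The validated data.frame (invisibly usable downstream).
#' @export
validate_clinical <- function(clinical) {
  required <- c("sample_id", "os_time", "os_event", "tumor", "batch")
  miss <- setdiff(required, names(clinical))
  if (length(miss)) stop2("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(clinical$sample_id)) stop2("duplicate sample_id in clinical table")
  ok <- is.na(clinical$os_event) | clinical$os_event %in% c(0, 1)
  if (!all(ok)) stop2("os_event must be 0 or 1; offending value(s): ",
                      paste(unique(clinical$os_event[!ok]), collapse = ", "))
  if (any(clinical$os_time < 0, na.rm = TRUE)) stop2("negative os_time")
  if ("response" %in% names(clinical)) {
    bad <- !is.na(clinical$response) & !clinical$response %in% c("CR", "PR", "SD", "PD")
    if (any(bad)) stop2("unknown response label(s): ",
                        paste(unique(clinical$response[bad]), collapse = ", "))
  }
  clinical
}
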