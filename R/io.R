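# Readers/writers for the three plain-text formats the pipeline touches:
# expression matrices (TSV or GCT 1.2), clinical tables (TSV) and gene-set
# collections (GMT). Every silent modification (collapsed duplicate row,
# dropped record) is counted in a load report attached as an attribute so
# totals always reconcile: rows_in = rows_out + dropped + collapsed.

load_report <- function(rows_in, rows_out, dropped = 0L, collapsed = 0L, notes = character()) {
  list(rows_in = rows_in, rows_out = rows_out, dropped = dropped,
       collapsed = collapsed, notes = notes)
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV: first column = gene IDs, header row = sample IDs, tab separated.
#' GCT: version line `#1.2`, a dimensions line, then `Name`, `Description`
#' and one column per sample. Gzip-compressed files are accepted.
#'
#' Duplicate gene rows are collapsed to the row with the highest mean
#' expression; genes with any missing value are dropped. Both events are
#' counted in the load report (`attr(x, "load_report")`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param log2_transform apply `log2(x + 1)` after loading (for count-like
#'   input; the pipeline otherwise assumes values are already on log scale).
#' @return An [expr_matrix()] with a `load_report` attribute.
#' @export
read_expression <- function(path, format = c("tsv", "gct"), log2_transform = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
      stop2("not a GCT 1.2 file (line 1 must be '#1.2'): ", path)
    }
    dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]][1:2])
    df <- read.delim(textConnection(lines[-(1:2)]), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(df) != dims[1]) {
      stop2("GCT declares ", dims[1], " rows but ", nrow(df),
            " data rows found (line 2)")
    }
    if (ncol(df) - 2L != dims[2]) {
      stop2("GCT declares ", dims[2], " samples but ", ncol(df) - 2L, " found")
    }
    ids <- as.character(df[[1]])
    values <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
  }
  if (anyDuplicated(colnames(values))) stop2("duplicate sample IDs in ", path)
  if (!is.numeric(values)) {
    bad <- which(!vapply(seq_len(ncol(values)), function(j)
      all(!is.na(suppressWarnings(as.numeric(values[, j]))) | is.na(values[, j])),
      logical(1)))
    stop2("non-numeric expression cells in column(s): ",
          paste(colnames(values)[bad], collapse = ", "))
  }
  rows_in <- nrow(values)
  rownames(values) <- ids
  notes <- character()

  # collapse duplicated gene IDs, keeping the row with the highest mean
  collapsed <- 0L
  if (anyDuplicated(ids)) {
    means <- rowMeans(values, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(ids), ids), function(ix) ix[which.max(means[ix])]))
    keep <- sort(unname(keep))
    collapsed <- rows_in - length(keep)
    notes <- c(notes, paste0(collapsed, " duplicate gene row(s) collapsed by max mean"))
    values <- values[keep, , drop = FALSE]
  }

  # drop genes with missing values
  has_na <- rowSums(is.na(values)) > 0
  dropped <- sum(has_na)
  if (dropped) {
    notes <- c(notes, paste0(dropped, " gene(s) dropped for missing values: ",
                             paste(head(rownames(values)[has_na], 5), collapse = ", ")))
    values <- values[!has_na, , drop = FALSE]
  }
  if (log2_transform) values <- log2(values + 1)
  out <- expr_matrix(values)
  attr(out, "load_report") <- load_report(rows_in, nrow(values), dropped, collapsed, notes)
  out
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param expr an [expr_matrix()] or bare matrix.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  x <- as_values(expr)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    df <- data.frame(Name = rownames(x), Description = rownames(x), x,
                     check.names = FALSE, stringsAsFactors = FALSE)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  } else {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' One set per line: name, description, then gene IDs, tab separated.
#' Duplicate genes within a set are removed (each counted once).
#'
#' @param path GMT file path (gz accepted).
#' @return Named list of character vectors with a `descriptions` attribute
#'   and class `gene_set_collection`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop2("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop2("duplicate set names in ", path)
  gene_set_collection(sets, vapply(fields, `[[`, character(1), 2L))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character gene vectors (non-empty, unique names).
#' @param descriptions optional character vector, one per set.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) stop2("sets must have unique names")
  if (any(lengths(sets) == 0L)) stop2("empty gene set(s)")
  sets <- lapply(sets, unique)
  structure(sets, descriptions = descriptions %||% names(sets),
            class = c("gene_set_collection", "list"))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection: ", length(x), " sets, sizes ",
      min(lengths(x)), "-", max(lengths(x)), "\n", sep = "")
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param sets a `gene_set_collection` or named list.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `os_time`, `os_event`, `tumor`, `batch`;
#' `response` (CR/PR/SD/PD) and extra endpoint columns are carried through.
#' Rows with missing `os_time` or `os_event` are dropped and counted in the
#' load report, mirroring the usual exclusion of patients without survival
#' information.
#'
#' @param path TSV path.
#' @return data.frame with a `load_report` attribute.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "os_time", "os_event", "tumor", "batch")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop2("clinical table missing column(s): ", paste(miss, collapse = ", "))
  df$tumor <- as.logical(df$tumor)
  rows_in <- nrow(df)
  keep <- !is.na(df$os_time) & !is.na(df$os_event)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df <- validate_clinical(df)
  attr(df, "load_report") <- load_report(
    rows_in, nrow(df), dropped = dropped,
    notes = if (dropped) paste0(dropped, " row(s) dropped for missing survival") else character())
  df
}

#' Write a clinical table to TSV
#' @param clinical data.frame as in [read_clinical()].
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
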