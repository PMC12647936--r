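# Xena-style matrix IO and cross-modality sample alignment.
#
# Orientation follows the UCSC Xena convention: rows are features, columns
# are samples, and the header row is `sample<TAB>id1<TAB>id2...`.

#' Construct an omics matrix
#'
#' A feature-by-sample numeric matrix tagged with its modality. Row names
#' are feature ids, column names sample ids; both must be unique. Missing
#' entries (NA) are permitted only for methylation before imputation.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param modality one of `"exon"`, `"mrna"`, `"mirna"`, `"methylation"`,
#'   `"fused"`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, modality) {
  modality <- match.arg(modality, MODALITIES)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_masegc("format", "values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_masegc("format", "values must carry feature (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_masegc("format", "duplicate feature ids: %s",
                paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop_masegc("format", "duplicate sample ids: %s",
                paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  structure(list(modality = modality, values = values), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> modality=%s  %d features x %d samples  (%d missing)\n",
              x$modality, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Construct a sample label table
#'
#' @param sample_ids character vector of unique sample ids.
#' @param labels binary vector (0 = normal, 1 = tumor), one per sample.
#' @return an object of class `label_table`.
#' @export
label_table <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_masegc("format", "duplicate sample ids in labels")
  labels <- as.integer(labels)
  if (length(labels) != length(sample_ids)) {
    stop_masegc("format", "one label per sample id required")
  }
  if (!all(labels %in% c(0L, 1L))) stop_masegc("format", "labels must be 0/1")
  structure(list(sample_ids = sample_ids, labels = stats::setNames(labels, sample_ids)),
            class = "label_table")
}

#' Read an omics matrix from a Xena-style TSV
#'
#' First row: header cell then sample ids; each following row: feature id
#' then numeric values. The tokens `NA`, `NaN` and the empty string
#' (case-insensitive) become missing entries.
#'
#' @param path file path.
#' @param modality modality tag for the returned matrix.
#' @param transpose if `TRUE` the file is sample-major (rows = samples) and
#'   is transposed on read.
#' @return an [omics_matrix].
#' @export
read_omics_matrix <- function(path, modality, transpose = FALSE) {
  if (!file.exists(path)) stop_masegc("io", "file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop_masegc("format", "no feature rows in %s", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]][-1L]
  body <- cells[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  n <- length(header)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n,
                 dimnames = list(ids, header))
  for (i in seq_along(body)) {
    row <- body[[i]][-1L]
    length(row) <- n  # short rows pad with NA
    isna <- tolower(trimws(row)) %in% NA_TOKENS | is.na(row)
    num <- suppressWarnings(as.numeric(row))
    bad <- which(!isna & is.na(num))
    if (length(bad)) {
      stop_masegc("parse", "non-numeric cell '%s' at feature '%s', sample '%s'",
                  row[bad[1L]], ids[i], header[bad[1L]])
    }
    num[isna] <- NA_real_
    vals[i, ] <- num
  }
  if (transpose) vals <- t(vals)
  omics_matrix(vals, modality)
}

#' Write an omics matrix as a Xena-style TSV
#'
#' Values are written with 10 significant digits (the documented round-trip
#' precision); missing entries are written as `NA`.
#'
#' @param matrix an [omics_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (nrow(matrix$values) == 0L) stop_masegc("format", "nothing to write: matrix has no features")
  fmt <- function(v) {
    out <- sprintf("%.10g", v)
    out[is.na(v)] <- "NA"
    out
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_masegc("io", "cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(matrix$values)), collapse = "\t"), con)
  for (i in seq_len(nrow(matrix$values))) {
    writeLines(paste(c(rownames(matrix$values)[i], fmt(matrix$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a two-column label TSV
#'
#' Columns: sample id and label; labels may be `tumor`/`normal` or `1`/`0`.
#'
#' @param path file path.
#' @return a [label_table].
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  lab <- tolower(df[[2L]])
  lab <- ifelse(lab %in% c("tumor", "sc", "1"), 1L,
                ifelse(lab %in% c("normal", "0"), 0L, NA_integer_))
  if (anyNA(lab)) stop_masegc("format", "unrecognized label token in %s", path)
  label_table(df[[1L]], lab)
}

#' Write a label table as TSV
#' @param labels a [label_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = labels$sample_ids, label = unname(labels$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align samples across modalities into a joint dataset
#'
#' Restricts every matrix and the label table to the intersection of their
#' sample ids, reordered to a canonical lexicographic order so results do
#' not depend on input column order.
#'
#' @param matrices list of [omics_matrix] objects (named by modality if the
#'   list is unnamed).
#' @param labels a [label_table].
#' @return a `multiomics_dataset`: list with `modalities` (named list of
#'   matrices), `labels`, `sample_ids`, and an `alignment` attribute with
#'   kept/dropped counts per modality.
#' @export
align_samples <- function(matrices, labels) {
  stopifnot(length(matrices) >= 1L, inherits(labels, "label_table"))
  shared <- labels$sample_ids
  for (m in matrices) shared <- intersect(shared, sample_ids(m))
  if (length(shared) == 0L) stop_masegc("alignment", "no samples shared across all modalities and labels")
  shared <- sort(shared)
  y <- labels$labels[shared]
  if (length(unique(y)) < 2L) {
    stop_masegc("class_coverage", "aligned samples contain a single class")
  }
  report <- lapply(matrices, function(m) {
    list(kept = length(shared), dropped = length(sample_ids(m)) - length(shared))
  })
  mods <- lapply(matrices, function(m) omics_matrix(m$values[, shared, drop = FALSE], m$modality))
  names(mods) <- vapply(mods, `[[`, character(1), "modality")
  names(report) <- names(mods)
  structure(list(modalities = mods,
                 labels = label_table(shared, unname(y)),
                 sample_ids = shared),
            alignment = report, class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d samples (%d tumor / %d normal), modalities: %s\n",
              length(x$sample_ids), sum(x$labels$labels == 1L), sum(x$labels$labels == 0L),
              paste(names(x$modalities), collapse = ", ")))
  invisible(x)
}
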