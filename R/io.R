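#' Read a feature abundance table (BIOM-style TSV export)
#'
#' Parses a tab-delimited features-x-samples count table as exported by
#' QIIME2-era tools (`biom convert --to-tsv`): an optional leading comment
#' line, an optional `#OTU ID` header line, first column holding feature
#' identifiers, remaining columns one per sample.
#'
#' @param path Path to a tab-delimited text file.
#' @param transposed If `TRUE` the file holds samples as rows and features
#'   as columns; the returned matrix is always features x samples.
#' @return A numeric matrix (features x samples) with unique row and column
#'   names, in file order.
#' @details Duplicate feature or sample identifiers, ragged rows and
#'   non-numeric cells raise a format error; negative counts raise a value
#'   error. Missing values are errors, never imputed.
#' @seealso [write_feature_table()], [bray_curtis()]
#' @export
read_feature_table <- function(path, transposed = FALSE) {
  if (!file.exists(path)) .cv_error(sprintf("file not found: %s", path), "cv_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # tolerate "# Constructed from biom file"-style comments; "#OTU ID" is a header
  drop <- startsWith(lines, "#") & !startsWith(lines, "#OTU ID")
  lines <- lines[!drop]
  if (length(lines) < 2L) .cv_error("feature table needs a header and at least one row", "cv_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(unique(lengths(fields))) != 1L) {
    .cv_error("ragged rows: all lines must have the same number of fields", "cv_format_error")
  }
  header <- fields[[1L]]
  if (length(header) < 2L) .cv_error("feature table needs at least one sample column", "cv_format_error")
  col_ids <- header[-1L]
  body <- fields[-1L]
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(row_ids)) .cv_error("duplicate feature ids in table", "cv_format_error")
  if (anyDuplicated(col_ids)) .cv_error("duplicate sample ids in table", "cv_format_error")
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(col_ids)))
  )
  counts <- matrix(vals, nrow = length(row_ids), ncol = length(col_ids), byrow = TRUE,
                   dimnames = list(row_ids, col_ids))
  if (anyNA(counts)) .cv_error("non-numeric or missing value in feature table", "cv_format_error")
  if (transposed) counts <- t(counts)
  if (any(counts < 0)) .cv_error("negative count in feature table", "cv_value_error")
  counts
}

#' Write a feature table in the BIOM-style TSV dialect
#'
#' @param counts Features x samples numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", colnames(counts)), collapse = "\t"), con)
  body <- apply(counts, 1L, function(x) paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                                              collapse = "\t"))
  writeLines(paste(rownames(counts), body, sep = "\t"), con)
  invisible(path)
}

#' Read a taxonomy assignment table
#'
#' Two-column TSV mapping feature id to a semicolon-delimited lineage
#' string. Greengenes-style (`k__`, `p__`, ...) and Silva-style
#' (`D_0__`, `D_1__`, ...) rank prefixes are stripped on ingest and
#' surrounding whitespace trimmed. A third (confidence) column, if present,
#' is ignored. Empty ranks are dropped; at most seven ranks
#' (domain..species) are retained.
#'
#' @param path Path to the TSV file; an optional header line
#'   (`Feature ID`/`feature-id`/`#OTU ID`) is tolerated.
#' @return A named list mapping feature id to a character vector of ranks
#'   (possibly empty for unassigned features).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) .cv_error(sprintf("file not found: %s", path), "cv_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields)) {
    first <- tolower(fields[[1L]][1L])
    if (first %in% c("feature id", "feature-id", "feature_id", "#otu id", "otu id")) {
      fields <- fields[-1L]
    }
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) .cv_error("feature listed twice in taxonomy", "cv_format_error")
  lineages <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", character(1L))
  out <- lapply(lineages, .parse_lineage)
  names(out) <- ids
  out
}

.parse_lineage <- function(s) {
  ranks <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  ranks <- sub("^D_[0-9]+__", "", ranks)
  ranks <- sub("^[a-zA-Z]__", "", ranks)
  ranks <- ranks[nzchar(ranks)]
  if (length(ranks) > 7L) ranks <- ranks[1:7]
  ranks
}

#' Write a taxonomy table (Silva-style rank prefixes)
#' @param tax Named list of rank vectors, as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  strings <- vapply(tax, function(r) {
    if (!length(r)) return("")
    paste(sprintf("D_%d__%s", seq_along(r) - 1L, r), collapse = ";")
  }, character(1L))
  writeLines(c("Feature ID\tTaxon", paste(names(tax), strings, sep = "\t")), path)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with one row per sample and named columns `sample-id` (or
#' `sample_id`), `system`, `population` and `ecotype`. Every sample must
#' carry all three labels and populations must nest within systems.
#'
#' @param path Path to the metadata TSV.
#' @return A data frame with columns `sample_id`, `system`, `population`,
#'   `ecotype` in file order.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) .cv_error(sprintf("file not found: %s", path), "cv_format_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE, comment.char = "")
  names(df)[tolower(names(df)) %in% c("sample-id", "sample_id", "#sampleid", "sampleid")] <- "sample_id"
  need <- c("sample_id", "system", "population", "ecotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) .cv_error(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")),
                              "cv_format_error")
  df <- df[, need]
  if (anyDuplicated(df$sample_id)) .cv_error("duplicate sample ids in metadata", "cv_format_error")
  if (any(!nzchar(as.matrix(df)))) .cv_error("metadata has empty labels; every sample needs system, population and ecotype",
                                             "cv_format_error")
  sys_per_pop <- tapply(df$system, df$population, function(x) length(unique(x)))
  if (any(sys_per_pop > 1L)) {
    .cv_error(sprintf("population(s) span multiple systems: %s",
                      paste(names(sys_per_pop)[sys_per_pop > 1L], collapse = ", ")),
              "cv_value_error")
  }
  rownames(df) <- NULL
  df
}

#' Write sample metadata
#' @param meta Data frame as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  names(out)[names(out) == "sample_id"] <- "sample-id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a comparison design
#'
#' TSV with named columns `vector_id`, `from_group`, `to_group`; one row
#' per change-vector. Direction is meaningful (always from ecotype A to
#' ecotype B, or from the outgroup to each focal population) and is taken
#' exactly as written, never auto-flipped. The design kind is inferred:
#' `"outgroup"` when every row shares one `from_group` (and there is more
#' than one row), `"pair"` otherwise.
#'
#' @param path Path to the design TSV.
#' @return A data frame with attribute `kind`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) .cv_error(sprintf("file not found: %s", path), "cv_format_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE, comment.char = "")
  need <- c("vector_id", "from_group", "to_group")
  miss <- setdiff(need, names(df))
  if (length(miss)) .cv_error(sprintf("design missing column(s): %s", paste(miss, collapse = ", ")),
                              "cv_format_error")
  df <- df[, need]
  validate_design(df)
}

#' Validate (and classify) a comparison design
#' @param design Data frame with columns `vector_id`, `from_group`, `to_group`.
#' @return The validated design with attribute `kind` (`"pair"` or `"outgroup"`).
#' @export
validate_design <- function(design) {
  if (anyDuplicated(design$vector_id)) .cv_error("duplicate vector_id in design", "cv_design_error")
  same <- design$from_group == design$to_group
  if (any(same)) {
    .cv_error(sprintf("design row with from_group == to_group: %s",
                      paste(design$vector_id[same], collapse = ", ")),
              "cv_design_error")
  }
  kind <- if (nrow(design) > 1L && length(unique(design$from_group)) == 1L) "outgroup" else "pair"
  attr(design, "kind") <- kind
  rownames(design) <- NULL
  design
}

#' Write a comparison design
#' @param design Design data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("vector_id", "from_group", "to_group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square labelled distance matrix (LSMAT-style TSV)
#'
#' Header row and first column carry the same sample labels. The matrix
#' must be symmetric within `tol` (it is then symmetrized by averaging,
#' since floating-point exports commonly differ in the last digits) and
#' have a zero diagonal.
#'
#' @param path Path to the matrix TSV.
#' @param tol Absolute symmetry/diagonal tolerance (default `1e-8`).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) .cv_error(sprintf("file not found: %s", path), "cv_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(unique(lengths(fields))) != 1L) .cv_error("ragged distance matrix", "cv_format_error")
  labels <- fields[[1L]][-1L]
  if (anyDuplicated(labels)) .cv_error("duplicate labels in distance matrix", "cv_format_error")
  body <- fields[-1L]
  row_labels <- vapply(body, `[[`, character(1L), 1L)
  if (!identical(row_labels, labels)) {
    .cv_error("distance matrix row labels do not match column labels", "cv_format_error")
  }
  m <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(length(labels))))
  dimnames(m) <- list(labels, labels)
  if (anyNA(m)) .cv_error("non-numeric value in distance matrix", "cv_format_error")
  validate_distance_matrix(m, tol = tol)
}

#' Validate a square distance matrix
#' @param m Square numeric matrix with matching dimnames.
#' @param tol Absolute symmetry/diagonal tolerance.
#' @return The symmetrized matrix (average of `m` and `t(m)`) with exact
#'   zero diagonal.
#' @export
validate_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) .cv_error("distance matrix must be square", "cv_format_error")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    .cv_error(sprintf("distance matrix asymmetric beyond tolerance (max |d(a,b) - d(b,a)| = %g)", asym),
              "cv_value_error")
  }
  if (max(abs(diag(m))) > tol) .cv_error("distance matrix diagonal is not zero", "cv_value_error")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Write a distance matrix in the LSMAT-style TSV dialect
#' @param m Symmetric labelled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(x) paste(format(x, digits = 15, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write analysis results (angles and test summaries)
#'
#' Emits one TSV of per-comparison angles/lengths/meanL and one TSV of
#' test summaries. Values are printed with enough digits that re-reading
#' reproduces them to at least 12 significant digits.
#'
#' @param angles Angle table as produced by [pairwise_angles()].
#' @param tests A list of test results (see [t_test_vs_90()] and friends)
#'   or a data frame of summaries; may be `NULL`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(angles, tests, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  angle_path <- file.path(dir, "angles.tsv")
  af <- angles
  num <- vapply(af, is.numeric, logical(1L))
  af[num] <- lapply(af[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(af, angle_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- angle_path
  if (!is.null(tests)) {
    tdf <- if (is.data.frame(tests)) tests else do.call(rbind, lapply(tests, as.data.frame))
    test_path <- file.path(dir, "tests.tsv")
    num <- vapply(tdf, is.numeric, logical(1L))
    tdf[num] <- lapply(tdf[num], function(x) format(x, digits = 15, trim = TRUE))
    utils::write.table(tdf, test_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, test_path)
  }
  invisible(paths)
}
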