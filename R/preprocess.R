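#' Rarefy a count table to even depth
#'
#' Subsamples each sample's counts without replacement (a multivariate
#' hypergeometric draw) down to `depth` reads. Samples whose total is below
#' `depth` are dropped and reported. One integer seed governs all samples:
#' each sample uses a deterministic substream keyed to its column position,
#' so results do not depend on which other samples are present.
#'
#' @param counts Features x samples matrix of nonnegative integers.
#' @param depth Target depth (positive integer).
#' @param seed Integer seed.
#' @return Rarefied count matrix whose columns all sum exactly to `depth`;
#'   dropped sample ids are attached as attribute `"dropped"`.
#' @export
rarefy <- function(counts, depth, seed) {
  .assert_scalar_count(depth, "depth")
  if (missing(seed) || is.null(seed)) .cv_error("rarefy requires a seed", "cv_value_error")
  if (any(counts != round(counts))) .cv_error("rarefaction requires integer counts", "cv_value_error")
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep)) .cv_error("all samples are below the rarefaction depth", "cv_value_error")
  dropped <- colnames(counts)[!keep]
  if (length(dropped)) {
    message(sprintf("rarefy: dropping %d sample(s) below depth %d: %s",
                    length(dropped), as.integer(depth), paste(dropped, collapse = ", ")))
  }
  out <- matrix(0, nrow(counts), sum(keep),
                dimnames = list(rownames(counts), colnames(counts)[keep]))
  pos <- which(keep)
  for (k in seq_along(pos)) {
    j <- pos[k]
    x <- counts[, j]
    set.seed(.sub_seed(seed, j))
    pool <- rep.int(seq_along(x), x)
    take <- sample(pool, size = depth, replace = FALSE)
    out[, k] <- tabulate(take, nbins = length(x))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Collapse a feature table to a named taxonomic level
#'
#' Features whose lineage, truncated at `level`, is identical are summed.
#' Features lacking an assignment at that level are pooled into a single
#' `unclassified_<level>` bin. Per-sample totals are conserved exactly.
#'
#' @param counts Features x samples matrix.
#' @param tax Taxonomy map as returned by [read_taxonomy()] (named list of
#'   rank vectors, domain first).
#' @param level One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @param missing What to do with features absent from `tax`: `"error"`
#'   (default) or `"pool"` into the unclassified bin.
#' @return Collapsed matrix, rows in order of first appearance.
#' @export
collapse_taxonomy <- function(counts, tax, level, missing = c("error", "pool")) {
  missing <- match.arg(missing)
  levels6 <- c("phylum", "class", "order", "family", "genus", "species")
  if (!(is.character(level) && length(level) == 1L && level %in% levels6)) {
    .cv_error(sprintf("level must be one of: %s", paste(levels6, collapse = ", ")), "cv_value_error")
  }
  idx <- match(level, levels6) + 1L  # rank 1 is the domain
  unknown <- paste0("unclassified_", level)
  feats <- rownames(counts)
  absent <- !(feats %in% names(tax))
  if (any(absent) && missing == "error") {
    .cv_error(sprintf("feature(s) absent from taxonomy: %s",
                      paste(feats[absent][seq_len(min(5L, sum(absent)))], collapse = ", ")),
              "cv_value_error")
  }
  key <- vapply(feats, function(f) {
    if (!(f %in% names(tax))) return(unknown)
    ranks <- tax[[f]]
    if (length(ranks) < idx || !nzchar(ranks[idx])) return(unknown)
    paste(ranks[seq_len(idx)], collapse = ";")
  }, character(1L))
  collapsed <- rowsum(counts, group = key, reorder = FALSE)
  # rowsum with reorder = FALSE keeps first-appearance order already
  collapsed
}
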