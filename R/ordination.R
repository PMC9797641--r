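#' Bray-Curtis dissimilarity between samples of a feature table
#'
#' BC(i, j) = sum_k |x_ki - x_kj| / sum_k (x_ki + x_kj), computed over all
#' features for every pair of samples; symmetric, zero diagonal, values in
#' \[0, 1\]. Delegates to [vegan::vegdist()].
#'
#' @param counts Features x samples matrix of nonnegative abundances with
#'   at least two samples.
#' @return Symmetric labelled distance matrix.
#' @export
bray_curtis <- function(counts) {
  if (ncol(counts) < 2L) .cv_error("Bray-Curtis needs at least 2 samples", "cv_value_error")
  if (any(counts < 0)) .cv_error("negative abundance in feature table", "cv_value_error")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    .cv_error(sprintf("sample(s) with zero total abundance: %s",
                      paste(colnames(counts)[zero], collapse = ", ")),
              "cv_value_error")
  }
  m <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  diag(m) <- 0
  m
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of the squared distances,
#' `B = -1/2 * J D^2 J` with `J = I - 11'/n`, followed by an
#' eigendecomposition of `B`. Coordinates are eigenvectors scaled by the
#' square root of their eigenvalue. Axes with eigenvalue at or below
#' `tol * max(eigenvalue)` are discarded; in particular negative axes
#' (which arise for non-Euclidean dissimilarities such as Bray-Curtis) are
#' dropped without Lingoes/Cailliez correction, and the discarded negative
#' eigenvalue mass is recorded on the result. Axis signs are arbitrary in
#' PCoA; they are fixed deterministically by forcing the entry of largest
#' absolute value in each axis to be positive, so that one shared
#' ordination always has one consistent basis.
#'
#' @param d Square symmetric distance matrix (or `dist`) over >= 2 samples.
#' @param n_axes Optional cap on the number of retained axes (the first
#'   `min(n_axes, positive axes)` are kept).
#' @param tol Relative eigenvalue tolerance (default `1e-8`).
#' @return An object of class `cv_ordination`: list with `points`
#'   (samples x d coordinate matrix), `eig` (retained eigenvalues,
#'   nonincreasing), `all_eig`, `negative_mass` (sum of |negative
#'   eigenvalues|), and `d` (retained dimensionality).
#' @export
pcoa <- function(d, n_axes = NULL, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) .cv_error("pcoa needs a square distance matrix", "cv_format_error")
  n <- nrow(d)
  if (n < 2L) .cv_error("pcoa needs at least 2 samples", "cv_value_error")
  d <- validate_distance_matrix(d, tol = 1e-8)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  b <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  b <- (b + t(b)) / 2
  ee <- eigen(b, symmetric = TRUE)
  vals <- ee$values
  if (max(vals) <= 0) .cv_error("degenerate input: no positive eigenvalue", "cv_degenerate_error")
  pos <- vals > tol * max(vals)
  negative_mass <- sum(abs(vals[vals < 0]))
  keep <- which(pos)
  if (!is.null(n_axes)) {
    .assert_scalar_count(n_axes, "n_axes")
    keep <- keep[seq_len(min(length(keep), as.integer(n_axes)))]
  }
  lam <- vals[keep]
  pts <- ee$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), length(lam))
  # deterministic sign convention: largest-|loading| entry of each axis positive
  for (k in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, k]))
    if (pts[i, k] < 0) pts[, k] <- -pts[, k]
  }
  dimnames(pts) <- list(rownames(d), paste0("Axis.", seq_along(keep)))
  structure(
    list(points = pts, eig = lam, all_eig = vals, negative_mass = negative_mass,
         d = length(keep), token = .ord_counter()),
    class = "cv_ordination"
  )
}

#' Wrap externally computed sample coordinates as an ordination
#'
#' Scores from other ordination methods (e.g. NMDS) can be supplied
#' directly to the vector analysis; this wraps a samples x axes matrix in
#' the same container [pcoa()] returns.
#'
#' @param coordinates Samples x axes numeric matrix with row names.
#' @return A `cv_ordination` object (with `eig = NULL`).
#' @export
as_ordination <- function(coordinates) {
  if (inherits(coordinates, "cv_ordination")) return(coordinates)
  coordinates <- as.matrix(coordinates)
  if (is.null(rownames(coordinates))) .cv_error("coordinates need sample row names", "cv_format_error")
  if (!is.numeric(coordinates) || anyNA(coordinates)) .cv_error("coordinates must be numeric and complete", "cv_value_error")
  structure(
    list(points = coordinates, eig = NULL, all_eig = NULL, negative_mass = NA_real_,
         d = ncol(coordinates), token = .ord_counter()),
    class = "cv_ordination"
  )
}

#' @export
print.cv_ordination <- function(x, ...) {
  cat(sprintf("Ordination: %d samples on %d retained axes\n", nrow(x$points), x$d))
  if (!is.null(x$eig)) {
    rel <- x$eig / sum(x$eig)
    cat(sprintf("  first axes explain %s of retained variance\n",
                paste(sprintf("%.1f%%", 100 * utils::head(rel, 3L)), collapse = ", ")))
    cat(sprintf("  discarded negative eigenvalue mass: %.4g\n", x$negative_mass))
  }
  invisible(x)
}

#' Write ordination coordinates and eigenvalues as TSV
#' @param ord A `cv_ordination` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ord$eig)) {
    writeLines(paste(c("#eigenvalues", format(ord$eig, digits = 15, trim = TRUE)), collapse = "\t"), con)
  }
  writeLines(paste(c("sample-id", colnames(ord$points)), collapse = "\t"), con)
  body <- apply(ord$points, 1L, function(x) paste(format(x, digits = 15, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(ord$points), body, sep = "\t"), con)
  invisible(path)
}
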