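#' Group centroids in an ordination
#'
#' Arithmetic mean of the member samples' coordinates on all retained
#' axes, for each level of a metadata grouping column.
#'
#' @param ord A `cv_ordination` (or samples x axes matrix with row names).
#' @param metadata Data frame with `sample_id` and the grouping column.
#' @param groups Optional character vector restricting/ordering the groups;
#'   default: every group present.
#' @param grouping Metadata column defining the groups (default
#'   `"population"`).
#' @return Groups x axes matrix of centroids; the ordination identity is
#'   carried along so that vectors from different ordinations cannot be
#'   mixed downstream.
#' @export
group_centroids <- function(ord, metadata, groups = NULL, grouping = "population") {
  ord <- as_ordination(ord)
  pts <- ord$points
  if (!grouping %in% names(metadata)) {
    .cv_error(sprintf("metadata has no column '%s'", grouping), "cv_format_error")
  }
  lab <- metadata[[grouping]][match(rownames(pts), metadata$sample_id)]
  if (is.null(groups)) groups <- unique(lab[!is.na(lab)])
  cent <- matrix(NA_real_, length(groups), ncol(pts), dimnames = list(groups, colnames(pts)))
  for (g in groups) {
    members <- which(!is.na(lab) & lab == g)
    if (!length(members)) {
      .cv_error(sprintf("group with no samples in the ordination: %s", g), "cv_design_error")
    }
    cent[g, ] <- colMeans(pts[members, , drop = FALSE])
  }
  attr(cent, "ord_token") <- ord$token
  cent
}

#' Centroid change-vectors for a comparison design
#'
#' For each design row, `v = centroid(to_group) - centroid(from_group)`.
#' Direction is taken exactly from the design and never auto-flipped:
#' holding direction consistent across comparisons (e.g. always benthic to
#' limnetic) is what makes the angles biologically interpretable.
#'
#' @param centroids Groups x axes matrix from [group_centroids()].
#' @param design Validated design data frame (see [read_design()]).
#' @return An object of class `change_vectors`: list with `vectors`
#'   (k x d matrix, row names = vector ids), `lengths`, `from`, `to`, `d`.
#' @export
change_vectors <- function(centroids, design) {
  design <- validate_design(design)
  missing_groups <- setdiff(unique(c(design$from_group, design$to_group)), rownames(centroids))
  if (length(missing_groups)) {
    .cv_error(sprintf("design references group(s) absent from centroids: %s",
                      paste(missing_groups, collapse = ", ")),
              "cv_design_error")
  }
  v <- centroids[design$to_group, , drop = FALSE] - centroids[design$from_group, , drop = FALSE]
  rownames(v) <- design$vector_id
  len <- sqrt(rowSums(v * v))
  if (any(len < 1e-12)) {
    .cv_error(sprintf("degenerate change-vector (zero length, angle undefined): %s",
                      paste(design$vector_id[len < 1e-12], collapse = ", ")),
              "cv_degenerate_error")
  }
  structure(
    list(vectors = v, lengths = len, from = design$from_group, to = design$to_group,
         d = ncol(v), ord_token = attr(centroids, "ord_token")),
    class = "change_vectors"
  )
}

#' Combine change-vector sets
#'
#' Only sets built in the same shared ordination can be combined; angles
#' between vectors expressed in different bases are meaningless, so mixing
#' ordinations is a hard error.
#' @param ... `change_vectors` objects.
#' @return A single `change_vectors` object.
#' @export
c.change_vectors <- function(...) {
  sets <- list(...)
  tok <- unique(unlist(lapply(sets, `[[`, "ord_token")))
  if (length(tok) > 1L) {
    .cv_error("cannot combine change-vectors from different ordinations", "cv_value_error")
  }
  dd <- unique(vapply(sets, `[[`, integer(1L), "d"))
  if (length(dd) > 1L) .cv_error("change-vector sets differ in dimensionality", "cv_value_error")
  v <- do.call(rbind, lapply(sets, `[[`, "vectors"))
  if (anyDuplicated(rownames(v))) .cv_error("duplicate vector ids when combining", "cv_design_error")
  structure(
    list(vectors = v, lengths = sqrt(rowSums(v * v)),
         from = unlist(lapply(sets, `[[`, "from")), to = unlist(lapply(sets, `[[`, "to")),
         d = dd, ord_token = if (length(tok)) tok else NULL),
    class = "change_vectors"
  )
}

# Accept a change_vectors object, a cva fit, or a bare k x d matrix.
.as_vector_matrix <- function(x) {
  if (inherits(x, "cva")) x <- x$vectors
  if (inherits(x, "change_vectors")) return(x$vectors)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("v", seq_len(nrow(x)))
    return(x)
  }
  .cv_error("expected change-vectors, a cva fit, or a numeric matrix of vectors", "cv_value_error")
}

#' All pairwise angles and mean lengths of a change-vector set
#'
#' theta = arccos of the clamped normalized dot product, in degrees, for
#' every unordered pair; `meanL` is the unweighted mean of the two vector
#' lengths of each comparison. Angles below 90 degrees indicate
#' parallelism, around 90 orthogonal change, above 90 anti-parallelism.
#'
#' @param vs A `change_vectors` object (or k x d matrix, k >= 2).
#' @return Data frame with columns `vector_id_1`, `vector_id_2`,
#'   `theta_deg`, `L1`, `L2`, `meanL`; `choose(k, 2)` rows.
#' @export
pairwise_angles <- function(vs) {
  v <- .as_vector_matrix(vs)
  k <- nrow(v)
  if (k < 2L) .cv_error("need at least 2 vectors for pairwise angles", "cv_value_error")
  len <- sqrt(rowSums(v * v))
  if (any(len < 1e-12)) .cv_error("zero-length vector in set", "cv_degenerate_error")
  u <- v / len
  g <- tcrossprod(u)
  pr <- .pair_index(k)
  theta <- acos(.clamp(g[pr], -1, 1)) * 180 / pi
  data.frame(
    vector_id_1 = rownames(v)[pr[, 1L]],
    vector_id_2 = rownames(v)[pr[, 2L]],
    theta_deg = theta,
    L1 = len[pr[, 1L]],
    L2 = len[pr[, 2L]],
    meanL = (len[pr[, 1L]] + len[pr[, 2L]]) / 2,
    stringsAsFactors = FALSE
  )
}

#' Fit a change-vector analysis
#'
#' The central model of the package: inside one shared ordination, connect
#' group centroids according to a comparison design, and measure every
#' pairwise angle (direction of community change) and vector length
#' (magnitude of change). Input can be a feature table (counts are turned
#' into Bray-Curtis distances and ordinated by PCoA), a precomputed
#' distance matrix (e.g. UniFrac exported from another tool), or sample
#' coordinates from any ordination (e.g. NMDS scores).
#'
#' @param x Features x samples count matrix, square symmetric distance
#'   matrix (or `dist`), samples x axes coordinate matrix, or a
#'   `cv_ordination` object.
#' @param metadata Sample metadata (see [read_metadata()]); only
#'   `sample_id` and the grouping column are required.
#' @param design Comparison design (see [read_design()]).
#' @param grouping Metadata column whose levels the design refers to
#'   (default `"population"`).
#' @param n_axes Optional cap on retained PCoA axes; default keeps all
#'   positive axes.
#' @param input One of `"auto"`, `"counts"`, `"distance"`,
#'   `"coordinates"`. `"auto"` treats a square symmetric zero-diagonal
#'   matrix as distances, any other matrix with negative entries as
#'   coordinates, and a nonnegative rectangular matrix as counts.
#' @return An object of class `cva` with components `vectors`
#'   (`change_vectors`), `angles` (the pairwise angle table), `centroids`,
#'   `ordination`, `design`, `d`. Methods: `print`, `summary` (runs the
#'   parallelism tests), `coef` (the vector matrix), `plot` (angle
#'   distribution).
#' @examples
#' coords <- matrix(c(0, 0, 3, 4, 0, 0, 4, 3), 4, 2, byrow = TRUE,
#'                  dimnames = list(paste0("s", 1:4), NULL))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    population = c("a1", "a2", "b1", "b2"))
#' des <- data.frame(vector_id = c("v1", "v2"),
#'                   from_group = c("a1", "b1"), to_group = c("a2", "b2"))
#' fit <- cva(coords, meta, des, input = "coordinates")
#' fit$angles$theta_deg  # angle between (3,4) and (4,3)
#' @export
cva <- function(x, metadata, design, grouping = "population", n_axes = NULL,
                input = c("auto", "counts", "distance", "coordinates")) {
  input <- match.arg(input)
  ord <- .resolve_ordination(x, n_axes = n_axes, input = input)
  design <- validate_design(design)
  groups <- unique(c(design$from_group, design$to_group))
  cent <- group_centroids(ord, metadata, groups = groups, grouping = grouping)
  vs <- change_vectors(cent, design)
  structure(
    list(vectors = vs, angles = pairwise_angles(vs), centroids = cent,
         ordination = ord, design = design, grouping = grouping, d = ord$d,
         call = match.call()),
    class = "cva"
  )
}

.resolve_ordination <- function(x, n_axes, input) {
  if (inherits(x, "cv_ordination")) return(x)
  if (inherits(x, "dist")) return(pcoa(x, n_axes = n_axes))
  x <- as.matrix(x)
  if (input == "auto") {
    input <- if (nrow(x) == ncol(x) && max(abs(x - t(x))) <= 1e-8 && max(abs(diag(x))) <= 1e-8) {
      "distance"
    } else if (any(x < 0)) "coordinates" else "counts"
  }
  switch(input,
    distance = pcoa(x, n_axes = n_axes),
    counts = pcoa(bray_curtis(x), n_axes = n_axes),
    coordinates = as_ordination(if (!is.null(n_axes)) x[, seq_len(min(ncol(x), n_axes)), drop = FALSE] else x)
  )
}

#' @export
print.cva <- function(x, digits = 3, ...) {
  cat("Change-vector analysis\n")
  cat(sprintf("  %d vectors (%s design) in %d dimensions\n",
              nrow(x$vectors$vectors), attr(x$design, "kind"), x$d))
  cat(sprintf("  %d pairwise comparisons; mean angle %.*f deg, mean length %.*f\n",
              nrow(x$angles), digits, mean(x$angles$theta_deg), digits, mean(x$vectors$lengths)))
  invisible(x)
}

#' @export
coef.cva <- function(object, ...) object$vectors$vectors

#' Summarize a change-vector analysis with parallelism tests
#'
#' Runs the selected significance tests on the fitted angle set:
#' a one-sample location test of the angles against the 90-degree null of
#' non-parallelism (`t` or `wilcoxon`; `"auto"` picks the t-test when a
#' Shapiro-Wilk test does not reject normality at `alpha = 0.05` and the
#' Wilcoxon signed-rank test otherwise), a Monte-Carlo comparison of the
#' observed mean angle against the null distribution of mean pairwise
#' angles among uniformly random directions (`mc`; needs `seed`), and a
#' Rayleigh test of directional concentration of the vectors themselves
#' (`rayleigh`).
#'
#' @param object A `cva` fit.
#' @param methods Character vector from `"auto"`, `"t"`, `"wilcoxon"`,
#'   `"mc"`, `"rayleigh"`, or `"all"` (auto + mc + rayleigh; default).
#' @param iterations Monte-Carlo iterations (default `1e5`).
#' @param seed Integer seed; required when the Monte-Carlo test runs.
#' @param ... Unused.
#' @return An object of class `summary.cva`: list of test results plus
#'   angle summaries.
#' @export
summary.cva <- function(object, methods = "all", iterations = 100000L, seed = NULL, ...) {
  angles <- object$angles$theta_deg
  if ("all" %in% methods) methods <- c("auto", "mc", "rayleigh")
  tests <- list()
  for (m in methods) {
    res <- switch(m,
      auto = {
        gate <- tryCatch(shapiro_gate(angles), changevec_error = function(e) "normal")
        if (identical(gate, "normal")) t_test_vs_90(angles) else wilcoxon_vs_90(angles)
      },
      t = t_test_vs_90(angles),
      wilcoxon = wilcoxon_vs_90(angles),
      mc = {
        if (is.null(seed)) .cv_error("Monte-Carlo test requires a seed", "cv_value_error")
        monte_carlo_parallelism(object, iterations = iterations, seed = seed)
      },
      rayleigh = rayleigh_test(object),
      .cv_error(sprintf("unknown method '%s'", m), "cv_value_error")
    )
    tests[[res$method]] <- res
  }
  structure(
    list(tests = tests, n_vectors = nrow(object$vectors$vectors),
         n_comparisons = nrow(object$angles), d = object$d,
         mean_angle = mean(angles), mean_length = mean(object$vectors$lengths),
         design_kind = attr(object$design, "kind")),
    class = "summary.cva"
  )
}

#' @export
print.summary.cva <- function(x, digits = 4, ...) {
  cat(sprintf("Change-vector analysis: %d vectors, %d comparisons, d = %d (%s design)\n",
              x$n_vectors, x$n_comparisons, x$d, x$design_kind))
  cat(sprintf("  mean angle %.*f deg (90 = no parallelism), mean length %.*f\n\n",
              digits, x$mean_angle, digits, x$mean_length))
  for (t in x$tests) {
    cat(sprintf("  %-14s statistic = %.*g  p = %.*g  (n = %d)\n",
                t$method, digits, t$statistic, digits, t$p_value, t$n))
  }
  invisible(x)
}

#' Plot the angle distribution of a fitted change-vector analysis
#'
#' Histogram of pairwise angles with the 90-degree non-parallelism
#' reference marked.
#' @param x A `cva` fit.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.cva <- function(x, ...) {
  a <- x$angles$theta_deg
  graphics::hist(a, breaks = seq(0, 180, by = 10),
                 main = "Pairwise angles between change-vectors",
                 xlab = "angle (degrees)", col = "grey85", border = "white", ...)
  graphics::abline(v = 90, lty = 2, col = "red3")
  graphics::abline(v = mean(a), lwd = 2, col = "steelblue4")
  invisible(x)
}
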