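# Internal helpers shared across the package.

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Row-major unordered pair index for k items: (1,2),(1,3),...,(2,3),...
.pair_index <- function(k) {
  i <- rep.int(seq_len(k - 1L), times = (k - 1L):1L)
  j <- unlist(lapply(seq_len(k - 1L), function(a) (a + 1L):k), use.names = FALSE)
  cbind(i = i, j = j)
}

.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m * m))
  if (any(nrm < 1e-12)) {
    .cv_error("zero-length vector cannot be normalized", "cv_degenerate_error")
  }
  m / nrm
}

# Angle between two vectors in degrees, dot product clamped to [-1, 1]
# so that numerically coincident / antipodal vectors give exactly 0 / 180.
.angle_deg <- function(v, w) {
  ct <- sum(v * w) / sqrt(sum(v * v) * sum(w * w))
  acos(.clamp(ct, -1, 1)) * 180 / pi
}

# Uniformly random rotation (special orthogonal matrix) via QR with the
# sign of diag(R) fixed; determinant forced to +1.
.random_rotation <- function(d) {
  qrd <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))), d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Classed errors so callers/tests can distinguish failure modes.
.cv_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "changevec_error", "error", "condition")))
}

.assert_scalar_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    .cv_error(sprintf("%s must be a single positive number", what), "cv_value_error")
  }
}

# Sub-seed derivation: one user seed fans out into deterministic substreams
# (kept well below 2^31).
.sub_seed <- function(seed, stream) {
  (as.integer(seed) + 1000003L * as.integer(stream)) %% 2147483587L
}

# Ordination identity tokens: angles are only meaningful between vectors that
# share one ordination basis; mixing bases is a hard error.
.ord_counter <- local({
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  function() {
    env$n <- env$n + 1L
    sprintf("ordination-%d", env$n)
  }
})
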