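# Synthetic-data generators with known ground truth: exact-angle vector
# fans for geometry oracles, Gaussian ordination clouds for estimator
# recovery, and Dirichlet-multinomial count tables for end-to-end runs.

#' Scenario specification for the simulators
#'
#' Collects the knobs shared by [simulate_ordination_groups()] and
#' [simulate_count_tables()]. Defaults describe a strong, clearly resolved
#' scenario: 4 population pairs of 50 samples each, within-group
#' dispersion 1 against a centroid shift of 5 (in latent space the shift
#' is in coordinate units; in count space it is the log-fold change of
#' the shifted features), 200 features sequenced to depth 10,000 under a
#' Dirichlet-multinomial with per-feature concentration 0.5.
#'
#' @param pairs_per_system Number of population pairs (= change-vectors).
#' @param n_per_group Samples per population.
#' @param d Latent dimensionality (ordination simulator).
#' @param n_features Number of features (count simulator).
#' @param shift_magnitude Per-pair centroid displacement (latent units) /
#'   log-fold feature shift (count simulator).
#' @param parallelism_mode `"parallel"`, `"orthogonal"`, `"antiparallel"`
#'   or `"random"`: geometry of the true change directions.
#' @param dispersion Within-group spread (latent space sd / extra log-scale
#'   baseline noise among populations in count space).
#' @param overlap In `"parallel"` count scenarios: per-feature probability
#'   that a pair reuses the first pair's shifted feature set.
#' @param depth Sequencing depth per sample (count simulator).
#' @param concentration Dirichlet-multinomial per-feature concentration.
#' @param seed Integer seed; one seed determines the whole scenario.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(pairs_per_system = 4L, n_per_group = 50L, d = 10L,
                          n_features = 200L, shift_magnitude = 5,
                          parallelism_mode = c("parallel", "orthogonal", "antiparallel", "random"),
                          dispersion = 1, overlap = 1, depth = 10000L,
                          concentration = 0.5, seed = 1L) {
  parallelism_mode <- match.arg(parallelism_mode)
  if (n_per_group < 1L) .cv_error("n_per_group must be >= 1", "cv_value_error")
  if (shift_magnitude < 0) .cv_error("shift_magnitude must be >= 0", "cv_value_error")
  if (overlap < 0 || overlap > 1) .cv_error("overlap must be in [0, 1]", "cv_value_error")
  structure(
    list(pairs_per_system = as.integer(pairs_per_system),
         n_per_group = as.integer(n_per_group), d = as.integer(d),
         n_features = as.integer(n_features), shift_magnitude = shift_magnitude,
         parallelism_mode = parallelism_mode, dispersion = dispersion,
         overlap = overlap, depth = as.integer(depth),
         concentration = concentration, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Construct a planar vector fan with prescribed pairwise angles
#'
#' Builds `k` vectors lying in a plane embedded in `d` dimensions whose
#' pairwise angles reproduce `target_angles` essentially exactly (within
#' 1e-9 degrees), serving as an oracle for the angle operator. The fan is
#' laid out by solving ray positions from the pairwise targets; planar
#' unit vectors use `cospi`/`sinpi` so that right angles and antipodal
#' pairs are represented exactly. By default the plane is the first two
#' coordinate axes (zero-padded embedding, which preserves angles
#' exactly); `rotate = TRUE` additionally applies a seeded random
#' orthogonal rotation of the full space.
#'
#' @param k Number of vectors (>= 2).
#' @param d Embedding dimensionality (>= 2).
#' @param target_angles Either `choose(k, 2)` pairwise angles in row-major
#'   pair order ((1,2), (1,3), ..., (2,3), ...) or `k` ray angles measured
#'   from the first vector (first entry 0); degrees, each in \[0, 180\].
#' @param lengths Vector lengths (recycled to `k`; default 1).
#' @param rotate Apply a random orthogonal rotation (seeded).
#' @param seed Seed for the rotation (only used when `rotate = TRUE`).
#' @return A `change_vectors` object with ids `v1..vk`.
#' @export
make_vector_fan <- function(k, d, target_angles, lengths = 1, rotate = FALSE, seed = 1L) {
  if (k < 2L) .cv_error("need k >= 2", "cv_value_error")
  if (d < 2L) .cv_error("need d >= 2", "cv_value_error")
  if (any(target_angles < 0 | target_angles > 180)) {
    .cv_error("target angles must lie in [0, 180] degrees", "cv_value_error")
  }
  npairs <- choose(k, 2L)
  if (length(target_angles) == k && target_angles[1] == 0) {
    phi <- target_angles
  } else if (length(target_angles) == npairs) {
    phi <- .solve_fan_positions(k, target_angles)
  } else {
    .cv_error(sprintf("target_angles must have length %d (pairwise) or %d (ray positions)",
                      npairs, k), "cv_value_error")
  }
  lengths <- rep_len(lengths, k)
  v <- matrix(0, k, d)
  v[, 1L] <- lengths * cospi(phi / 180)
  v[, 2L] <- lengths * sinpi(phi / 180)
  if (rotate) {
    set.seed(as.integer(seed))
    v <- v %*% t(.random_rotation(d))
  }
  rownames(v) <- paste0("v", seq_len(k))
  structure(
    list(vectors = v, lengths = lengths, from = rep(NA_character_, k),
         to = rep(NA_character_, k), d = d, ord_token = "synthetic-fan"),
    class = "change_vectors"
  )
}

# Solve planar ray positions phi (degrees) from pairwise angle targets.
# phi_1 = 0; phi_j = +/- theta(1, j), signs chosen to satisfy the
# remaining constraints; inconsistent targets raise a construction error.
.solve_fan_positions <- function(k, targets) {
  pr <- .pair_index(k)
  theta <- function(i, j) targets[which(pr[, 1L] == min(i, j) & pr[, 2L] == max(i, j))]
  planar_angle <- function(a, b) {
    x <- abs(a - b) %% 360
    min(x, 360 - x)
  }
  phi <- numeric(k)
  phi[2L] <- theta(1L, 2L)
  tol <- 1e-9
  for (j in seq_len(k)[-(1:2)]) {
    placed <- FALSE
    for (cand in c(theta(1L, j), -theta(1L, j))) {
      ok <- all(vapply(seq_len(j - 1L), function(i) {
        abs(planar_angle(phi[i], cand) - theta(i, j)) <= tol
      }, logical(1L)))
      if (ok) {
        phi[j] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) .cv_error("inconsistent target angle set: not realizable by a planar fan", "cv_value_error")
  }
  phi
}

#' Simulate group clouds in a latent ordination space
#'
#' Places pairs of population centroids so that the true change-vector
#' geometry matches `parallelism_mode` (parallel: all pair directions
#' identical; orthogonal: mutually orthogonal; antiparallel: alternating
#' opposite; random: uniform random directions), then draws each sample
#' from a spherical Gaussian (`sd = dispersion`) around its population
#' centroid. "From" centroids are scattered randomly so pairs do not share
#' a base point.
#'
#' @param spec A [scenario_spec()].
#' @return List with `coordinates` (samples x d, row names = sample ids),
#'   `metadata`, `design`, `true_vectors` (k x d), `true_angles` (the
#'   pairwise angle table of the true vectors).
#' @export
simulate_ordination_groups <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  k <- spec$pairs_per_system
  d <- spec$d
  if (spec$parallelism_mode == "orthogonal" && k > d) {
    .cv_error("orthogonal mode needs at least as many dimensions as pairs", "cv_value_error")
  }
  set.seed(spec$seed)
  dirs <- switch(spec$parallelism_mode,
    parallel = matrix(rep(c(1, numeric(d - 1L)), each = k), k, d),
    orthogonal = diag(1, k, d),
    antiparallel = outer(ifelse(seq_len(k) %% 2L == 1L, 1, -1), c(1, numeric(d - 1L))),
    random = .unit_rows(matrix(stats::rnorm(k * d), k, d))
  )
  true_vectors <- spec$shift_magnitude * dirs
  rownames(true_vectors) <- paste0("v", seq_len(k))
  from_cent <- matrix(stats::rnorm(k * d, sd = spec$shift_magnitude), k, d)
  to_cent <- from_cent + true_vectors
  n <- spec$n_per_group
  coords <- matrix(NA_real_, 2L * k * n, d)
  sample_id <- character(2L * k * n)
  population <- character(2L * k * n)
  ecotype <- character(2L * k * n)
  row <- 0L
  for (p in seq_len(k)) {
    for (side in c("A", "B")) {
      cent <- if (side == "A") from_cent[p, ] else to_cent[p, ]
      idx <- row + seq_len(n)
      noise <- if (spec$dispersion > 0) {
        matrix(stats::rnorm(n * d, sd = spec$dispersion), n, d)
      } else matrix(0, n, d)
      coords[idx, ] <- matrix(cent, n, d, byrow = TRUE) + noise
      sample_id[idx] <- sprintf("s%04d", idx)
      population[idx] <- sprintf("pair%d_%s", p, side)
      ecotype[idx] <- side
      row <- row + n
    }
  }
  rownames(coords) <- sample_id
  metadata <- data.frame(sample_id = sample_id, system = "system1",
                         population = population, ecotype = ecotype,
                         stringsAsFactors = FALSE)
  design <- validate_design(data.frame(
    vector_id = paste0("v", seq_len(k)),
    from_group = sprintf("pair%d_A", seq_len(k)),
    to_group = sprintf("pair%d_B", seq_len(k)),
    stringsAsFactors = FALSE
  ))
  list(coordinates = coords, metadata = metadata, design = design,
       true_vectors = true_vectors,
       true_angles = if (k >= 2L) pairwise_angles(true_vectors) else NULL)
}

#' Simulate Dirichlet-multinomial count tables with controlled parallelism
#'
#' Emulates processed amplicon data for a multi-pair study system: per
#' population a Dirichlet-multinomial count model around a shared baseline
#' composition; "to" populations receive log-fold shifts
#' (`shift_magnitude`) on a subset of features (10% of features). In
#' `"parallel"` mode each later pair reuses the first pair's shifted set
#' feature-by-feature with probability `overlap` (replacements drawn from
#' the unshifted features); `"orthogonal"` uses disjoint feature sets;
#' `"antiparallel"` shifts the same features with alternating sign;
#' `"random"` draws a fresh random subset and sign per pair. Taxonomy
#' strings are generated from a consistent seven-rank hierarchy so that
#' taxonomic collapse can be exercised at every level.
#'
#' @param spec A [scenario_spec()].
#' @return List with `counts` (features x samples), `taxonomy` (named
#'   list), `metadata`, `design`, `shifted_features` (list per pair),
#'   `true_log_effects` (features x pairs signed log-fold matrix).
#' @export
simulate_count_tables <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$n_features
  if (m < 10L) .cv_error("need n_features >= 10", "cv_value_error")
  if (spec$depth < m) .cv_error("depth too small for the number of features", "cv_value_error")
  k <- spec$pairs_per_system
  n <- spec$n_per_group
  set.seed(spec$seed)
  base <- exp(stats::rnorm(m, sd = 1))
  base <- base / sum(base)
  n_shift <- max(2L, round(0.1 * m))
  s1 <- sort(sample.int(m, n_shift))
  pool <- setdiff(seq_len(m), s1)
  shifted <- vector("list", k)
  sign_of <- numeric(k)
  for (p in seq_len(k)) {
    if (p == 1L) {
      shifted[[p]] <- s1
      sign_of[p] <- 1
    } else {
      switch(spec$parallelism_mode,
        parallel = {
          keep <- stats::runif(n_shift) < spec$overlap
          repl <- if (any(!keep)) sample(pool, sum(!keep)) else integer(0)
          shifted[[p]] <- sort(c(s1[keep], repl))
          sign_of[p] <- 1
        },
        orthogonal = {
          avail <- setdiff(seq_len(m), unlist(shifted))
          if (length(avail) < n_shift) .cv_error("not enough features for disjoint shifted sets", "cv_value_error")
          shifted[[p]] <- sort(sample(avail, n_shift))
          sign_of[p] <- 1
        },
        antiparallel = {
          shifted[[p]] <- s1
          sign_of[p] <- if (p %% 2L == 1L) 1 else -1
        },
        random = {
          shifted[[p]] <- sort(sample.int(m, n_shift))
          sign_of[p] <- sample(c(-1, 1), 1L)
        }
      )
    }
  }
  if (spec$parallelism_mode == "antiparallel") sign_of[1L] <- 1
  true_log_effects <- matrix(0, m, k, dimnames = list(NULL, paste0("v", seq_len(k))))
  for (p in seq_len(k)) true_log_effects[shifted[[p]], p] <- sign_of[p] * spec$shift_magnitude

  feature_ids <- sprintf("feat%04d", seq_len(m))
  pops <- as.vector(t(outer(seq_len(k), c("A", "B"), function(p, s) sprintf("pair%d_%s", p, s))))
  # per-population composition: shared baseline, mild population-specific
  # baseline wobble, plus the designed shifts on "B" populations
  pop_pi <- list()
  for (p in seq_len(k)) {
    for (side in c("A", "B")) {
      lp <- log(base) + stats::rnorm(m, sd = 0.05 * spec$dispersion)
      if (side == "B") lp <- lp + true_log_effects[, p]
      pi_ <- exp(lp)
      pop_pi[[sprintf("pair%d_%s", p, side)]] <- pi_ / sum(pi_)
    }
  }
  counts <- matrix(0L, m, length(pops) * n,
                   dimnames = list(feature_ids, sprintf("s%04d", seq_len(length(pops) * n))))
  sample_pop <- character(ncol(counts))
  col <- 0L
  for (pop in pops) {
    alpha <- spec$concentration * m * pop_pi[[pop]]
    for (i in seq_len(n)) {
      col <- col + 1L
      g <- stats::rgamma(m, shape = alpha)
      if (sum(g) == 0) g <- rep(1, m)
      counts[, col] <- stats::rmultinom(1L, spec$depth, g / sum(g))
      sample_pop[col] <- pop
    }
  }
  metadata <- data.frame(sample_id = colnames(counts), system = "system1",
                         population = sample_pop,
                         ecotype = sub("^pair[0-9]+_", "", sample_pop),
                         stringsAsFactors = FALSE)
  design <- validate_design(data.frame(
    vector_id = paste0("v", seq_len(k)),
    from_group = sprintf("pair%d_A", seq_len(k)),
    to_group = sprintf("pair%d_B", seq_len(k)),
    stringsAsFactors = FALSE
  ))
  taxonomy <- .synthetic_taxonomy(feature_ids)
  list(counts = counts, taxonomy = taxonomy, metadata = metadata, design = design,
       shifted_features = lapply(shifted, function(s) feature_ids[s]),
       true_log_effects = true_log_effects)
}

# Seven-rank nested hierarchy over the feature list: 4 phyla, 2 classes per
# phylum, 2 orders per class, and so on; species unique per feature.
.synthetic_taxonomy <- function(feature_ids) {
  m <- length(feature_ids)
  i <- seq_len(m) - 1L
  phy <- i %% 4L
  cls <- phy * 2L + (i %/% 4L) %% 2L
  ord <- cls * 2L + (i %/% 8L) %% 2L
  fam <- ord * 2L + (i %/% 16L) %% 2L
  gen <- fam * 2L + (i %/% 32L) %% 2L
  tax <- lapply(seq_len(m), function(j) {
    c("Bacteria",
      sprintf("Phylum%02d", phy[j] + 1L),
      sprintf("Class%02d", cls[j] + 1L),
      sprintf("Order%02d", ord[j] + 1L),
      sprintf("Family%02d", fam[j] + 1L),
      sprintf("Genus%02d", gen[j] + 1L),
      sprintf("Species_%s", feature_ids[j]))
  })
  names(tax) <- feature_ids
  tax
}

#' Write a simulated count scenario to disk
#'
#' Emits the feature table, taxonomy, metadata and design in the package's
#' TSV dialects plus a ground-truth TSV of per-pair shifted features.
#'
#' @param sim Result of [simulate_count_tables()].
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_feature_table(sim$counts, file.path(dir, "feature_table.tsv")),
    write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv")),
    write_metadata(sim$metadata, file.path(dir, "metadata.tsv")),
    write_design(sim$design, file.path(dir, "design.tsv"))
  )
  vec_ids <- paste0("v", seq_along(sim$shifted_features))
  truth <- data.frame(
    vector_id = rep(vec_ids, lengths(sim$shifted_features)),
    feature_id = unlist(sim$shifted_features),
    log_effect = unlist(lapply(seq_along(sim$shifted_features), function(p) {
      sim$true_log_effects[match(sim$shifted_features[[p]], rownames(sim$counts)), p]
    }))
  )
  tp <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tp))
}
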