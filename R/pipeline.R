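# Workflow orchestration: one config (list or YAML file) drives
# rarefaction -> taxonomic collapse -> distance -> PCoA -> change-vectors
# -> angles -> significance tests -> TSV outputs + a run manifest.

.default_config <- list(
  feature_table = NULL, taxonomy = NULL, metadata = NULL, design = NULL,
  distance_matrix = NULL, metric = "bray_curtis", n_axes = NULL,
  rarefaction_depth = NULL, taxonomy_level = NULL, grouping = "population",
  methods = "all", iterations = 100000L, seed = NULL, output_dir = NULL
)

#' Read / normalize a run configuration
#'
#' @param config A named list of options or the path to a YAML file with
#'   the same keys. Recognized keys: `feature_table`, `taxonomy`,
#'   `metadata`, `design`, `distance_matrix`, `metric` (`"bray_curtis"`
#'   or `"precomputed"`), `n_axes`, `rarefaction_depth`, `taxonomy_level`,
#'   `grouping`, `methods`, `iterations`, `seed`, `output_dir`.
#' @param overrides Named list of values that win over the file (mirrors
#'   CLI flags).
#' @return The merged, validated configuration list.
#' @export
read_run_config <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .cv_error(sprintf("config file not found: %s", config), "cv_format_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .cv_error("config must be a list or a YAML file path", "cv_format_error")
  cfg <- .default_config
  for (k in names(config)) cfg[[k]] <- config[[k]]
  for (k in names(overrides)) if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  unknown <- setdiff(names(config), names(.default_config))
  if (length(unknown)) .cv_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                                 "cv_format_error")
  if (!cfg$metric %in% c("bray_curtis", "precomputed")) {
    .cv_error("metric must be 'bray_curtis' or 'precomputed'", "cv_value_error")
  }
  # all referenced files must exist before any compute starts
  for (k in c("feature_table", "taxonomy", "metadata", "design", "distance_matrix")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      .cv_error(sprintf("config: %s file not found: %s", k, cfg[[k]]), "cv_format_error")
    }
  }
  if (is.null(cfg$metadata)) .cv_error("config: metadata path is required", "cv_format_error")
  if (is.null(cfg$design)) .cv_error("config: design path is required", "cv_format_error")
  if (cfg$metric == "precomputed" && is.null(cfg$distance_matrix)) {
    .cv_error("config: metric 'precomputed' needs a distance_matrix path", "cv_format_error")
  }
  if (cfg$metric == "bray_curtis" && is.null(cfg$feature_table)) {
    .cv_error("config: metric 'bray_curtis' needs a feature_table path", "cv_format_error")
  }
  stochastic <- !is.null(cfg$rarefaction_depth) ||
    any(cfg$methods %in% c("all", "mc"))
  if (stochastic && is.null(cfg$seed)) {
    .cv_error("config: seed is required when rarefaction or the Monte-Carlo test is selected",
              "cv_value_error")
  }
  cfg
}

#' Run the full change-vector analysis pipeline from a configuration
#'
#' Executes (optional rarefaction) -> (optional taxonomy collapse) ->
#' distance -> PCoA -> centroids -> change-vectors -> pairwise angles ->
#' the selected parallelism tests, writes `angles.tsv` / `tests.tsv` and
#' a JSON run manifest when `output_dir` is set, and returns everything.
#' With the same config and seed all output files are reproduced
#' bit-for-bit.
#'
#' @param config See [read_run_config()].
#' @param overrides Named list of config overrides.
#' @return (Invisibly) a list with `fit` (the [cva()] object), `tests`,
#'   `angles`, `config`, and `files` (paths written, or `NULL`).
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- read_run_config(config, overrides)
  metadata <- read_metadata(cfg$metadata)
  design <- read_design(cfg$design)
  dropped <- character(0)
  if (cfg$metric == "precomputed") {
    dm <- read_distance_matrix(cfg$distance_matrix)
    ord <- pcoa(dm, n_axes = cfg$n_axes)
  } else {
    counts <- read_feature_table(cfg$feature_table)
    if (!is.null(cfg$rarefaction_depth)) {
      counts <- rarefy(counts, cfg$rarefaction_depth, seed = cfg$seed)
      dropped <- attr(counts, "dropped")
    }
    if (!is.null(cfg$taxonomy_level)) {
      if (is.null(cfg$taxonomy)) .cv_error("taxonomy_level set but no taxonomy path", "cv_format_error")
      tax <- read_taxonomy(cfg$taxonomy)
      counts <- collapse_taxonomy(counts, tax, cfg$taxonomy_level)
    }
    ord <- pcoa(bray_curtis(counts), n_axes = cfg$n_axes)
  }
  message(sprintf("pipeline: %d samples, %d retained axes, negative eigenvalue mass %.4g",
                  nrow(ord$points), ord$d,
                  if (is.na(ord$negative_mass)) 0 else ord$negative_mass))
  fit <- cva(ord, metadata, design, grouping = cfg$grouping)
  smry <- summary(fit, methods = cfg$methods, iterations = cfg$iterations, seed = cfg$seed)
  files <- NULL
  if (!is.null(cfg$output_dir)) {
    files <- write_results(fit$angles, smry$tests, cfg$output_dir)
    manifest <- list(
      config = cfg[!vapply(cfg, is.null, logical(1L))],
      package_version = as.character(utils::packageVersion("changevec")),
      n_samples = nrow(ord$points), retained_axes = ord$d,
      negative_eigenvalue_mass = ord$negative_mass,
      dropped_samples = as.list(dropped)
    )
    mp <- file.path(cfg$output_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, mp)
  }
  invisible(list(fit = fit, summary = smry, tests = smry$tests,
                 angles = fit$angles, config = cfg, files = files))
}

#' Repeat the analysis across taxonomic levels
#'
#' Collapses the feature table at each requested level, reruns
#' distance -> PCoA -> change-vector analysis, and collects all angles
#' and lengths in one long-format table for cross-level comparison.
#' Levels at which fewer than two features survive are skipped with a
#' warning.
#'
#' @param config See [read_run_config()]; `feature_table` and `taxonomy`
#'   are required.
#' @param levels Levels to sweep (default all six, phylum..species).
#' @return (Invisibly) a list with `angles` (long data frame with a
#'   `level` column), `summary` (per-level mean angle / meanL), `fits`.
#'   When `output_dir` is set, writes `taxon_sweep.tsv`.
#' @export
taxon_level_sweep <- function(config,
                              levels = c("phylum", "class", "order", "family", "genus", "species")) {
  cfg <- read_run_config(config, list(methods = character(0)))
  if (is.null(cfg$feature_table) || is.null(cfg$taxonomy)) {
    .cv_error("taxon_level_sweep needs feature_table and taxonomy paths", "cv_format_error")
  }
  metadata <- read_metadata(cfg$metadata)
  design <- read_design(cfg$design)
  counts <- read_feature_table(cfg$feature_table)
  if (!is.null(cfg$rarefaction_depth)) counts <- rarefy(counts, cfg$rarefaction_depth, seed = cfg$seed)
  tax <- read_taxonomy(cfg$taxonomy)
  out <- list()
  fits <- list()
  for (lv in levels) {
    collapsed <- collapse_taxonomy(counts, tax, lv)
    if (nrow(collapsed) < 2L) {
      warning(sprintf("level '%s' has fewer than 2 features after collapse; skipped", lv))
      next
    }
    fit <- cva(pcoa(bray_curtis(collapsed), n_axes = cfg$n_axes), metadata, design,
               grouping = cfg$grouping)
    a <- fit$angles
    a$level <- lv
    out[[lv]] <- a
    fits[[lv]] <- fit
  }
  if (!length(out)) .cv_error("no taxonomic level produced a usable table", "cv_value_error")
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  smry <- data.frame(
    level = names(out),
    n_features = vapply(names(out), function(lv) nrow(collapse_taxonomy(counts, tax, lv)), integer(1L)),
    mean_angle = vapply(out, function(a) mean(a$theta_deg), numeric(1L)),
    mean_meanL = vapply(out, function(a) mean(a$meanL), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(long, file.path(cfg$output_dir, "taxon_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(angles = long, summary = smry, fits = fits))
}
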