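# Fixture builders used across the suite; everything is generated in code.

tiny_table <- function() {
  matrix(c(2, 1, 2, 3, 0, 0), nrow = 3, byrow = TRUE,
         dimnames = list(c("f1", "f2", "f3"), c("sA", "sB")))
}

meta_for <- function(sample_ids, population, system = "sys1", ecotype = NULL) {
  if (is.null(ecotype)) ecotype <- population
  data.frame(sample_id = sample_ids, system = system,
             population = population, ecotype = ecotype,
             stringsAsFactors = FALSE)
}

design_for <- function(from, to, ids = paste0("v", seq_along(from))) {
  validate_design(data.frame(vector_id = ids, from_group = from, to_group = to,
                             stringsAsFactors = FALSE))
}

# Euclidean distance matrix of a coordinate configuration (oracle for PCoA).
euclid_dm <- function(coords) {
  m <- as.matrix(dist(coords))
  dimnames(m) <- list(rownames(coords), rownames(coords))
  m
}

# Brute-force Bray-Curtis of two abundance profiles (formula oracle).
bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)
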