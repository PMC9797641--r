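# Simulators: exact-angle fans, latent Gaussian clouds, and
# Dirichlet-multinomial count scenarios with controlled parallel structure.

test_that("vector fans reproduce prescribed pairwise angles essentially exactly", {
  # k = 2 special cases
  expect_equal(pairwise_angles(make_vector_fan(2, 3, 0))$theta_deg, 0, tolerance = 1e-9)
  expect_equal(pairwise_angles(make_vector_fan(2, 5, 90))$theta_deg, 90, tolerance = 1e-9)
  expect_equal(pairwise_angles(make_vector_fan(2, 4, 180))$theta_deg, 180, tolerance = 1e-9)
  # fan at rays 0/30/90 from its pairwise target set {30, 90, 60}
  f <- make_vector_fan(3, 6, c(30, 90, 60))
  expect_equal(pairwise_angles(f)$theta_deg, c(30, 90, 60), tolerance = 1e-9)
  # inconsistent target set is rejected
  expect_error(make_vector_fan(3, 4, c(30, 40, 170)), class = "cv_value_error")
  expect_error(make_vector_fan(2, 3, 200), class = "cv_value_error")
})

test_that("fan construction composed with the angle operator is the identity", {
  set.seed(77)
  for (rep_ in 1:10) {
    k <- sample(3:5, 1)
    # realizable by construction: random rays in [0, 180]
    rays <- c(0, sort(runif(k - 1, 0, 180)))
    targets <- pairwise_angles(make_vector_fan(k, 8, rays))$theta_deg
    rebuilt <- make_vector_fan(k, 8, targets)
    expect_equal(pairwise_angles(rebuilt)$theta_deg, targets, tolerance = 1e-9)
  }
  # rotation embedding preserves the targets to numerical precision
  rot <- make_vector_fan(3, 10, c(30, 90, 60), rotate = TRUE, seed = 3)
  expect_equal(pairwise_angles(rot)$theta_deg, c(30, 90, 60), tolerance = 1e-6)
})

test_that("latent group simulation recovers true geometry when dispersion vanishes", {
  spec <- scenario_spec(pairs_per_system = 3, n_per_group = 5, d = 6,
                        dispersion = 0, parallelism_mode = "orthogonal", seed = 2)
  sim <- simulate_ordination_groups(spec)
  fit <- cva(sim$coordinates, sim$metadata, sim$design, input = "coordinates")
  expect_equal(coef(fit), sim$true_vectors, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$angles$theta_deg, sim$true_angles$theta_deg, tolerance = 1e-9)
  expect_equal(fit$angles$theta_deg, rep(90, 3))
})

test_that("centroid estimation converges on the generating geometry", {
  spec <- scenario_spec(pairs_per_system = 2, n_per_group = 200, d = 8,
                        dispersion = 1, shift_magnitude = 5,
                        parallelism_mode = "parallel", seed = 11)
  sim <- simulate_ordination_groups(spec)
  fit <- cva(sim$coordinates, sim$metadata, sim$design, input = "coordinates")
  expect_lt(fit$angles$theta_deg, 5)           # true angle 0
  spec_o <- scenario_spec(pairs_per_system = 4, n_per_group = 200, d = 8,
                          dispersion = 1, shift_magnitude = 5,
                          parallelism_mode = "orthogonal", seed = 12)
  sim_o <- simulate_ordination_groups(spec_o)
  fit_o <- cva(sim_o$coordinates, sim_o$metadata, sim_o$design, input = "coordinates")
  expect_lt(abs(mean(fit_o$angles$theta_deg) - 90), 5)
  # antiparallel pairs sit on the anti-parallel side
  spec_a <- scenario_spec(pairs_per_system = 2, n_per_group = 200, d = 8,
                          parallelism_mode = "antiparallel", seed = 13)
  sim_a <- simulate_ordination_groups(spec_a)
  fit_a <- cva(sim_a$coordinates, sim_a$metadata, sim_a$design, input = "coordinates")
  expect_gt(fit_a$angles$theta_deg, 175)
})

test_that("count tables are deterministic, valid and taxonomy is nested", {
  spec <- scenario_spec(pairs_per_system = 2, n_per_group = 6, n_features = 40,
                        depth = 1000, seed = 21)
  sim1 <- simulate_count_tables(spec)
  sim2 <- simulate_count_tables(spec)
  expect_identical(sim1$counts, sim2$counts)
  expect_true(all(colSums(sim1$counts) == 1000))
  expect_true(all(sim1$counts >= 0))
  expect_equal(length(sim1$taxonomy), 40L)
  expect_true(all(lengths(sim1$taxonomy) == 7L))
  # ranks nest: equal genus implies equal family and above
  tx <- sim1$taxonomy
  for (a in seq(1, 39, by = 7)) for (b in seq(2, 40, by = 9)) {
    if (tx[[a]][6] == tx[[b]][6]) expect_identical(tx[[a]][1:5], tx[[b]][1:5])
  }
  expect_error(simulate_count_tables(scenario_spec(n_features = 5)), class = "cv_value_error")
  expect_error(simulate_count_tables(scenario_spec(n_features = 50, depth = 20)),
               class = "cv_value_error")
})

test_that("null count scenario (no shift) centres angles near 90", {
  spec <- scenario_spec(pairs_per_system = 4, n_per_group = 20, n_features = 100,
                        shift_magnitude = 0, depth = 4000, seed = 31)
  sim <- simulate_count_tables(spec)
  fit <- cva(sim$counts, sim$metadata, sim$design, input = "counts")
  expect_lt(abs(mean(fit$angles$theta_deg) - 90), 20)
  expect_gt(t_test_vs_90(fit$angles$theta_deg)$p_value, 0.05)
})

test_that("meanL grows monotonically with the generating shift magnitude", {
  mean_l <- vapply(c(1, 3, 6), function(s) {
    spec <- scenario_spec(pairs_per_system = 3, n_per_group = 8, d = 6,
                          shift_magnitude = s, dispersion = 0.5, seed = 41)
    sim <- simulate_ordination_groups(spec)
    fit <- cva(sim$coordinates, sim$metadata, sim$design, input = "coordinates")
    mean(fit$angles$meanL)
  }, numeric(1))
  expect_true(all(diff(mean_l) > 0))
})

test_that("simulation writer round-trips through the package readers", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec(pairs_per_system = 2, n_per_group = 4, n_features = 30,
                        depth = 500, seed = 51)
  sim <- simulate_count_tables(spec)
  write_simulation(sim, dir)
  counts <- read_feature_table(file.path(dir, "feature_table.tsv"))
  expect_equal(counts, sim$counts + 0)  # reader returns numeric storage
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax, sim$taxonomy)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$population, sim$metadata$population)
  truth <- utils::read.delim(file.path(dir, "ground_truth.tsv"))
  expect_true(all(truth$feature_id %in% rownames(sim$counts)))
})
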