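# Centroids, change-vectors, pairwise angles, and the cva() fit surface.

test_that("group centroids are coordinate means; missing groups are design errors", {
  pts <- matrix(c(0, 0, 2, 0, 1, 3, 5, 5), 4, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), NULL))
  meta <- meta_for(paste0("s", 1:4), c("g1", "g1", "g1", "g2"))
  cent <- group_centroids(pts, meta)
  expect_equal(unname(cent["g1", ]), c(1, 1))      # mean of (0,0),(2,0),(1,3)
  expect_equal(unname(cent["g2", ]), c(5, 5))      # single-sample group
  # symmetric pair straddling the origin
  meta2 <- meta_for(c("s1", "s2"), c("g", "g"))
  pts2 <- matrix(c(3, 0, -3, 0), 2, 2, byrow = TRUE, dimnames = list(c("s1", "s2"), NULL))
  expect_equal(unname(group_centroids(pts2, meta2)["g", ]), c(0, 0))
  expect_error(group_centroids(pts, meta, groups = c("g1", "ghost")),
               class = "cv_design_error")
})

test_that("change vectors are to-minus-from with design direction preserved", {
  cent <- rbind(a = c(0, 0), b = c(3, 4), out = c(1, 1), p1 = c(2, 1), p2 = c(0, 3))
  vs <- change_vectors(cent, design_for("a", "b"))
  expect_equal(unname(vs$vectors["v1", ]), c(3, 4))
  expect_equal(unname(vs$lengths["v1"]), 5)
  # reversing the design reverses the vector, never auto-flipped
  rev_ <- change_vectors(cent, design_for("b", "a"))
  expect_equal(unname(rev_$vectors["v1", ]), c(-3, -4))
  # outgroup design: one shared origin, one vector per focal group
  outg <- change_vectors(cent, design_for(rep("out", 3), c("b", "p1", "p2")))
  expect_equal(nrow(outg$vectors), 3L)
  expect_true(all(outg$from == "out"))
  # coincident centroids produce a degenerate vector
  cent2 <- rbind(a = c(1, 2), b = c(1, 2))
  expect_error(change_vectors(cent2, design_for("a", "b")), class = "cv_degenerate_error")
  expect_error(change_vectors(cent, design_for("a", "missing")), class = "cv_design_error")
})

test_that("pairwise angles reproduce exact geometric constructions", {
  v <- rbind(e1 = c(1, 0), e1b = c(1, 0), diag = c(1, 1), e2 = c(0, 1), neg = c(-1, 0))
  a <- pairwise_angles(v)
  ang <- function(i, j) a$theta_deg[a$vector_id_1 == i & a$vector_id_2 == j]
  expect_equal(ang("e1", "e1b"), 0)
  expect_equal(ang("e1", "neg"), 180)
  expect_equal(ang("e1", "e2"), 90, tolerance = 1e-12)
  expect_equal(ang("e1", "diag"), 45, tolerance = 1e-12)
  expect_equal(nrow(a), choose(5, 2))
  ml <- a$meanL[a$vector_id_1 == "e1" & a$vector_id_2 == "diag"]
  expect_equal(ml, (1 + sqrt(2)) / 2)
})

test_that("angles are scale-invariant, flip to 180 - theta under negation, and rotation-invariant", {
  set.seed(5)
  d <- 6
  v <- matrix(rnorm(4 * d), 4, d)
  base <- pairwise_angles(v)$theta_deg
  # positive rescaling of single vectors
  scl <- v * c(0.01, 7, 1, 120)
  expect_equal(pairwise_angles(scl)$theta_deg, base, tolerance = 1e-9)
  # negating vector 1 maps its angles to 180 - theta
  neg <- v; neg[1, ] <- -neg[1, ]
  flipped <- pairwise_angles(neg)$theta_deg
  involving1 <- 1:3  # row-major pairs (1,2),(1,3),(1,4) come first
  expect_equal(flipped[involving1], 180 - base[involving1], tolerance = 1e-9)
  expect_equal(flipped[-involving1], base[-involving1], tolerance = 1e-12)
  # common orthogonal rotation leaves all angles unchanged
  for (rep_ in 1:5) {
    q <- changevec:::.random_rotation(d)
    expect_equal(pairwise_angles(v %*% q)$theta_deg, base, tolerance = 1e-6)
  }
})

test_that("angle classification arithmetic matches the parallel/orthogonal/anti-parallel reading", {
  v <- rbind(a = c(1, 0.1), b = c(1, -0.1), c = c(0.1, 1), d = c(-1, 0))
  a <- pairwise_angles(v)
  ang <- function(i, j) a$theta_deg[a$vector_id_1 == i & a$vector_id_2 == j]
  expect_lt(ang("a", "b"), 90)   # parallel side
  expect_gt(ang("a", "d"), 90)   # anti-parallel side
  expect_equal(ang("a", "c"), 90, tolerance = 15)  # near-orthogonal
  expect_true(all(a$theta_deg >= 0 & a$theta_deg <= 180))
})

test_that("vector sets from different ordinations cannot be combined", {
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  meta <- meta_for(paste0("s", 1:6), rep(c("a", "b", "c"), each = 2))
  o1 <- as_ordination(pts)
  o2 <- as_ordination(pts + 1)
  v1 <- change_vectors(group_centroids(o1, meta), design_for("a", "b"))
  v2 <- change_vectors(group_centroids(o2, meta), design_for("a", "c", ids = "v9"))
  expect_error(c(v1, v2), class = "cv_value_error")
  v1b <- change_vectors(group_centroids(o1, meta), design_for("a", "c", ids = "v9"))
  both <- c(v1, v1b)
  expect_equal(nrow(both$vectors), 2L)
  expect_equal(nrow(pairwise_angles(both)), 1L)
})

test_that("cva() fits from coordinates, distances and counts consistently", {
  set.seed(13)
  sim <- simulate_ordination_groups(scenario_spec(pairs_per_system = 3, n_per_group = 10,
                                                  d = 4, dispersion = 0.5, seed = 31))
  fit <- cva(sim$coordinates, sim$metadata, sim$design, input = "coordinates")
  expect_s3_class(fit, "cva")
  expect_equal(nrow(fit$angles), 3L)
  expect_equal(coef(fit), fit$vectors$vectors)
  # distance route: PCoA of Euclidean distances preserves the geometry,
  # so angles agree with the direct-coordinate fit
  dm <- euclid_dm(sim$coordinates)
  fit_d <- cva(dm, sim$metadata, sim$design)
  expect_equal(fit_d$angles$theta_deg, fit$angles$theta_deg, tolerance = 1e-6)
  expect_equal(fit_d$angles$meanL, fit$angles$meanL, tolerance = 1e-6)
  expect_output(print(fit), "Change-vector analysis")
})

test_that("one vector or degenerate designs are rejected", {
  v <- matrix(c(1, 0), 1, 2)
  expect_error(pairwise_angles(v), class = "cv_value_error")
})
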