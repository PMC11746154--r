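test_that("kabsch: identity, exact recovery and input validation", {
  set.seed(1)
  X <- matrix(stats::rnorm(18), 6, 3)
  k0 <- kabsch(X, X)
  expect_equal(k0$rmsd, 0, tolerance = 1e-12)
  expect_equal(k0$transform$rotation, diag(3), tolerance = 1e-9)
  t0 <- rt_translation(c(1, 2, 3)) %o% rt_rotation_z(90)
  Y <- rt_apply(t0, X)
  k <- kabsch(X, Y)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(k$transform$rotation, rt_inverse(t0)$rotation, tolerance = 1e-9)
  expect_error(kabsch(X, X[1:5, ]), "counts differ")
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("kabsch is optimal against a randomized brute-force search", {
  set.seed(42)
  for (rep in 1:3) {
    X <- matrix(stats::rnorm(18, sd = 5), 6, 3)
    Y <- matrix(stats::rnorm(18, sd = 5), 6, 3)
    best <- kabsch(X, Y)$rmsd
    # brute force over random rigid transforms, translation set optimally
    # (centroid match) so only the rotation is randomized
    cX <- colMeans(X); cY <- colMeans(Y)
    X0 <- sweep(X, 2, cX); Y0 <- sweep(Y, 2, cY)
    brute <- min(vapply(1:20000, function(i) {
      R <- random_rotation()
      sqrt(mean(rowSums((Y0 %*% t(R) - X0)^2)))
    }, numeric(1)))
    expect_lte(best, brute + 1e-9)
    expect_lt(brute - best, 0.2)   # random search gets close, never below
  }
})

test_that("optimal rmsd is invariant under pre-transforming the mobile set", {
  set.seed(3)
  X <- matrix(stats::rnorm(24, sd = 4), 8, 3)
  Y <- X + matrix(stats::rnorm(24, sd = 0.3), 8, 3)
  base <- kabsch(X, Y)$rmsd
  for (i in 1:5)
    expect_equal(kabsch(X, rt_apply(random_rigid(), Y))$rmsd, base,
                 tolerance = 1e-9)
})

test_that("structure superposition pairs shared C-alphas and matches bio3d", {
  s <- fake_complex()
  self <- superpose_structures(s, s)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$n_pairs, sum(s$atoms$elety == "CA"))
  pp <- make_perturbed_pair(s, sigma = 0.4, seed = 5)
  res <- superpose_structures(pp$fixed, pp$mobile)
  expect_gte(res$rmsd, pp$expected_rmsd_bounds[1])
  expect_lte(res$rmsd, pp$expected_rmsd_bounds[2])
  # independent cross-check of the fitted rmsd against bio3d's fitter
  rb <- bio3d::rot.lsq(xx = as.numeric(t(coords(pp$mobile))),
                       yy = as.numeric(t(coords(pp$fixed))))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(rb, ncol = 3, byrow = TRUE) - coords(pp$fixed))^2)))
  expect_equal(res$rmsd, rmsd_bio3d, tolerance = 1e-6)
  expect_error(superpose_structures(s, build_bform_duplex("ACGTAC")),
               "C-alpha")
})

test_that("helical axis fit: straight duplexes, orientation, elbows", {
  d <- build_bform_duplex(strrep("ACGT", 6))
  ax <- fit_helical_axis(d)
  expect_lt(interaxis_angle(ax, axis_line(c(0, 0, 0), c(0, 0, 1))), 0.5)
  # swapping strand roles flips the reported direction
  ax_rev <- fit_helical_axis(d, chains = c("B", "A"))
  expect_gt(interaxis_angle(ax, ax_rev), 179.5)
  expect_error(fit_helical_axis(build_bform_duplex("ACG")), "4 paired")
  # designed elbow: second duplex bent by 50 deg about y -> oriented axes 50 apart
  d2 <- transform_structure(d, rt_rotation(c(0, 1, 0), 50))
  expect_equal(interaxis_angle(fit_helical_axis(d), fit_helical_axis(d2)), 50,
               tolerance = 1)
})

test_that("interaxis angle and offset have the documented conventions", {
  a <- axis_line(c(0, 0, 0), c(1, 0, 0))
  expect_equal(interaxis_angle(a, a), 0)
  expect_equal(as.numeric(axis_offset(a, a)), 0)
  b <- axis_line(c(0, 0, 0), c(0, 1, 0))
  expect_equal(interaxis_angle(a, b), 90)
  expect_equal(as.numeric(axis_offset(a, b)), 0)
  expect_equal(interaxis_angle(b, a), interaxis_angle(a, b))
  # skew perpendicular lines 5 A apart
  c5 <- axis_line(c(0, 0, 5), c(0, 1, 0))
  expect_equal(as.numeric(axis_offset(a, c5)), 5)
  expect_equal(as.numeric(axis_offset(c5, a)), 5)
  # parallel lines are flagged and report their separation
  par <- axis_line(c(0, 3, 4), c(1, 0, 0))
  off <- axis_offset(a, par)
  expect_true(attr(off, "parallel"))
  expect_equal(as.numeric(off), 5)
})

test_that("atom distances: minimum heavy-atom and CA-CA modes", {
  s <- mmstruct(rbind(
    atom_row("A", 1L, "GLY", "CA", "C", 0, 0, 0),
    atom_row("A", 1L, "GLY", "O", "O", 1, 0, 0),
    atom_row("B", 1L, "GLY", "CA", "C", 0, 0, 7),
    atom_row("B", 1L, "GLY", "N", "N", 0, 0, 4)))
  expect_equal(atom_distance(s, sel(chain = "A"), sel(chain = "B")), 4)
  expect_equal(atom_distance(s, sel(chain = "A"), sel(chain = "B"),
                             mode = "ca-ca"), 7)
  expect_equal(atom_distance(s, sel(chain = "A"), sel(chain = "A")), 0)
  expect_error(suppressWarnings(
    atom_distance(s, sel(chain = "Q"), sel(chain = "B"))), "empty")
  two_ca <- mmstruct(rbind(atom_row("A", 1L, "GLY", "CA", "C", 0, 0, 0),
                           atom_row("A", 2L, "GLY", "CA", "C", 1, 0, 0),
                           atom_row("B", 1L, "GLY", "CA", "C", 5, 0, 0)))
  expect_error(atom_distance(two_ca, sel(chain = "A"), sel(chain = "B"),
                             mode = "ca-ca"), "exactly one")
})
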