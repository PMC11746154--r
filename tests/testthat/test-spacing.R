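# default sphere toy used across the spacing tests: envelope centred
# mid-duplex, clash onset known in closed form
spacing_toy <- function(radius = 8, dna_length = 10, n_atoms = 80) {
  make_toy_complex(dna_length = dna_length, overhang = 2,
                   envelope = envelope_sphere(radius = radius, n_atoms = n_atoms))
}

# independent placement oracle: for an ideal toy (DNA built on the rail
# frames), copy 1 sits at the identity and copy 2 at frame(L-1) o flip
oracle_copy2_transform <- function(L, params)
  helical_frame_at(params, L - 1) %o% rt_rotation(c(1, 0, 0), 180)

test_that("double-end docking follows the helical frame algebra", {
  params <- helix_params()
  toy <- spacing_toy()
  spec <- dock_spec(toy)
  d <- dock_double_end(spec, 30, params)
  expect_lt(max(d$anchor_rmsd), 1e-6)          # ideal toy docks exactly
  expect_lt(max(abs(rt_apply(d$transform1, coords(toy)) - coords(d$copy1))), 1e-12)
  # copy-2 transform equals the direct frame-composition oracle
  o <- oracle_copy2_transform(30, params)
  expect_equal(d$transform2$rotation, o$rotation, tolerance = 1e-6)
  expect_equal(d$transform2$translation, o$translation, tolerance = 1e-6)
  # assembly atom count doubles the complex
  expect_equal(n_atoms(dock_assembly(d)), 2 * n_atoms(toy))
  # one helical period further: same relative orientation, +10 rises apart
  d2 <- dock_double_end(spec, 40, params)
  expect_equal(d2$transform2$rotation, d$transform2$rotation, tolerance = 1e-6)
  shift <- d2$transform2$translation - d$transform2$translation
  expect_equal(sqrt(sum(shift^2)), 10 * params$rise, tolerance = 1e-6)
  expect_equal(d2$relative_rotation, d$relative_rotation, tolerance = 1e-9)
  expect_error(dock_double_end(spec, 5, params), "too short")
})

test_that("scan equals exhaustive placement + all-pairs clash counting", {
  params <- helix_params()
  crit <- clash_criterion(0.6)
  toy <- spacing_toy()
  spec <- dock_spec(toy)
  lengths <- 8:20
  scan <- clash_vs_length_scan(spec, lengths, crit, params)
  env <- select_atoms(toy, sel(resid = "ENV"))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    copy2 <- transform_structure(env, oracle_copy2_transform(L, params))
    expect_identical(scan$n_clashes[i], brute_force_clash_count(env, copy2, crit))
  }
})

test_that("clash onset matches the analytic threshold at both cutoffs", {
  toy <- spacing_toy(radius = 8)
  spec <- dock_spec(toy)
  for (cutoff in c(0.4, 0.6)) {
    scan <- clash_vs_length_scan(spec, 8:30, clash_criterion(cutoff))
    onset <- min(scan$length[scan$n_clashes == 0])
    expect_identical(onset, as.integer(analytic_clash_onset(toy, cutoff)))
    # monotone tail: clash-free stays clash-free beyond the onset
    expect_true(all(scan$n_clashes[scan$length >= onset] == 0))
  }
})

test_that("relative rotation is periodic and classifies co-orientation", {
  toy <- spacing_toy()
  scan <- clash_vs_length_scan(dock_spec(toy), 10:41)
  expect_equal(scan$relative_rotation[scan$length == 21],
               scan$relative_rotation[scan$length == 31])
  expect_true(all(scan$center_to_center - scan$length == 2))
  co <- scan$length[scan$co_oriented]
  expect_true(all(diff(co) == 10))             # round(360 / twist)
  # at 34.3 deg/bp the comb spacing follows the 10.5-bp turn; because the
  # 18-deg tolerance slightly exceeds half the 34.3-deg step, boundary
  # lengths can qualify in adjacent pairs
  scan2 <- clash_vs_length_scan(dock_spec(toy), 10:41,
                                params = helix_params(34.3))
  co2 <- scan2$length[scan2$co_oriented]
  expect_true(all(diff(co2) %in% c(1, 9, 10, 11)))
  runs <- split(co2, cumsum(c(1, diff(co2) > 1)))
  centers <- vapply(runs, mean, numeric(1))
  expect_equal(unname(diff(centers)), rep(10.5, length(centers) - 1),
               tolerance = 0.01)
})

test_that("scan results are invariant under a global rigid transform", {
  toy <- spacing_toy()
  moved <- transform_structure(toy, random_rigid())
  s1 <- clash_vs_length_scan(dock_spec(toy), 10:24)
  s2 <- clash_vs_length_scan(dock_spec(moved), 10:24)
  expect_equal(s1$n_clashes, s2$n_clashes)
  expect_equal(s1$relative_rotation, s2$relative_rotation)
})

test_that("minimum co-oriented clash-free length agrees with brute force", {
  set.seed(21)
  for (radius in c(6, 9, 12)) {
    toy <- spacing_toy(radius = radius)
    scan <- clash_vs_length_scan(dock_spec(toy), 8:45)
    got <- min_cooriented_clashfree(scan)
    brute <- scan$length[scan$relative_rotation <= 18 & scan$n_clashes == 0]
    expect_identical(got$min_length, min(brute))
    expect_identical(got$qualifying, sort(brute))
    expect_gte(got$min_length, analytic_clash_onset(toy, 0.6))
    if (length(brute) > 1) expect_equal(got$step, 10)
  }
  # nothing qualifies inside a range that is all clashing
  toy <- spacing_toy(radius = 20, n_atoms = 120)
  scan <- clash_vs_length_scan(dock_spec(toy), 8:16)
  expect_true(is.na(min_cooriented_clashfree(scan)$min_length))
})
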