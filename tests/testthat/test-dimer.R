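test_that("B-form co-docking: clash-free control, continuous-duplex geometry", {
  # small envelope far from the junction end: clash-free by construction
  toy <- make_toy_complex(dna_length = 12, overhang = 2,
                          envelope = envelope_sphere(radius = 4, center_bp = 9,
                                                     n_atoms = 40))
  cd <- build_bform_codocked_dimer(toy)
  expect_lt(max(cd$anchor_rmsd), 1e-6)
  expect_equal(cd$clashes$n_clashes, 0)
  expect_equal(cd$dna_clashes[[1]]$n_clashes, 0)
  # the two duplexes continue one straight B-form path
  g <- dimer_dna_geometry(cd)
  expect_equal(g$inter_dna_angle, 180, tolerance = 1)
  expect_lt(g$axis_offset, 0.3)
  # envelope crowding the junction produces clashes
  toy2 <- make_toy_complex(dna_length = 12, overhang = 2,
                           envelope = envelope_sphere(radius = 9, center_bp = 1,
                                                      n_atoms = 80))
  cd2 <- build_bform_codocked_dimer(toy2)
  expect_gt(cd2$clashes$n_clashes, 0)
  expect_error(build_bform_codocked_dimer(
    make_toy_complex(dna_length = 12, overhang = 0,
                     envelope = envelope_sphere(radius = 4, n_atoms = 20))),
    "overhang")
})

test_that("templating a structure on itself gives zero RMSD and zero rotation", {
  cplx <- fake_complex()
  tmpl <- fake_template()
  td <- build_topo6_templated_dimer(cplx, tmpl, fake_split(), fake_mapping(),
                                    c("X", "X"))
  expect_equal(td$metrics$rmsd_N, 0, tolerance = 1e-9)
  expect_equal(td$metrics$rmsd_C, 0, tolerance = 1e-9)
  expect_equal(td$metrics$wh_rotation, 0, tolerance = 1e-4)
  expect_equal(td$metrics$n_pairs_N, 20)
  expect_equal(td$metrics$n_pairs_C, 20)
})

test_that("a built-in template domain rotation is recovered as the WH rotation", {
  cplx <- fake_complex()
  for (ang in c(30, 45, 60)) {
    tmpl <- fake_template(c_rotation = ang)
    td <- build_topo6_templated_dimer(cplx, tmpl, fake_split(), fake_mapping(),
                                      c("X", "Y"))
    expect_equal(td$metrics$rmsd_N, 0, tolerance = 1e-9)
    expect_equal(td$metrics$rmsd_C, 0, tolerance = 1e-9)
    expect_equal(td$metrics$wh_rotation, ang, tolerance = 1e-6)
    # consistency: the reported rotation equals rotation_angle(T_N o T_C^-1)
    rel <- rt_compose(td$fits[[1]]$N$transform,
                      rt_inverse(td$fits[[1]]$C$transform))
    expect_equal(td$metrics$wh_rotation, rotation_angle(rel)$angle,
                 tolerance = 1e-9)
  }
})

test_that("templated dimers are deterministic and validate their inputs", {
  cplx <- fake_complex()
  tmpl <- fake_template(c_rotation = 45)
  t1 <- build_topo6_templated_dimer(cplx, tmpl, fake_split(), fake_mapping(),
                                    c("X", "Y"))
  t2 <- build_topo6_templated_dimer(cplx, tmpl, fake_split(), fake_mapping(),
                                    c("X", "Y"))
  expect_identical(coords(t1$copy1), coords(t2$copy1))
  expect_identical(unclass(t1$metrics), unclass(t2$metrics))
  small <- fake_mapping()[c(1, 2, 21, 22), ]
  expect_error(build_topo6_templated_dimer(cplx, tmpl, fake_split(), small,
                                           c("X", "Y")), "fewer than 3")
})

test_that("templating relieves the clashes of the B-form co-docked control", {
  # complex whose envelope crowds the DNA end: codocked copies clash
  toy <- make_toy_complex(dna_length = 12, overhang = 2,
                          envelope = envelope_sphere(radius = 9, center_bp = 1,
                                                     n_atoms = 80))
  cd <- build_bform_codocked_dimer(toy)
  expect_gt(cd$clashes$n_clashes, 0)
  # template: protomer X = the toy itself serialized into one chain,
  # protomer Y = a far-removed two-fold copy, so the templated dimer is
  # open where the co-docked control is crowded
  tmpl1 <- toy$atoms
  tmpl1$chain <- "X"
  tmpl1$resno <- seq_len(nrow(tmpl1))
  tmpl2 <- tmpl1
  tmpl2$chain <- "Y"
  tmpl2[, c("x", "y", "z")] <- rt_apply(
    rt_translation(c(80, 0, 0)) %o% rt_rotation_z(180),
    as.matrix(tmpl1[, c("x", "y", "z")]))
  tmpl <- mmstruct(rbind(tmpl1, tmpl2), id = "open_template")
  env <- sel(resid = "ENV")
  split <- domain_split(part_N = !env, part_C = env)
  rowN <- which(toy$atoms$chain == "A" & toy$atoms$resno %in% 3:10 &
                  toy$atoms$elety == "C1'")
  rowC <- which(toy$atoms$chain == "E" &
                  toy$atoms$resno %in% c(1L, 20L, 40L, 60L, 80L))
  mapping <- rbind(
    data.frame(part = "N", complex_chain = "A",
               complex_resno = toy$atoms$resno[rowN],
               template_resno = rowN, elety = "C1'"),
    data.frame(part = "C", complex_chain = "E",
               complex_resno = toy$atoms$resno[rowC],
               template_resno = rowC, elety = "C"))
  tdA <- build_topo6_templated_dimer(toy, tmpl, split, mapping, c("X", "Y"))
  expect_lt(tdA$clashes$n_clashes, cd$clashes$n_clashes)
  expect_equal(tdA$clashes$n_clashes, 0)
})
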