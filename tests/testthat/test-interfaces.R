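test_that("clash criterion boundary: overlap must reach the cutoff", {
  a <- single_atom(0, 0, 0)                      # carbon, r = 1.70
  expect_equal(count_clashes(a, single_atom(3.40, 0, 0))$n_clashes, 0)
  expect_equal(count_clashes(a, single_atom(2.81, 0, 0))$n_clashes, 0)
  r <- count_clashes(a, single_atom(2.50, 0, 0)) # overlap 0.90 >= 0.6
  expect_equal(r$n_clashes, 1)
  expect_equal(r$pairs$overlap, 0.9, tolerance = 1e-9)
  expect_equal(count_clashes(a, single_atom(2.80, 0, 0))$n_clashes, 1)
})

test_that("cell-list clash counting equals the all-pairs oracle on random clouds", {
  set.seed(99)
  for (rep in 1:3) {
    a <- random_cloud(200, scale = 12)
    b <- random_cloud(200, scale = 12)
    prev <- Inf
    for (cutoff in c(0.0, 0.4, 0.6, 1.0)) {
      crit <- clash_criterion(cutoff)
      got <- count_clashes(a, b, crit)$n_clashes
      expect_identical(got, brute_force_clash_count(a, b, crit))
      expect_identical(got, count_clashes(b, a, crit)$n_clashes)  # symmetric
      expect_lte(got, prev)                       # monotone in cutoff
      prev <- got
    }
  }
})

test_that("clash report pairs all satisfy the criterion and hydrogens are ignored", {
  set.seed(5)
  a <- random_cloud(80, scale = 8)
  b <- random_cloud(80, scale = 8)
  rep <- count_clashes(a, b, clash_criterion(0.6))
  expect_equal(rep$n_clashes, nrow(rep$pairs))
  expect_true(all(rep$pairs$overlap >= 0.6))
  h <- b$atoms; h$elesy <- "H"
  expect_equal(count_clashes(a, mmstruct(h))$n_clashes, 0)
})

test_that("SASA: analytic sphere, additivity, symmetry, determinism", {
  s1 <- single_atom(0, 0, 0)
  total <- attr(sasa(s1), "total")
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(total - analytic) / analytic, 0.01)
  # far-apart atoms are additive
  far <- mmstruct(rbind(atom_row("A", 1L, "ENV", "C", "C", 0, 0, 0),
                        atom_row("A", 2L, "ENV", "C", "C", 100, 0, 0)))
  expect_equal(attr(sasa(far), "total"), 2 * total, tolerance = 1e-9)
  # symmetric diatomic: equal per-atom areas
  dia <- mmstruct(rbind(atom_row("A", 1L, "ENV", "C", "C", 0, 0, 0),
                        atom_row("A", 2L, "ENV", "C", "C", 2.5, 0, 0)))
  ar <- sasa(dia)
  expect_equal(ar[1], ar[2], tolerance = 1e-6)
  expect_lt(ar[1], total)
  # deterministic lattice: identical across calls
  expect_identical(sasa(dia), sasa(dia))
  # occluding atoms only ever reduce the area of existing atoms
  set.seed(8)
  cloud <- random_cloud(40, scale = 6)
  plus <- mmstruct(rbind(cloud$atoms,
                         atom_row("Z", 99L, "ENV", "C", "C", 3, 3, 3,
                                  het = FALSE)))
  expect_lte(sum(sasa(plus)[seq_len(40)]), attr(sasa(cloud), "total") + 1e-9)
})

test_that("buried interface area: symmetry, disjoint bodies, convention", {
  a <- select_atoms(make_toy_complex(dna_length = 6, overhang = 0,
                                     envelope = envelope_sphere(10, n_atoms = 60)),
                    sel(chain = "E"))
  b <- transform_structure(a, rt_translation(c(24, 0, 0)))
  ia <- buried_interface_area(a, b, n_points = 480)
  ib <- buried_interface_area(b, a, n_points = 480)
  expect_equal(ia$area, ib$area, tolerance = 1e-9)
  expect_gt(ia$area, 0)
  expect_equal(ia$area, (ia$sasa_a + ia$sasa_b - ia$sasa_ab) / 2)
  expect_equal(ia$total_buried, 2 * ia$area)
  far <- transform_structure(a, rt_translation(c(100, 0, 0)))
  expect_equal(buried_interface_area(a, far, n_points = 480)$area, 0,
               tolerance = 1e-9)
  expect_warning(buried_interface_area(a, a, n_points = 240), "severe")
})

test_that("contact map classifies hydrogen bonds, salt bridges and ion coordination", {
  cplx <- mmstruct(rbind(
    atom_row("S", 131L, "ARG", "NH1", "N", 0.0, 0, 0),    # salt bridge to OP1
    atom_row("S", 144L, "GLN", "NE2", "N", 20.0, 0, 0),   # hbond to O5'
    atom_row("S", 288L, "ASP", "OD1", "O", 10, 10, 10),   # coordinates MG
    atom_row("S", 290L, "ASP", "OD2", "O", 10, 14.2, 10),
    atom_row("D", 40L, "DG", "OP1", "O", 3.1, 0, 0),
    atom_row("D", 40L, "DG", "O5'", "O", 20.0, 2.7, 0),
    atom_row("M", 1L, "MG", "MG", "MG", 10, 12.1, 10, het = TRUE)))
  cm <- contact_map(cplx, sel(polymer = "protein"), sel(polymer = "nucleic"))
  sb <- cm[cm$kind == "salt_bridge", ]
  expect_equal(nrow(sb), 1)
  expect_equal(sb$protein_resid, "ARG")
  expect_equal(sb$partner_atom, "OP1")
  hb <- cm[cm$kind == "hbond", ]
  expect_true(any(hb$protein_resid == "GLN" & hb$partner_atom == "O5'"))
  ion <- cm[cm$kind == "ion_coordination", ]
  expect_setequal(ion$protein_resno, c(288L, 290L))
  expect_true(all(ion$distance <= 2.8))
  # bodies 100 A apart produce no contacts
  farp <- transform_structure(select_atoms(cplx, sel(polymer = "protein")),
                              rt_translation(c(100, 0, 0)))
  shifted <- merge_structures(list(farp,
                                   select_atoms(cplx, !sel(polymer = "protein"))),
                              disambiguate = FALSE)
  expect_equal(nrow(contact_map(shifted)), 0)
})
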