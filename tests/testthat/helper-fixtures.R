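# shared fixture builders -- everything generated in code, nothing downloaded

atom_row <- function(chain, resno, resid, elety, elesy, x, y, z, het = FALSE) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = x, y = y, z = z, occ = 1, het = het)
}

single_atom <- function(x = 0, y = 0, z = 0, elesy = "C", chain = "A",
                        resno = 1L, resid = "ENV", elety = elesy) {
  mmstruct(atom_row(chain, resno, resid, elety, elesy, x, y, z))
}

# uniform random rotation via normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rigid <- function() rigid_xform(random_rotation(), stats::rnorm(3, 0, 10))

# random atom cloud with mixed elements
random_cloud <- function(n, scale = 10, elements = c("C", "N", "O", "P")) {
  mmstruct(atom_row(chain = "A", resno = seq_len(n), resid = "ENV",
                    elety = "X", elesy = sample(elements, n, replace = TRUE),
                    x = stats::runif(n, 0, scale),
                    y = stats::runif(n, 0, scale),
                    z = stats::runif(n, 0, scale)))
}

# O(n^2) all-pairs clash oracle, independent of the cell-list path
brute_force_clash_count <- function(a, b, criterion) {
  aa <- a$atoms[a$atoms$elesy != "H", ]
  bb <- b$atoms[b$atoms$elesy != "H", ]
  ra <- vdw_radius(aa$elesy, criterion$radii)
  rb <- vdw_radius(bb$elesy, criterion$radii)
  d <- sqrt(outer(aa$x, bb$x, `-`)^2 + outer(aa$y, bb$y, `-`)^2 +
              outer(aa$z, bb$z, `-`)^2)
  sum(outer(ra, rb, `+`) - d >= criterion$overlap_cutoff)
}

# synthetic two-domain protomer (C-alpha trace): domain N residues 1..20,
# domain C residues 21..40, well-separated blobs
fake_protomer_atoms <- function(chain = "S", seed = 7) {
  set.seed(seed)
  n <- 40
  xy <- matrix(stats::rnorm(3 * n, sd = 6), ncol = 3)
  xy[1:20, ] <- sweep(xy[1:20, ], 2, c(0, 14, 0), `+`)
  xy[21:40, ] <- sweep(xy[21:40, ], 2, c(0, -14, 25), `+`)
  atom_row(chain = chain, resno = 1:n, resid = "GLY", elety = "CA",
           elesy = "C", x = xy[, 1], y = xy[, 2], z = xy[, 3])
}

# dimeric template: protomer X = the protomer itself (optionally with its
# C domain rotated by `c_rotation` degrees about the z axis through the
# C-domain centroid), protomer Y = X mapped by a two-fold
fake_template <- function(seed = 7, c_rotation = 0,
                          two_fold = rt_translation(c(60, 0, 0)) %o%
                            rt_rotation_z(180)) {
  pa <- fake_protomer_atoms("X", seed)
  if (c_rotation != 0) {
    iC <- pa$resno >= 21
    ctr <- colMeans(as.matrix(pa[iC, c("x", "y", "z")]))
    rot <- rt_rotation(c(0, 0, 1), c_rotation, center = ctr)
    pa[iC, c("x", "y", "z")] <- rt_apply(rot, as.matrix(pa[iC, c("x", "y", "z")]))
  }
  pb <- pa; pb$chain <- "Y"
  pb[, c("x", "y", "z")] <- rt_apply(two_fold, as.matrix(pa[, c("x", "y", "z")]))
  mmstruct(rbind(pa, pb), id = "fake_template")
}

fake_split <- function() domain_split(sel(resno = 1:20), sel(resno = 21:40),
                                      boundary = c(20, 21))

fake_mapping <- function() data.frame(part = rep(c("N", "C"), each = 20),
                                      complex_chain = "S",
                                      complex_resno = 1:40,
                                      template_resno = 1:40)

fake_complex <- function(seed = 7) mmstruct(fake_protomer_atoms("S", seed),
                                            id = "fake_complex")

# unwrap a phase sequence so successive differences stay within (-pi, pi]
unwrap_angles <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

# deposited-structure cache used by the real-structure acceptance checks;
# populated by scripts/fetch_structures.R (network required)
cached_structure <- function(acc) {
  for (dir in c(testthat::test_path("..", "..", "structures"),
                path.expand("~/.cache/spo11dock"))) {
    for (ext in c(".cif", ".pdb")) {
      p <- file.path(dir, paste0(tolower(acc), ext))
      if (file.exists(p)) return(p)
    }
  }
  NULL
}
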