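#' Steric-clash criterion
#'
#' A pair of non-bonded heavy atoms clashes when their van der Waals
#' spheres interpenetrate by at least `overlap_cutoff`:
#' `r_A + r_B - d >= overlap_cutoff`.  The default cutoff of 0.6 Angstrom
#' is the common interactive-modelling default; 0.4 is a stricter
#' alternative reported alongside in the scan robustness checks.
#'
#' @param overlap_cutoff minimal vdW overlap in Angstrom (>= 0).
#' @param radii element radius table (see [vdw_radii_default()]).
#' @return Object of class `clash_criterion`.
#' @export
clash_criterion <- function(overlap_cutoff = 0.6, radii = vdw_radii_default()) {
  stopifnot(is.finite(overlap_cutoff), overlap_cutoff >= 0)
  structure(list(overlap_cutoff = overlap_cutoff, radii = radii),
            class = "clash_criterion")
}

#' Count steric clashes between two bodies
#'
#' Exhaustive over inter-body heavy-atom pairs using a cell-list spatial
#' index (identical to all-pairs brute force).  Hydrogens are ignored.
#'
#' @param a,b [mmstruct] objects (non-empty).
#' @param criterion a [clash_criterion].
#' @return Object of class `clash_report`: list with `pairs` (data.frame
#'   of clashing atom pairs with distance and overlap) and `n_clashes`.
#' @export
count_clashes <- function(a, b, criterion = clash_criterion()) {
  stopifnot(n_atoms(a) > 0, n_atoms(b) > 0)
  aa <- a$atoms[a$atoms$elesy != "H", , drop = FALSE]
  bb <- b$atoms[b$atoms$elesy != "H", , drop = FALSE]
  ra <- vdw_radius(aa$elesy, criterion$radii)
  rb <- vdw_radius(bb$elesy, criterion$radii)
  hits <- if (nrow(aa) && nrow(bb)) {
    dmax <- max(ra) + max(rb) - criterion$overlap_cutoff
    neighbor_pairs(as.matrix(aa[, c("x", "y", "z")]),
                   as.matrix(bb[, c("x", "y", "z")]), dmax)
  } else matrix(numeric(0), 0, 3)
  pairs <- data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), elety_a = character(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), elety_b = character(),
                      distance = numeric(), overlap = numeric())
  if (nrow(hits)) {
    ov <- ra[hits[, 1]] + rb[hits[, 2]] - hits[, 3]
    keep <- ov >= criterion$overlap_cutoff
    if (any(keep)) {
      i <- hits[keep, 1]; j <- hits[keep, 2]
      pairs <- data.frame(
        chain_a = aa$chain[i], resno_a = aa$resno[i],
        resid_a = aa$resid[i], elety_a = aa$elety[i],
        chain_b = bb$chain[j], resno_b = bb$resno[j],
        resid_b = bb$resid[j], elety_b = bb$elety[j],
        distance = hits[keep, 3], overlap = ov[keep])
      pairs <- pairs[order(pairs$chain_a, pairs$resno_a, pairs$chain_b,
                           pairs$resno_b, -pairs$overlap), ]
      rownames(pairs) <- NULL
    }
  }
  structure(list(pairs = pairs, n_clashes = nrow(pairs),
                 criterion = criterion), class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("clash report: %d clashing pairs (vdW overlap >= %.2f A)\n",
              x$n_clashes, x$criterion$overlap_cutoff))
  if (x$n_clashes) {
    print(utils::head(x$pairs, 10))
    if (x$n_clashes > 10) cat("  ...", x$n_clashes - 10, "more\n")
  }
  invisible(x)
}

# cell-list neighbor search: all (i, j, d) with d <= dmax between two
# coordinate sets; returns 3-column matrix
neighbor_pairs <- function(xa, xb, dmax) {
  na <- nrow(xa); nb <- nrow(xb)
  out <- matrix(numeric(0), 0, 3)
  if (!na || !nb || dmax <= 0) return(out)
  h <- dmax
  origin <- pmin(apply(xa, 2, min), apply(xb, 2, min))
  cell_of <- function(x) floor(sweep(x, 2, origin) / h)
  key <- function(cells) paste(cells[, 1], cells[, 2], cells[, 3], sep = ",")
  cb <- cell_of(xb)
  idx_b <- split(seq_len(nb), key(cb))
  ca <- cell_of(xa)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- list(); res_j <- list(); res_d <- list(); k <- 0L
  # group a-atoms by cell so each neighbor cell is visited once per group
  idx_a <- split(seq_len(na), key(ca))
  for (ak in names(idx_a)) {
    ia <- idx_a[[ak]]
    cc <- as.integer(strsplit(ak, ",", fixed = TRUE)[[1]])
    nb_keys <- paste(cc[1] + shifts[, 1], cc[2] + shifts[, 2],
                     cc[3] + shifts[, 3], sep = ",")
    jb <- unlist(idx_b[nb_keys], use.names = FALSE)
    if (!length(jb)) next
    d2 <- outer(xa[ia, 1], xb[jb, 1], `-`)^2 +
      outer(xa[ia, 2], xb[jb, 2], `-`)^2 +
      outer(xa[ia, 3], xb[jb, 3], `-`)^2
    hit <- which(d2 <= dmax^2, arr.ind = TRUE)
    if (nrow(hit)) {
      k <- k + 1L
      res_i[[k]] <- ia[hit[, 1]]
      res_j[[k]] <- jb[hit[, 2]]
      res_d[[k]] <- sqrt(d2[hit])
    }
  }
  if (!k) return(out)
  cbind(unlist(res_i), unlist(res_j), unlist(res_d))
}

#' Protein-nucleic contact map
#'
#' Distance-based contact detection between a protein selection and a
#' nucleic-acid selection, plus coordination of hetero metal ions by the
#' protein selection.  Criteria (heavy atoms, no angle terms since
#' cryo-EM models lack hydrogens):
#' * `hbond`: N/O donor-acceptor distance <= 3.5 Angstrom;
#' * `salt_bridge`: Lys NZ / Arg NH1/NH2/NE / His NE2/ND1 to phosphate
#'   oxygen or phosphorus <= 4.0 Angstrom;
#' * `ion_coordination`: ion to O/N <= 2.8 Angstrom.
#'
#' @param s an [mmstruct] of the complex.
#' @param protein_sel,na_sel `atom_sel` selections for the protein and
#'   nucleic sides.
#' @return data.frame of contact records sorted by nucleotide (or ion)
#'   then protein residue.
#' @export
contact_map <- function(s, protein_sel = sel(polymer = "protein"),
                        na_sel = sel(polymer = "nucleic")) {
  p <- select_atoms(s, protein_sel)$atoms
  n <- select_atoms(s, na_sel)$atoms
  ions <- select_atoms(s, sel(polymer = "ion"))$atoms
  if (!nrow(p) || (!nrow(n) && !nrow(ions)))
    stop("empty selection in contact_map")
  p <- p[p$elesy != "H", , drop = FALSE]
  n <- n[n$elesy != "H", , drop = FALSE]
  rec <- list()
  if (nrow(n)) {
    hits <- neighbor_pairs(as.matrix(p[, c("x", "y", "z")]),
                           as.matrix(n[, c("x", "y", "z")]), 4.0)
    if (nrow(hits)) {
      i <- hits[, 1]; j <- hits[, 2]; d <- hits[, 3]
      basic <- (p$resid[i] == "LYS" & p$elety[i] == "NZ") |
        (p$resid[i] == "ARG" & p$elety[i] %in% c("NH1", "NH2", "NE")) |
        (p$resid[i] == "HIS" & p$elety[i] %in% c("NE2", "ND1"))
      phos <- n$elety[j] %in% c("P", "OP1", "OP2", "O1P", "O2P",
                                "O5'", "O3'")
      sb <- basic & phos & d <= 4.0
      hb <- p$elesy[i] %in% c("N", "O") & n$elesy[j] %in% c("N", "O") &
        d <= 3.5 & !sb
      keep <- sb | hb
      if (any(keep)) {
        rec[[1]] <- data.frame(
          kind = ifelse(sb[keep], "salt_bridge", "hbond"),
          protein_chain = p$chain[i][keep], protein_resno = p$resno[i][keep],
          protein_resid = p$resid[i][keep], protein_atom = p$elety[i][keep],
          partner_chain = n$chain[j][keep], partner_resno = n$resno[j][keep],
          partner_resid = n$resid[j][keep], partner_atom = n$elety[j][keep],
          distance = d[keep])
      }
    }
  }
  if (nrow(ions)) {
    don <- p[p$elesy %in% c("O", "N"), , drop = FALSE]
    if (nrow(don)) {
      hits <- neighbor_pairs(as.matrix(don[, c("x", "y", "z")]),
                             as.matrix(ions[, c("x", "y", "z")]), 2.8)
      if (nrow(hits)) {
        i <- hits[, 1]; j <- hits[, 2]
        rec[[length(rec) + 1]] <- data.frame(
          kind = "ion_coordination",
          protein_chain = don$chain[i], protein_resno = don$resno[i],
          protein_resid = don$resid[i], protein_atom = don$elety[i],
          partner_chain = ions$chain[j], partner_resno = ions$resno[j],
          partner_resid = ions$resid[j], partner_atom = ions$elety[j],
          distance = hits[, 3])
      }
    }
  }
  if (!length(rec))
    return(data.frame(kind = character(), protein_chain = character(),
                      protein_resno = integer(), protein_resid = character(),
                      protein_atom = character(), partner_chain = character(),
                      partner_resno = integer(), partner_resid = character(),
                      partner_atom = character(), distance = numeric()))
  out <- do.call(rbind, rec)
  out <- out[order(out$partner_chain, out$partner_resno, out$protein_chain,
                   out$protein_resno, out$distance), ]
  rownames(out) <- NULL
  out
}

# deterministic Fibonacci sphere lattice (unit vectors); closed under point
# inversion for even n so that symmetric atom pairs get exactly equal areas
fibonacci_sphere <- function(n) {
  m <- if (n %% 2 == 0) n / 2 else n
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  if (n %% 2 == 0) rbind(pts, -pts) else pts
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA from a deterministic Fibonacci sphere lattice (no random
#' numbers): each atom's sphere of radius `r_vdw + probe` is sampled at
#' `n_points` points and a point counts as accessible when outside every
#' neighbouring atom's probe-expanded sphere.  Hydrogens are ignored.
#'
#' @param s an [mmstruct].
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param n_points lattice points per atom.
#' @param radii element radius table.
#' @return numeric vector of per-atom areas (Angstrom^2) over the heavy
#'   atoms of `s`, with `total` attribute; names follow the atom table
#'   rows.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, radii = vdw_radii_default()) {
  a <- s$atoms[s$atoms$elesy != "H", , drop = FALSE]
  n <- nrow(a)
  if (!n) return(structure(numeric(0), total = 0))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- vdw_radius(a$elesy, radii) + probe
  pts <- fibonacci_sphere(n_points)
  nb <- neighbor_pairs(xyz, xyz, 2 * max(r))
  nb <- nb[nb[, 1] != nb[, 2] & nb[, 3] < r[nb[, 1]] + r[nb[, 2]], , drop = FALSE]
  nb_of <- split(nb[, 2], factor(nb[, 1], levels = seq_len(n)))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb_of[[i]]) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 > r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  structure(areas, total = sum(areas))
}

#' Buried interface area between two bodies
#'
#' Solvent-accessible surface area lost on complexation:
#' `area = (SASA(A) + SASA(B) - SASA(AB)) / 2` (per-side, PISA-like
#' convention); the unhalved total buried area is reported alongside since
#' published values do not always state their convention.
#'
#' @param a,b [mmstruct] objects in the same coordinate frame.
#' @param probe,n_points,radii as in [sasa()].
#' @return Object of class `interface_area`: list with `area` (per-side),
#'   `total_buried`, and components `sasa_a`, `sasa_b`, `sasa_ab`.
#' @export
buried_interface_area <- function(a, b, probe = 1.4, n_points = 960,
                                  radii = vdw_radii_default()) {
  sev <- count_clashes(a, b, clash_criterion(1.5, radii))
  if (sev$n_clashes > 0)
    warning("severe inter-body clashes (", sev$n_clashes,
            " pairs with overlap >= 1.5 A); interface area may be meaningless")
  sa <- attr(sasa(a, probe, n_points, radii), "total")
  sb <- attr(sasa(b, probe, n_points, radii), "total")
  ab <- merge_structures(list(a, b), id = "ab")
  sab <- attr(sasa(ab, probe, n_points, radii), "total")
  buried <- max(0, sa + sb - sab)
  structure(list(area = buried / 2, total_buried = buried,
                 sasa_a = sa, sasa_b = sb, sasa_ab = sab),
            class = "interface_area")
}

#' @export
print.interface_area <- function(x, ...) {
  cat(sprintf("buried interface: %.0f A^2 per side (%.0f A^2 total buried)\n",
              x$area, x$total_buried))
  invisible(x)
}
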