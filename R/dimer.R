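#' Domain split of a DNA-bound complex
#'
#' Partitions a complex into the two rigid bodies moved independently when
#' templating a dimer: for the Spo11 core complex, part N is the Spo11
#' winged-helix domain (residues up to the WH/Toprim linker boundary,
#' Q172) together with the DNA, Rec102 and Rec104, and part C is the
#' Toprim domain (K173 onward) plus Ski8.  The DNA travels with part N so
#' the protein-DNA contacts of the WH domain are preserved.
#'
#' @param part_N,part_C `atom_sel` selections partitioning the complex.
#' @param boundary informational residue-number pair at the split (e.g.
#'   `c(172, 173)`).
#' @return Object of class `domain_split`.
#' @export
domain_split <- function(part_N, part_C, boundary = NULL) {
  stopifnot(inherits(part_N, "atom_sel"), inherits(part_C, "atom_sel"))
  structure(list(part_N = part_N, part_C = part_C, boundary = boundary),
            class = "domain_split")
}

#' Default Spo11 core-complex split
#'
#' Spo11 (given chain) residues <= `boundary` plus every other chain
#' except the Ski8 chain form part N; Spo11 residues > `boundary` plus
#' Ski8 form part C.
#'
#' @param spo11_chain,ski8_chain chain ids.
#' @param boundary last residue of the N-terminal part (WH domain).
#' @export
spo11_domain_split <- function(spo11_chain = "A", ski8_chain = "B",
                               boundary = 172) {
  part_C <- (sel(chain = spo11_chain) & sel(resno = (boundary + 1):10000)) |
    sel(chain = ski8_chain)
  domain_split(part_N = !part_C, part_C = part_C,
               boundary = c(boundary, boundary + 1))
}

#' Co-dock two complexes on one continuous B-form duplex
#'
#' Places two copies of a DNA-end-bound complex on a single idealized
#' B-form rail in the pre-break register: the duplexes sit back to back
#' with their two-nucleotide 5' overhangs annealed across the junction, so
#' the first overhang nucleotide of one copy lies one nucleotide away from
#' the recessed 3' end of the other.  This is the geometry the broken ends
#' would have on unbent B-form DNA; for the real core complex it produces
#' extensive steric clashes.
#'
#' @param complex an [mmstruct] with a traced 5'-overhang nucleotide and a
#'   recessed 3' end.
#' @param params a [helix_params].
#' @param criterion a [clash_criterion].
#' @param spec optional pre-built [dock_spec] (anchor override).
#' @return List of class `codocked_dimer`: `copy1`, `copy2`, the clash
#'   report `clashes` (protein vs protein), `dna_clashes` (each copy's
#'   protein vs the other copy's DNA), and the placement transforms.
#' @export
build_bform_codocked_dimer <- function(complex, params = helix_params(),
                                       criterion = clash_criterion(),
                                       spec = NULL) {
  if (is.null(spec)) spec <- dock_spec(complex)
  v <- spec$overhang_len
  if (v < 1)
    stop("complex has no traced 5'-overhang nucleotide on the bound duplex")
  span <- nrow(spec$anchor)
  # rail long enough to host both anchors around the junction
  c0 <- span + v + 2L              # rail bp index of copy 1's terminal bp
  n_tot <- 2L * c0 + 2L
  rail <- build_bform_duplex(paste(rep_len(strsplit("ACGT", "")[[1]], n_tot),
                                   collapse = ""), params, id = "rail")
  hx <- attr(rail, "helix")
  grab <- function(at, chain, resno)
    at[at$chain == chain & at$resno == resno &
         at$elety %in% c("P", "C1'"), c("elety", "x", "y", "z")]
  pair_for <- function(offset_fun, chains) {
    mob <- list(); fix <- list()
    for (r in seq_len(nrow(spec$anchor))) {
      k <- spec$anchor$k[r]
      rails <- offset_fun(k)
      ref_rail <- grab(rail$atoms, chains[1], rails[1])
      par_rail <- grab(rail$atoms, chains[2], rails[2])
      ref_cplx <- grab(complex$atoms, spec$anchor$chain_ref[r],
                       spec$anchor$resno_ref[r])
      par_cplx <- grab(complex$atoms, spec$anchor$chain_partner[r],
                       spec$anchor$resno_partner[r])
      for (pp in list(list(ref_cplx, ref_rail), list(par_cplx, par_rail))) {
        common <- intersect(pp[[1]]$elety, pp[[2]]$elety)
        if (!length(common)) next
        mob[[length(mob) + 1]] <-
          as.matrix(pp[[1]][match(common, pp[[1]]$elety), c("x", "y", "z")])
        fix[[length(fix) + 1]] <-
          as.matrix(pp[[2]][match(common, pp[[2]]$elety), c("x", "y", "z")])
      }
    }
    list(mobile = do.call(rbind, mob), fixed = do.call(rbind, fix))
  }
  # copy 1: duplex bp k at rail c0 + k on strand A (overhang points to lower rail)
  p1 <- pair_for(function(k) c(hx$resno_A(c0 + k), hx$resno_B(c0 + k)),
                 c(hx$chainA, hx$chainB))
  # copy 2 flipped: duplex bp k at rail c0 - (v + 1) - k on strand B
  p2 <- pair_for(function(k) {
    j <- c0 - (v + 1L) - k
    c(hx$resno_B(j), hx$resno_A(j))
  }, c(hx$chainB, hx$chainA))
  f1 <- kabsch(p1$fixed, p1$mobile)
  f2 <- kabsch(p2$fixed, p2$mobile)
  copy1 <- transform_structure(complex, f1$transform)
  copy2 <- transform_structure(complex, f2$transform)
  prot <- !sel(polymer = "nucleic")
  nuc <- sel(polymer = "nucleic")
  clashes <- count_clashes(select_atoms(copy1, prot), select_atoms(copy2, prot),
                           criterion)
  dna12 <- count_clashes(select_atoms(copy1, prot), select_atoms(copy2, nuc),
                         criterion)
  dna21 <- count_clashes(select_atoms(copy2, prot), select_atoms(copy1, nuc),
                         criterion)
  structure(list(copy1 = copy1, copy2 = copy2, rail = rail,
                 transform1 = f1$transform, transform2 = f2$transform,
                 anchor_rmsd = c(f1$rmsd, f2$rmsd),
                 clashes = clashes, dna_clashes = list(dna12, dna21)),
            class = "codocked_dimer")
}

#' @export
print.codocked_dimer <- function(x, ...) {
  cat(sprintf("B-form co-docked dimer: %d protein-protein clashes, %d/%d protein-DNA clashes\n",
              x$clashes$n_clashes, x$dna_clashes[[1]]$n_clashes,
              x$dna_clashes[[2]]$n_clashes))
  invisible(x)
}

#' Build a topoisomerase VI-templated dimer model
#'
#' Splits the complex into two rigid bodies (a [domain_split]) and aligns
#' each independently onto its cognate domain in the two protomers of a
#' dimeric template (a Topo VI A-subunit dimer for the real system), using
#' a residue-correspondence table.  The result is a dimer assembly in
#' which each copy's two parts may rotate relative to one another; the
#' rotation of part N relative to part C and the clash count between the
#' two copies are reported.
#'
#' @param complex an [mmstruct].
#' @param template an [mmstruct] containing two protomers.
#' @param split a [domain_split] for `complex`.
#' @param mapping data.frame with columns `part` ("N"/"C"),
#'   `complex_chain`, `complex_resno`, `template_resno`, optional `elety`
#'   (default "CA"): residue correspondence to ONE template protomer.
#' @param template_chains length-2 chain ids of the two template
#'   protomers; `mapping$template_resno` is looked up on each in turn.
#' @param criterion a [clash_criterion].
#' @return List of class `templated_dimer`: `copy1`, `copy2` (each a
#'   re-assembled [mmstruct]), per-part superpositions, and `metrics`
#'   (class `dimer_metrics`).
#' @export
build_topo6_templated_dimer <- function(complex, template, split, mapping,
                                        template_chains,
                                        criterion = clash_criterion()) {
  stopifnot(inherits(split, "domain_split"), length(template_chains) == 2)
  mapping <- as.data.frame(mapping)
  if (is.null(mapping$elety)) mapping$elety <- "CA"
  mN <- sel_mask(complex, split$part_N)
  mC <- sel_mask(complex, split$part_C)
  if (any(mN & mC)) warning("domain split parts overlap (",
                            sum(mN & mC), " atoms)")
  if (!all(mN | mC)) warning("domain split parts do not cover the complex (",
                             sum(!(mN | mC)), " atoms dropped)")
  pick <- function(s, ch, rn, at) {
    a <- s$atoms
    idx <- mapply(function(c0, r0, a0)
      which(a$chain == c0 & a$resno == r0 & a$elety == a0)[1], ch, rn, at)
    if (anyNA(idx)) stop("mapping residues missing from structure (rows ",
                         paste(utils::head(which(is.na(idx)), 5), collapse = ","), ")")
    as.matrix(a[idx, c("x", "y", "z")])
  }
  fit_part <- function(part, tchain) {
    mp <- mapping[mapping$part == part, , drop = FALSE]
    if (nrow(mp) < 3) stop("mapping yields fewer than 3 pairs for part ", part)
    fixed <- pick(template, rep(tchain, nrow(mp)), mp$template_resno, mp$elety)
    mobile <- pick(complex, mp$complex_chain, mp$complex_resno, mp$elety)
    kabsch(fixed, mobile)
  }
  copies <- list(); fits <- list()
  for (i in 1:2) {
    fN <- fit_part("N", template_chains[i])
    fC <- fit_part("C", template_chains[i])
    aN <- complex$atoms[mN, , drop = FALSE]
    aC <- complex$atoms[mC, , drop = FALSE]
    aN[, c("x", "y", "z")] <- rt_apply(fN$transform, as.matrix(aN[, c("x", "y", "z")]))
    aC[, c("x", "y", "z")] <- rt_apply(fC$transform, as.matrix(aC[, c("x", "y", "z")]))
    copies[[i]] <- mmstruct(rbind(aN, aC), id = sprintf("%s_copy%d", complex$id, i))
    fits[[i]] <- list(N = fN, C = fC)
  }
  prot <- !sel(polymer = "nucleic")
  clashes <- count_clashes(select_atoms(copies[[1]], prot),
                           select_atoms(copies[[2]], prot), criterion)
  rel <- rt_compose(fits[[1]]$N$transform, rt_inverse(fits[[1]]$C$transform))
  metrics <- structure(list(
    rmsd_N = fits[[1]]$N$rmsd, n_pairs_N = fits[[1]]$N$n_pairs,
    rmsd_C = fits[[1]]$C$rmsd, n_pairs_C = fits[[1]]$C$n_pairs,
    wh_rotation = rotation_angle(rel)$angle,
    n_clashes = clashes$n_clashes,
    inter_dna_angle = NA_real_, axis_offset = NA_real_,
    end_separation = NA_real_), class = "dimer_metrics")
  out <- structure(list(copy1 = copies[[1]], copy2 = copies[[2]],
                        fits = fits, clashes = clashes, metrics = metrics),
                   class = "templated_dimer")
  dna_ok <- tryCatch({
    g <- dimer_dna_geometry(out)
    out$metrics$inter_dna_angle <- g$inter_dna_angle
    out$metrics$axis_offset <- g$axis_offset
    out$metrics$end_separation <- g$end_separation
    TRUE
  }, error = function(e) FALSE)
  out
}

#' @export
print.dimer_metrics <- function(x, ...) {
  cat(sprintf("part N: rmsd %.2f A over %d pairs; part C: rmsd %.2f A over %d pairs\n",
              x$rmsd_N, x$n_pairs_N, x$rmsd_C, x$n_pairs_C))
  cat(sprintf("N-vs-C rotation: %.1f deg; inter-copy clashes: %d\n",
              x$wh_rotation, x$n_clashes))
  if (!is.na(x$inter_dna_angle))
    cat(sprintf("DNA path angle %.1f deg, axis offset %.2f A, end separation %.2f A\n",
                x$inter_dna_angle, x$axis_offset, x$end_separation))
  invisible(x)
}

#' @export
print.templated_dimer <- function(x, ...) {
  cat("templated dimer model\n")
  print(x$metrics)
  invisible(x)
}

# 5' end atom of a duplex copy: P (else C5', else C1') of the 5'-most
# traced nucleotide of the overhang strand; 3' end atom: O3' (else C1')
# of the recessed strand's 3'-terminal residue
duplex_end_atoms <- function(dna) {
  bp <- pair_duplex_c1(dna)
  res <- residues(dna)
  nuc <- res[res$class == "nucleic", ]
  ovA <- sum(nuc$resno[nuc$chain == bp$chainA[1]] < min(bp$resnoA))
  ovB <- sum(nuc$resno[nuc$chain == bp$chainB[1]] < min(bp$resnoB))
  if (ovB > ovA) {
    ref_chain <- bp$chainB[1]; rec_chain <- bp$chainA[1]
    rec_resno <- bp$resnoA[which.min(bp$resnoB)]
  } else {
    ref_chain <- bp$chainA[1]; rec_chain <- bp$chainB[1]
    rec_resno <- bp$resnoB[which.min(bp$resnoA)]
  }
  a <- dna$atoms
  five_res <- min(a$resno[a$chain == ref_chain])
  pick1 <- function(chain, resno, prefs) {
    for (p in prefs) {
      row <- a[a$chain == chain & a$resno == resno & a$elety == p, ]
      if (nrow(row)) return(as.numeric(row[1, c("x", "y", "z")]))
    }
    stop("no suitable end atom on ", chain, " ", resno)
  }
  # recessed strand 3' terminus: highest resno end of the recessed chain
  # adjacent to the overhang-proximal bp
  rec_res3 <- max(a$resno[a$chain == rec_chain & a$resno <= rec_resno])
  list(p5 = pick1(ref_chain, five_res, c("P", "C5'", "C1'")),
       o3 = pick1(rec_chain, rec_res3, c("O3'", "C1'")))
}

#' DNA geometry of a dimer model
#'
#' Fits a helical axis through each copy's bound duplex, orients both
#' toward the junction between the juxtaposed DNA ends, and reports the
#' path angle between them (180 degrees = straight, smaller = more bent),
#' the minimal distance between the two axis lines, and the separation
#' between the inferred 5' and 3' strand ends across the junction (mean
#' of the two directed pairs: 5'-end atom of one copy to the recessed
#' 3'-end atom of the other).
#'
#' @param dimer a `templated_dimer`, `codocked_dimer`, or list with
#'   elements `copy1` and `copy2` ([mmstruct]s, each containing a duplex).
#' @return List of class `dimer_dna_geometry`: `inter_dna_angle` (deg),
#'   `axis_offset` (A), `end_separation` (A, mean) with per-pair values in
#'   `end_separations`.
#' @export
dimer_dna_geometry <- function(dimer) {
  nuc <- sel(polymer = "nucleic")
  d1 <- select_atoms(dimer$copy1, nuc)
  d2 <- select_atoms(dimer$copy2, nuc)
  if (!n_atoms(d2)) stop("second duplex absent from dimer")
  ax1 <- fit_helical_axis(d1)
  ax2 <- fit_helical_axis(d2)
  e1 <- duplex_end_atoms(d1)
  e2 <- duplex_end_atoms(d2)
  # junction = midpoint of the closest C1'-C1' approach between the copies
  c1 <- d1$atoms[d1$atoms$elety == "C1'", c("x", "y", "z")]
  c2 <- d2$atoms[d2$atoms$elety == "C1'", c("x", "y", "z")]
  d2m <- outer(c1$x, c2$x, `-`)^2 + outer(c1$y, c2$y, `-`)^2 +
    outer(c1$z, c2$z, `-`)^2
  ij <- which(d2m == min(d2m), arr.ind = TRUE)[1, ]
  junction <- as.numeric((c1[ij[1], ] + c2[ij[2], ]) / 2)
  orient <- function(ax, dna) {
    ctr <- colMeans(coords(dna))
    if (sum(ax$direction * (junction - ctr)) < 0)
      axis_line(ax$point, -ax$direction) else ax
  }
  a1 <- orient(ax1, d1); a2 <- orient(ax2, d2)
  seps <- c(sqrt(sum((e1$p5 - e2$o3)^2)), sqrt(sum((e2$p5 - e1$o3)^2)))
  structure(list(inter_dna_angle = interaxis_angle(a1, a2),
                 axis_offset = as.numeric(axis_offset(a1, a2)),
                 end_separation = mean(seps), end_separations = seps),
            class = "dimer_dna_geometry")
}

#' @export
print.dimer_dna_geometry <- function(x, ...) {
  cat(sprintf("DNA path angle %.1f deg, axis offset %.2f A, end separation %.2f A (pairs: %s)\n",
              x$inter_dna_angle, x$axis_offset, x$end_separation,
              paste(sprintf("%.2f", x$end_separations), collapse = ", ")))
  invisible(x)
}

#' Read a residue-mapping table
#'
#' TSV with columns `part`, `complex_chain`, `complex_resno`,
#' `template_resno`, optional `elety`.
#' @param path file path.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
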