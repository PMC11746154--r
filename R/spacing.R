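#' Docking specification for the double-end scan
#'
#' Describes how a DNA-bound complex is anchored on the B-form rail: which
#' base pairs of its bound duplex are used for frame matching.  By default
#' the anchor is the first `n_anchor_bp` fully paired base pairs at the
#' 5'-overhang-proximal end of the bound duplex, detected from C1'-C1'
#' pairing; pass `anchor` explicitly to override (a data.frame with
#' columns `k` (0-based bp index from the end), `chain_ref`, `resno_ref`,
#' `chain_partner`, `resno_partner`).
#'
#' @param complex an [mmstruct]: a DNA-bound complex.
#' @param anchor optional explicit anchor table.
#' @param n_anchor_bp anchor span in base pairs (>= 3).
#' @return Object of class `dock_spec`.
#' @export
dock_spec <- function(complex, anchor = NULL, n_anchor_bp = 4) {
  stopifnot(n_anchor_bp >= 3)
  if (is.null(anchor)) {
    det <- detect_anchor(complex, n_anchor_bp)
    anchor <- det$anchor
    overhang <- det$overhang_len
  } else {
    overhang <- attr(anchor, "overhang_len")
    if (is.null(overhang)) overhang <- 2L
  }
  if (nrow(anchor) < 3) stop("anchor resolves to fewer than 3 base pairs")
  structure(list(complex = complex, anchor = anchor,
                 overhang_len = overhang), class = "dock_spec")
}

# find the duplex, the overhang-bearing reference strand, and the anchor
# base pairs at the overhang-proximal duplex end
detect_anchor <- function(complex, n_anchor_bp) {
  bp <- pair_duplex_c1(complex)
  if (nrow(bp) < n_anchor_bp) stop("bound duplex too short for anchor")
  res <- residues(complex)
  nuc <- res[res$class == "nucleic", ]
  ov_at_low <- function(chain, paired_resno) {
    r <- nuc$resno[nuc$chain == chain]
    sum(r < min(paired_resno))
  }
  ovA <- ov_at_low(bp$chainA[1], bp$resnoA)
  ovB <- ov_at_low(bp$chainB[1], bp$resnoB)
  if (ovB > ovA) {   # reference strand is B: swap roles
    bp <- data.frame(chainA = bp$chainB, resnoA = bp$resnoB,
                     chainB = bp$chainA, resnoB = bp$resnoA)
    ov <- ovB
  } else ov <- ovA
  bp <- bp[order(bp$resnoA), ]
  anchor <- data.frame(k = seq_len(n_anchor_bp) - 1L,
                       chain_ref = bp$chainA[seq_len(n_anchor_bp)],
                       resno_ref = bp$resnoA[seq_len(n_anchor_bp)],
                       chain_partner = bp$chainB[seq_len(n_anchor_bp)],
                       resno_partner = bp$resnoB[seq_len(n_anchor_bp)])
  list(anchor = anchor, overhang_len = as.integer(ov))
}

# coordinates of the anchor atoms (P/C1' where present) of the complex,
# together with matching ideal-rail coordinates for a given placement.
# end = "fixed": anchor bp k -> rail bp k on rail strand A.
# end = "moving": anchor bp k -> rail bp L-1-k on rail strand B (the rail's
# antiparallel strand supplies the end-to-end flip).
anchor_pairing <- function(spec, rail, L, end) {
  hx <- attr(rail, "helix")
  cplx <- spec$complex$atoms
  ra <- rail$atoms
  grab <- function(at, chain, resno) {
    at[at$chain == chain & at$resno == resno &
         at$elety %in% c("P", "C1'"), c("elety", "x", "y", "z")]
  }
  mob <- list(); fix <- list()
  for (r in seq_len(nrow(spec$anchor))) {
    k <- spec$anchor$k[r]
    if (end == "fixed") {
      ref_rail <- grab(ra, hx$chainA, hx$resno_A(k))
      par_rail <- grab(ra, hx$chainB, hx$resno_B(k))
    } else {
      ref_rail <- grab(ra, hx$chainB, hx$resno_B(L - 1 - k))
      par_rail <- grab(ra, hx$chainA, hx$resno_A(L - 1 - k))
    }
    ref_cplx <- grab(cplx, spec$anchor$chain_ref[r], spec$anchor$resno_ref[r])
    par_cplx <- grab(cplx, spec$anchor$chain_partner[r], spec$anchor$resno_partner[r])
    for (pair in list(list(ref_cplx, ref_rail), list(par_cplx, par_rail))) {
      common <- intersect(pair[[1]]$elety, pair[[2]]$elety)
      if (!length(common)) next
      mob[[length(mob) + 1]] <-
        as.matrix(pair[[1]][match(common, pair[[1]]$elety), c("x", "y", "z")])
      fix[[length(fix) + 1]] <-
        as.matrix(pair[[2]][match(common, pair[[2]]$elety), c("x", "y", "z")])
    }
  }
  list(mobile = do.call(rbind, mob), fixed = do.call(rbind, fix))
}

#' Dock two copies of a complex on opposite ends of a B-form rail
#'
#' Builds an idealized rail duplex of `L` base pairs and rigidly places
#' two copies of the complex: copy 1 anchored at bp 0, copy 2 anchored at
#' bp `L - 1` in the opposite orientation (its anchor follows the rail's
#' antiparallel strand, so the two 5'-overhang ends point away from each
#' other).  Decreasing `L` by one rotates copy 2 by `-twist` and
#' translates it by `-rise` relative to copy 1.
#'
#' @param spec a [dock_spec].
#' @param L rail duplex length, bp.
#' @param params a [helix_params].
#' @return List of class `double_end_dock`: `copy1`, `copy2` (transformed
#'   [mmstruct]s), `rail`, the two `rigid_xform`s, anchor-fit RMSDs, and
#'   `relative_rotation` (residual helical rotation between the two end
#'   frames, degrees in `[0, 180]`).
#' @export
dock_double_end <- function(spec, L, params = helix_params()) {
  stopifnot(inherits(spec, "dock_spec"))
  span <- nrow(spec$anchor)
  if (L < 2 * span) stop("rail of ", L, " bp too short for two ", span,
                         "-bp anchors")
  rail <- build_bform_duplex(paste(rep_len(strsplit("ACGT", "")[[1]], L),
                                   collapse = ""), params, id = "rail")
  p1 <- anchor_pairing(spec, rail, L, "fixed")
  p2 <- anchor_pairing(spec, rail, L, "moving")
  f1 <- kabsch(p1$fixed, p1$mobile)
  f2 <- kabsch(p2$fixed, p2$mobile)
  copy1 <- transform_structure(spec$complex, f1$transform)
  copy2 <- transform_structure(spec$complex, f2$transform)
  structure(list(copy1 = copy1, copy2 = copy2, rail = rail,
                 transform1 = f1$transform, transform2 = f2$transform,
                 anchor_rmsd = c(f1$rmsd, f2$rmsd), L = L, params = params,
                 relative_rotation = fold180((L - 1) * params$twist)),
            class = "double_end_dock")
}

#' @export
print.double_end_dock <- function(x, ...) {
  cat(sprintf("double-end dock on %d-bp rail: relative rotation %.1f deg, anchor rmsd %.3f/%.3f A\n",
              x$L, x$relative_rotation, x$anchor_rmsd[1], x$anchor_rmsd[2]))
  invisible(x)
}

#' Assemble a double-end dock into one structure
#' @param dock a `double_end_dock`.
#' @param include_rail include the rail duplex atoms?
#' @return an [mmstruct] assembly with disambiguated chain ids.
#' @export
dock_assembly <- function(dock, include_rail = FALSE) {
  parts <- list(dock$copy1, dock$copy2)
  if (include_rail) parts <- c(parts, list(dock$rail))
  merge_structures(parts, id = sprintf("dock_L%d", dock$L))
}

#' Clash count versus duplex length
#'
#' For each rail length, docks two copies of the complex on opposite ends
#' and counts steric clashes between the two moieties.  By default the
#' complexes' bound DNA (and the rail) are excluded, so clashes are
#' protein-vs-protein (plus any non-nucleic pseudo-atoms such as the
#' synthetic envelope); set `include_dna = TRUE` to count DNA atoms too.
#'
#' @param spec a [dock_spec].
#' @param lengths integer vector of rail lengths (bp).
#' @param criterion a [clash_criterion].
#' @param params a [helix_params].
#' @param coorient_tol co-orientation tolerance, degrees (half a bp twist
#'   by default classifies every length unambiguously).
#' @param include_dna count the complexes' nucleic atoms as well?
#' @return data.frame of class `spacing_scan` with one row per length:
#'   `length`, `n_clashes`, `relative_rotation`, `co_oriented`,
#'   `center_to_center` (= length + overhang length at each end).
#' @export
clash_vs_length_scan <- function(spec, lengths, criterion = clash_criterion(),
                                 params = helix_params(), coorient_tol = 18,
                                 include_dna = FALSE) {
  stopifnot(length(lengths) >= 1)
  moiety <- if (include_dna) sel_all() else !sel(polymer = "nucleic")
  rows <- lapply(sort(unique(as.integer(lengths))), function(L) {
    dock <- dock_double_end(spec, L, params)
    m1 <- select_atoms(dock$copy1, moiety)
    m2 <- select_atoms(dock$copy2, moiety)
    nc <- if (n_atoms(m1) && n_atoms(m2))
      count_clashes(m1, m2, criterion)$n_clashes else 0L
    data.frame(length = L, n_clashes = nc,
               relative_rotation = dock$relative_rotation,
               co_oriented = dock$relative_rotation <= coorient_tol,
               center_to_center = L + spec$overhang_len)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spacing_scan", "data.frame")
  attr(out, "params") <- params
  attr(out, "criterion") <- criterion
  attr(out, "coorient_tol") <- coorient_tol
  out
}

#' @export
print.spacing_scan <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("clash-vs-length scan (%d lengths, twist %.1f deg/bp, overlap cutoff %.2f A)\n",
              nrow(x), p$twist, attr(x, "criterion")$overlap_cutoff))
  print.data.frame(x)
  invisible(x)
}

#' @export
plot.spacing_scan <- function(x, ...) {
  graphics::plot(x$length, x$n_clashes, type = "b", pch = 16,
                 col = ifelse(x$co_oriented, "red3", "grey40"),
                 xlab = "duplex length (bp)", ylab = "inter-complex clashes", ...)
  graphics::legend("topright", pch = 16, col = c("red3", "grey40"),
                   legend = c("co-oriented", "rotated"), bty = "n")
  invisible(x)
}

#' Shortest co-oriented clash-free duplex
#'
#' Finds the smallest scanned length that is co-oriented (residual
#' helical rotation within `tolerance`) and has at most `max_clashes`
#' clashes, together with the full ascending list of qualifying lengths
#' (whose spacing exposes the helical periodicity of roughly
#' `360 / twist` bp).
#'
#' @param scan a `spacing_scan` (contiguous length range).
#' @param tolerance co-orientation tolerance, degrees.
#' @param max_clashes clash-count epsilon still considered clash-free.
#' @return List of class `spacing_summary`: `min_length` (NA if none
#'   qualifies), `qualifying` lengths, `step` (median spacing between
#'   qualifying lengths), `tolerance`, `max_clashes`.
#' @export
min_cooriented_clashfree <- function(scan, tolerance = attr(scan, "coorient_tol"),
                                     max_clashes = 0) {
  if (is.null(tolerance)) tolerance <- 18
  ok <- scan$relative_rotation <= tolerance & scan$n_clashes <= max_clashes
  qual <- sort(scan$length[ok])
  structure(list(
    min_length = if (length(qual)) qual[1] else NA_integer_,
    qualifying = qual,
    step = if (length(qual) > 1) stats::median(diff(qual)) else NA_real_,
    tolerance = tolerance, max_clashes = max_clashes),
    class = "spacing_summary")
}

#' @export
print.spacing_summary <- function(x, ...) {
  if (is.na(x$min_length)) {
    cat("no co-oriented clash-free length in the scanned range\n")
  } else {
    cat(sprintf("shortest co-oriented clash-free duplex: %d bp (qualifying: %s; step %s bp)\n",
                x$min_length, paste(x$qualifying, collapse = ", "),
                format(x$step)))
  }
  invisible(x)
}
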