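#' Kabsch least-squares rigid-body superposition
#'
#' Closed-form optimal rigid fit (rotation + translation, never a
#' reflection) of `mobile` onto `fixed` over paired points, via SVD of the
#' cross-covariance matrix.
#'
#' @param fixed,mobile numeric n x 3 matrices of paired coordinates
#'   (n >= 3).
#' @return Object of class `superposition`: list with `transform`
#'   (a [rigid_xform] to apply to mobile coordinates), `rmsd` (Angstrom)
#'   and `n_pairs`.
#' @export
kabsch <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (nrow(fixed) != nrow(mobile)) stop("point counts differ: ",
                                        nrow(fixed), " vs ", nrow(mobile))
  n <- nrow(fixed)
  if (n < 3) stop("need at least 3 point pairs, got ", n)
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  F0 <- sweep(fixed, 2, cf); M0 <- sweep(mobile, 2, cm)
  H <- crossprod(M0, F0)                       # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # proper rotation branch
  t <- as.numeric(cf - R %*% cm)
  xf <- rigid_xform(R, t)
  rmsd <- sqrt(sum((rt_apply(xf, mobile) - fixed)^2) / n)
  structure(list(transform = xf, rmsd = rmsd, n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d atom pairs\n",
              x$rmsd, x$n_pairs))
  print(x$transform)
  invisible(x)
}

#' Superpose one structure onto another
#'
#' Pairs atoms between the two structures and fits `mobile` onto `fixed`
#' with [kabsch()].  The default pairing uses shared protein C-alpha atoms
#' matched by chain id + author residue number (DNA excluded, since bound
#' ligands may differ between models).  An explicit pairing data.frame
#' with columns `fixed_chain`, `fixed_resno`, `mobile_chain`,
#' `mobile_resno` and optionally `elety` (default `"CA"`) may be supplied
#' instead.
#'
#' @param fixed,mobile [mmstruct] objects.
#' @param pairing `"calpha"` or a pairing data.frame (see Details).
#' @param selection optional `atom_sel` restricting the default pairing.
#' @return A `superposition` whose `transform` maps the full mobile
#'   structure; component `mobile_fitted` holds the transformed mobile
#'   structure.
#' @export
superpose_structures <- function(fixed, mobile, pairing = "calpha",
                                 selection = NULL) {
  if (identical(pairing, "calpha")) {
    fs <- sel(polymer = "protein", elety = "CA")
    ms <- fs
    if (!is.null(selection)) { fs <- fs & selection; ms <- ms & selection }
    fa <- select_atoms(fixed, fs)$atoms
    ma <- select_atoms(mobile, ms)$atoms
    key_f <- paste(fa$chain, fa$resno)
    key_m <- paste(ma$chain, ma$resno)
    shared <- intersect(key_f, key_m)
    if (length(shared) < 3)
      stop("fewer than 3 shared C-alpha atoms between chains {",
           paste(unique(fa$chain), collapse = ","), "} and {",
           paste(unique(ma$chain), collapse = ","), "}")
    fa <- fa[match(shared, key_f), ]; ma <- ma[match(shared, key_m), ]
    fxyz <- as.matrix(fa[, c("x", "y", "z")])
    mxyz <- as.matrix(ma[, c("x", "y", "z")])
  } else {
    p <- as.data.frame(pairing)
    if (is.null(p$elety)) p$elety <- "CA"
    pick <- function(s, ch, rn, at) {
      a <- s$atoms
      idx <- mapply(function(c0, r0, a0)
        which(a$chain == c0 & a$resno == r0 & a$elety == a0)[1], ch, rn, at)
      if (anyNA(idx))
        stop("pairing rows not found in structure: ",
             paste(which(is.na(idx)), collapse = ", "))
      as.matrix(a[idx, c("x", "y", "z")])
    }
    fxyz <- pick(fixed, p$fixed_chain, p$fixed_resno, p$elety)
    mxyz <- pick(mobile, p$mobile_chain, p$mobile_resno, p$elety)
  }
  res <- kabsch(fxyz, mxyz)
  res$mobile_fitted <- transform_structure(mobile, res$transform)
  res
}

#' Oriented line in space
#'
#' @param point a point on the line (Angstrom).
#' @param direction direction vector (normalized internally); oriented
#'   5'-3' along the reference strand for helical axes.
#' @return Object of class `axis_line`.
#' @export
axis_line <- function(point, direction) {
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("zero-length direction")
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / n),
            class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("axis: point [%s], direction [%s]\n",
              paste(sprintf("%.2f", x$point), collapse = ", "),
              paste(sprintf("%.3f", x$direction), collapse = ", ")))
  invisible(x)
}

PURINES <- c("DA", "DG", "A", "G", "DI", "I")

# Watson-Crick pairing of two nucleic chains via the central H-bond atoms:
# purine N1 against pyrimidine N3 (cross-pair distance ~2.8-3.1 A), mutual
# nearest within 3.4 A -- unambiguous where C1'-C1' windows are not, since
# cross-strand stacked neighbours can come closer than the pair itself.
# Midpoints are C1'-C1' midpoints of the paired residues.
pair_duplex_c1 <- function(s, chains = NULL) {
  at <- s$atoms[residue_class(s$atoms$resid) == "nucleic", ]
  if (is.null(chains)) {
    c1 <- at[at$elety == "C1'", ]
    chains <- names(sort(table(c1$chain), decreasing = TRUE))
    if (length(chains) < 2) stop("need two nucleic chains to pair a duplex")
    chains <- chains[1:2]
  }
  wc_anchor <- function(chain) {
    a <- at[at$chain == chain, ]
    pur <- a$resid %in% PURINES
    a[(pur & a$elety == "N1") | (!pur & a$elety == "N3"), , drop = FALSE]
  }
  wa <- wc_anchor(chains[1]); wb <- wc_anchor(chains[2])
  if (!nrow(wa) || !nrow(wb))
    stop("no Watson-Crick anchor atoms (purine N1 / pyrimidine N3) found")
  d <- sqrt(outer(wa$x, wb$x, `-`)^2 + outer(wa$y, wb$y, `-`)^2 +
              outer(wa$z, wb$z, `-`)^2)
  j <- apply(d, 1, which.min)
  dmin <- d[cbind(seq_len(nrow(wa)), j)]
  mutual <- apply(d, 2, which.min)[j] == seq_len(nrow(wa))
  ok <- which(mutual & dmin <= 3.4)
  c1_of <- function(chain, resno) {
    m <- at[at$chain == chain & at$elety == "C1'", ]
    as.matrix(m[match(resno, m$resno), c("x", "y", "z")])
  }
  pa <- c1_of(chains[1], wa$resno[ok])
  pb <- c1_of(chains[2], wb$resno[j[ok]])
  mid <- (pa + pb) / 2
  out <- data.frame(chainA = rep(chains[1], length(ok)), resnoA = wa$resno[ok],
                    chainB = rep(chains[2], length(ok)), resnoB = wb$resno[j[ok]],
                    mid_x = mid[, 1], mid_y = mid[, 2], mid_z = mid[, 3])
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Fit the helical axis of a DNA duplex
#'
#' Pairs C1' atoms across the two strands, takes per-base-pair C1'-C1'
#' midpoints and fits a line through them by principal-component fit.  The
#' direction is oriented 5'-3' along the reference strand (the first of
#' `chains`, or the chain with most nucleotides).
#'
#' @param s an [mmstruct] containing a duplex (>= 4 paired bp).
#' @param chains optional length-2 chain ids `(reference, partner)`.
#' @return An [axis_line].
#' @export
fit_helical_axis <- function(s, chains = NULL) {
  bp <- pair_duplex_c1(s, chains)
  if (nrow(bp) < 4) stop("fewer than 4 paired base pairs identifiable")
  bp <- bp[order(bp$resnoA), ]
  mid <- as.matrix(bp[, c("mid_x", "mid_y", "mid_z")])
  # C1'-C1' midpoints sit slightly off-axis and spiral with the helix; a
  # running mean over ~one helical turn cancels the circular component
  # before the line fit
  n <- nrow(mid)
  w <- min(10L, n - 2L)
  if (w >= 2) {
    sm <- sapply(1:3, function(c0)
      stats::filter(mid[, c0], rep(1 / w, w), sides = 2))
    sm <- sm[stats::complete.cases(sm), , drop = FALSE]
    if (nrow(sm) >= 2) mid <- as.matrix(sm)
  }
  ctr <- colMeans(mid)
  sv <- svd(sweep(mid, 2, ctr))
  dir <- sv$v[, 1]
  # orient 5'->3' of the reference strand (ascending resno of chain A)
  span <- mid[nrow(mid), ] - mid[1, ]
  if (sum(span * dir) < 0) dir <- -dir
  axis_line(ctr, dir)
}

#' Angle and offset between two axes
#'
#' `interaxis_angle` returns the angle between the two oriented direction
#' vectors, in `[0, 180]` degrees.  `axis_offset` returns the minimal
#' distance between the two (infinite) lines; for parallel lines this is
#' the perpendicular distance between them, flagged with attribute
#' `parallel = TRUE`.
#'
#' @param a,b [axis_line] objects.
#' @return degrees / Angstrom.
#' @export
interaxis_angle <- function(a, b) {
  cs <- sum(a$direction * b$direction)
  acos(max(-1, min(1, cs))) * 180 / pi
}

#' @rdname interaxis_angle
#' @export
axis_offset <- function(a, b) {
  n <- cross3(a$direction, b$direction)
  w <- b$point - a$point
  if (sqrt(sum(n^2)) < 1e-9) {
    d <- w - sum(w * a$direction) * a$direction
    return(structure(sqrt(sum(d^2)), parallel = TRUE))
  }
  n <- n / sqrt(sum(n^2))
  structure(abs(sum(w * n)), parallel = FALSE)
}

cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

#' Distances between atom selections
#'
#' `mode = "min"` returns the minimal heavy-atom distance between the two
#' selections; `mode = "ca-ca"` requires each selection to resolve to a
#' single C-alpha atom and returns their distance.
#'
#' @param s an [mmstruct].
#' @param sel_a,sel_b `atom_sel` selections (non-empty).
#' @param mode `"min"` or `"ca-ca"`.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(s, sel_a, sel_b, mode = c("min", "ca-ca")) {
  mode <- match.arg(mode)
  a <- select_atoms(s, sel_a)$atoms
  b <- select_atoms(s, sel_b)$atoms
  if (!nrow(a) || !nrow(b)) stop("empty selection in atom_distance")
  if (mode == "ca-ca") {
    a <- a[a$elety == "CA", , drop = FALSE]
    b <- b[b$elety == "CA", , drop = FALSE]
    if (nrow(a) != 1 || nrow(b) != 1)
      stop("ca-ca mode needs selections resolving to exactly one C-alpha each ",
           "(got ", nrow(a), " and ", nrow(b), ")")
  } else {
    a <- a[a$elesy != "H", , drop = FALSE]
    b <- b[b$elesy != "H", , drop = FALSE]
  }
  d2 <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2 + outer(a$z, b$z, `-`)^2
  sqrt(min(d2))
}
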