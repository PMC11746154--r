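#' Idealized B-form helical parameters
#'
#' Defaults are 36 degrees of twist per base-pair step (10 bp/turn) and a
#' 3.38 Angstrom rise.  Guard rails reject values outside 20-45 degrees
#' and 2.5-4.5 Angstrom.
#'
#' @param twist degrees per base-pair step.
#' @param rise Angstrom per base-pair step.
#' @return Object of class `helix_params`.
#' @export
helix_params <- function(twist = 36, rise = 3.38) {
  if (!is.finite(twist) || twist < 20 || twist > 45)
    stop("twist must be in [20, 45] degrees")
  if (!is.finite(rise) || rise < 2.5 || rise > 4.5)
    stop("rise must be in [2.5, 4.5] Angstrom")
  structure(list(twist = twist, rise = rise), class = "helix_params")
}

#' @export
print.helix_params <- function(x, ...) {
  cat(sprintf("B-form helix: twist %.2f deg/bp (%.2f bp/turn), rise %.2f A/bp\n",
              x$twist, 360 / x$twist, x$rise))
  invisible(x)
}

# Coarse one-base-pair template in the local bp frame (helix axis +z, dyad
# +x).  Cylindrical anchors (radius A, azimuth deg, z A) for the reference
# strand; the partner strand is the dyad image (x, -y, -z).  Values give a
# 10.5 A cross-pair C1'-C1' separation and a 6.5 A intra-strand P-P step at
# the default twist/rise -- adequate anchors for frame math and docking
# (clash counting never uses rail atoms).
bp_template_polar <- list(
  P    = c(r = 8.90, phi = 95, z = 2.10),
  `C1'` = c(r = 5.85, phi = 64, z = 0.00),
  GLYC = c(r = 4.50, phi = 54, z = 0.00),
  WC   = c(r = 2.90, phi = 32, z = 0.00),   # central Watson-Crick H-bond atom
  C2   = c(r = 3.00, phi = 30, z = 0.00),
  C4   = c(r = 3.40, phi = 70, z = 0.00)
)

polar_xyz <- function(p) {
  a <- p[["phi"]] * pi / 180
  c(p[["r"]] * cos(a), p[["r"]] * sin(a), p[["z"]])
}

# atoms of one nucleotide of the reference strand in the local bp frame;
# glycosidic N is N9 (purine) or N1 (pyrimidine), and the central WC
# hydrogen-bond atom is N1 (purine) or N3 (pyrimidine) so that the
# cross-pair N1-N3 distance is ~3 A (the basis for duplex pairing)
nt_template <- function(base) {
  purine <- base %in% c("A", "G")
  xyz <- rbind(P = polar_xyz(bp_template_polar$P),
               `C1'` = polar_xyz(bp_template_polar$`C1'`),
               glyc = polar_xyz(bp_template_polar$GLYC),
               wc = polar_xyz(bp_template_polar$WC),
               C2 = polar_xyz(bp_template_polar$C2),
               C4 = polar_xyz(bp_template_polar$C4))
  rownames(xyz)[3] <- if (purine) "N9" else "N1"
  rownames(xyz)[4] <- if (purine) "N1" else "N3"
  xyz
}

# O3'(i) sits 1.6 A from P(i+1) back toward C1'(i); computed in frame i
o3_template <- function(params) {
  p_next <- rt_apply(helical_frame_at(params, 1), polar_xyz(bp_template_polar$P))
  c1 <- polar_xyz(bp_template_polar$`C1'`)
  v <- c1 - p_next
  p_next + 1.6 * v / sqrt(sum(v^2))
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Per-base-pair helical frame
#'
#' `helical_frame_at(params, i)` is the rigid transform placing the
#' canonical base-pair template at step `i` (0-based from the fixed end):
#' `frame(i) = step^i` with `step` a rotation by `twist` about +z composed
#' with a `rise` translation along +z.
#'
#' @param params a [helix_params].
#' @param i base-pair index, 0-based.  May be negative (frames extend the
#'   helix) unless `n_bp` is given.
#' @param n_bp optional duplex length; if given, `i` must lie in
#'   `[0, n_bp - 1]`.
#' @return A [rigid_xform].
#' @export
helical_frame_at <- function(params, i, n_bp = NULL) {
  stopifnot(inherits(params, "helix_params"), length(i) == 1, i == round(i))
  if (!is.null(n_bp) && (i < 0 || i >= n_bp))
    stop("bp index ", i, " out of range [0, ", n_bp - 1, "]")
  rigid_xform(rt_rotation_z(i * params$twist)$rotation, c(0, 0, i * params$rise))
}

#' @rdname helical_frame_at
#' @export
helix_step <- function(params) helical_frame_at(params, 1)

#' Build an idealized B-form DNA duplex
#'
#' Generates a coarse-anchor duplex (P, C1', glycosidic N1/N9, C2/C4 ring
#' anchors and O3' per nucleotide) from the one-base-pair template swept
#' along the helical frames.  Strand `A` is the input sequence 5'-3' with
#' residue 1 at base pair 0 (the fixed end); strand `B` is its reverse
#' complement, antiparallel, with residue 1 at the last base pair.  The 5'
#' terminal residue of each strand has no phosphate.
#'
#' @param sequence DNA string over A/C/G/T, length >= 2.
#' @param params a [helix_params].
#' @param id structure id.
#' @return An [mmstruct] with attribute `helix` recording the parameters,
#'   length and the bp-index-to-residue mapping of both strands.
#' @export
build_bform_duplex <- function(sequence, params = helix_params(), id = "bdna") {
  bases <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad)) stop("invalid base '", bases[bad[1]], "' at position ", bad[1])
  n <- length(bases)
  if (n < 2) stop("sequence must have length >= 2")
  o3 <- o3_template(params)
  flip <- rt_rotation(c(1, 0, 0), 180)
  rows <- list()
  for (i in seq_len(n)) {       # strand A residue i <-> bp i-1
    tpl <- rbind(nt_template(bases[i]), `O3'` = o3)
    if (i == 1) tpl <- tpl[rownames(tpl) != "P", , drop = FALSE]
    xyz <- rt_apply(helical_frame_at(params, i - 1), tpl)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "A", resno = i, resid = paste0("D", bases[i]),
      elety = rownames(tpl), elesy = substr(rownames(tpl), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  for (j in seq_len(n)) {       # strand B residue j <-> bp n-j
    b <- COMP[[bases[n - j + 1]]]
    tpl <- rbind(nt_template(b), `O3'` = o3)
    if (j == 1) tpl <- tpl[rownames(tpl) != "P", , drop = FALSE]
    xyz <- rt_apply(helical_frame_at(params, n - j) %o% flip, tpl)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "B", resno = j, resid = paste0("D", b),
      elety = rownames(tpl), elesy = substr(rownames(tpl), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  s <- mmstruct(do.call(rbind, rows), id = id)
  attr(s, "helix") <- list(params = params, n_bp = n,
                           chainA = "A", chainB = "B",
                           # bp index b (0-based) -> resno on each strand
                           resno_A = function(b) b + 1L,
                           resno_B = function(b) n - b)
  s
}
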