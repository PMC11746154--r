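#' Synthetic DNA-bound complex with known clash-onset geometry
#'
#' Builds a download-free stand-in for a DNA-end-bound complex: an
#' idealized duplex with a 5' overhang on the reference strand and a
#' rigid excluded-volume "protein" envelope attached to the DNA frame.
#' Envelope pseudo-atoms are carbon (so the shared radius table applies)
#' with residue name `ENV`, keeping them selectable but excluded from the
#' protein class.  Two envelope shapes are available:
#'
#' * `envelope_sphere()`: a spherical shell centred on the helix axis.
#'   Atoms lie on a deterministic Fibonacci lattice plus the two axis
#'   poles, so in a double-end dock the minimal inter-envelope atom
#'   distance equals the centre separation minus `2 * radius` exactly and
#'   the clash-onset duplex length has the closed form computed by
#'   [analytic_clash_onset()].
#' * `envelope_wrap()`: a left-handed helical wrap of atoms around the
#'   duplex (azimuth decreasing as the position advances along the
#'   helix), emulating how DNA-end-binding complexes wrap their duplex.
#'
#' @param dna_length duplex length, bp.
#' @param overhang 5' overhang length, nt (on the reference strand,
#'   extending beyond bp 0).
#' @param envelope an `envelope_sphere()` or `envelope_wrap()` spec.
#' @param params a [helix_params].
#' @param seed RNG seed (drives the optional `jitter` only; the base
#'   geometry is deterministic).
#' @return An [mmstruct] with chains `A` (reference strand,
#'   overhang + duplex), `B` (complementary strand) and `E` (envelope),
#'   plus attribute `toy` recording the generating spec.
#' @export
make_toy_complex <- function(dna_length = 25, overhang = 2,
                             envelope = envelope_sphere(),
                             params = helix_params(), seed = 1) {
  stopifnot(dna_length >= 6, overhang >= 0)
  seq <- paste(rep_len(strsplit("ACGT", "")[[1]], dna_length), collapse = "")
  dna <- build_bform_duplex(seq, params)
  a <- dna$atoms[c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")]
  a$resno[a$chain == "A"] <- a$resno[a$chain == "A"] + overhang
  if (overhang > 0) {
    ov <- list()
    for (j in seq_len(overhang)) {          # resno overhang+1-j at frame -j
      tpl <- nt_template("A")
      if (overhang + 1 - j == 1) tpl <- tpl[rownames(tpl) != "P", , drop = FALSE]
      xyz <- rt_apply(helical_frame_at(params, -j), tpl)
      ov[[j]] <- data.frame(chain = "A", resno = overhang + 1L - j,
                            resid = "DA", elety = rownames(tpl),
                            elesy = substr(rownames(tpl), 1, 1),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }
    a <- rbind(do.call(rbind, ov), a)
  }
  env <- envelope_atoms(envelope, dna_length, params, seed)
  s <- mmstruct(rbind(a, env), id = "toy_complex")
  attr(s, "toy") <- list(dna_length = dna_length, overhang = overhang,
                         envelope = envelope, params = params, seed = seed)
  s
}

#' @param radius envelope radius, Angstrom (> 0).
#' @param center_bp axial centre position in bp from the overhang-proximal
#'   duplex end (default: mid-duplex).
#' @param n_atoms number of envelope pseudo-atoms.
#' @param jitter s.d. of optional Gaussian positional jitter, Angstrom.
#' @rdname make_toy_complex
#' @export
envelope_sphere <- function(radius = 10, center_bp = NULL, n_atoms = 200,
                            jitter = 0) {
  if (!is.finite(radius) || radius <= 0) stop("envelope radius must be > 0")
  structure(list(type = "sphere", radius = radius, center_bp = center_bp,
                 n_atoms = n_atoms, jitter = jitter), class = "toy_envelope")
}

#' @param pitch axial advance per full turn of the wrap, Angstrom.
#' @param arc total arc swept by the wrap, degrees (0 degenerates to a
#'   straight line of atoms).
#' @rdname make_toy_complex
#' @export
envelope_wrap <- function(radius = 14, pitch = 34, arc = 540, n_atoms = 150,
                          jitter = 0) {
  if (!is.finite(radius) || radius <= 0) stop("envelope radius must be > 0")
  structure(list(type = "wrap", radius = radius, pitch = pitch, arc = arc,
                 n_atoms = n_atoms, jitter = jitter), class = "toy_envelope")
}

envelope_atoms <- function(envelope, dna_length, params, seed) {
  n <- envelope$n_atoms
  if (envelope$type == "sphere") {
    cb <- if (is.null(envelope$center_bp)) (dna_length - 1) / 2 else envelope$center_bp
    ctr <- c(0, 0, cb * params$rise)
    pts <- rbind(fibonacci_sphere(max(1L, n - 2L)) * envelope$radius,
                 c(0, 0, envelope$radius), c(0, 0, -envelope$radius))
    pts <- sweep(pts, 2, ctr, `+`)
  } else {
    t <- seq(0, envelope$arc, length.out = n)
    phi <- -t * pi / 180                    # left-handed: azimuth decreases
    z <- envelope$pitch * t / 360
    pts <- cbind(envelope$radius * cos(phi), envelope$radius * sin(phi), z)
  }
  if (envelope$jitter > 0) {
    set.seed(seed)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, envelope$jitter),
                        ncol = 3)
  }
  data.frame(chain = "E", resno = seq_len(nrow(pts)), resid = "ENV",
             elety = "C", elesy = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Analytic clash-onset length for a sphere-envelope toy
#'
#' For a sphere envelope of radius `R` centred on the helix axis at
#' `z_c = center_bp * rise`, a double-end dock at duplex length `L`
#' places the two envelope centres `(L - 1) * rise - 2 * z_c` apart, and
#' the closest atom pair are the two axis poles, at that distance minus
#' `2 R`.  A clash requires vdW overlap `2 r_C - d >= cutoff`, so the
#' shortest clash-free length is the smallest integer `L` with
#' `(L - 1) * rise - 2 z_c - 2 R > 2 r_C - cutoff`.
#'
#' @param toy a sphere-envelope toy from [make_toy_complex()].
#' @param overlap_cutoff clash overlap cutoff, Angstrom.
#' @return smallest clash-free duplex length, bp.
#' @export
analytic_clash_onset <- function(toy, overlap_cutoff = 0.6) {
  spec <- attr(toy, "toy")
  if (is.null(spec) || spec$envelope$type != "sphere")
    stop("analytic onset is defined for sphere-envelope toys only")
  params <- spec$params
  cb <- if (is.null(spec$envelope$center_bp)) (spec$dna_length - 1) / 2
        else spec$envelope$center_bp
  zc <- cb * params$rise
  rC <- vdw_radius("C")
  q <- (2 * zc + 2 * spec$envelope$radius + 2 * rC - overlap_cutoff) / params$rise
  as.integer(floor(q + 1 + 1e-9) + 1)
}

#' Perturbed structure pair with calibrated RMSD bounds
#'
#' Returns a copy of `base` moved by a random rigid transform with i.i.d.
#' Gaussian coordinate noise added, together with a 99% interval for the
#' RMSD after optimal rigid refitting: with `n` atoms the refitted sum of
#' squared residuals is approximately `sigma^2` times a chi-square with
#' `3n - 6` degrees of freedom (six degrees absorbed by the fitted
#' rotation and translation).
#'
#' @param base an [mmstruct].
#' @param sigma coordinate noise s.d., Angstrom (>= 0).
#' @param seed RNG seed.
#' @return List with `fixed` (= base), `mobile` (transformed + noisy
#'   copy), `expected_rmsd_bounds` (99% interval) and `sigma`.
#' @export
make_perturbed_pair <- function(base, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  set.seed(seed)
  n <- n_atoms(base)
  axis <- stats::rnorm(3)
  t <- rt_translation(stats::runif(3, -20, 20)) %o%
    rt_rotation(axis, stats::runif(1, 0, 360))
  mobile <- transform_structure(base, t)
  if (sigma > 0)
    coords(mobile) <- coords(mobile) + matrix(stats::rnorm(3 * n, 0, sigma),
                                              ncol = 3)
  df <- max(1, 3 * n - 6)
  bounds <- if (sigma == 0) c(0, 0)
            else sqrt(sigma^2 * stats::qchisq(c(0.005, 0.995), df) / n)
  list(fixed = base, mobile = mobile, expected_rmsd_bounds = bounds,
       sigma = sigma)
}
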