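#' Run configuration
#'
#' All tunable thresholds of the analyses, fully serializable to YAML so
#' every report can embed the configuration that produced it.
#'
#' @param twist,rise helical parameters (see [helix_params()]).
#' @param overlap_cutoff clash overlap cutoff, Angstrom.
#' @param probe,n_points SASA settings.
#' @param lmin,lmax scanned duplex-length range, bp.
#' @param coorient_tol co-orientation tolerance, degrees.
#' @param max_clashes clash-count epsilon still treated as clash-free.
#' @param seed seed for any randomized component.
#' @return List of class `run_config`.
#' @export
run_config <- function(twist = 36, rise = 3.38, overlap_cutoff = 0.6,
                       probe = 1.4, n_points = 960, lmin = 20, lmax = 45,
                       coorient_tol = 18, max_clashes = 0, seed = 1) {
  structure(list(helix = list(twist = twist, rise = rise),
                 clash = list(overlap_cutoff = overlap_cutoff),
                 sasa = list(probe = probe, n_points = n_points),
                 scan = list(lmin = lmin, lmax = lmax,
                             coorient_tol = coorient_tol,
                             max_clashes = max_clashes),
                 seed = seed), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[k]])) {
      for (k2 in intersect(names(raw[[k]]), names(cfg[[k]])))
        cfg[[k]][[k2]] <- raw[[k]][[k2]]
    } else cfg[[k]] <- raw[[k]]
  }
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' @export
print.run_config <- function(x, ...) {
  cat("run config (hash", substr(config_hash(x), 1, 8), "):\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

as_structure <- function(x) {
  if (inherits(x, "mmstruct")) x else read_structure(x)
}

#' Double-end spacing pipeline
#'
#' Docks two copies of a DNA-bound complex on opposite ends of an
#' idealized duplex, scans clash count against duplex length, and reports
#' the shortest co-oriented clash-free spacing plus the qualifying-length
#' periodicity.  Writes `scan.tsv` and `spacing_summary.json` (both
#' embedding the config hash) when `outdir` is given.
#'
#' @param complex an [mmstruct] or a structure file path.
#' @param config a [run_config].
#' @param outdir output directory (created if needed); NULL = no files.
#' @return List of class `spacing_pipeline`: `scan` (the
#'   [clash_vs_length_scan()] table), `summary`
#'   (a [min_cooriented_clashfree()] result), `config`.
#' @export
run_spacing_pipeline <- function(complex, config = run_config(),
                                 outdir = NULL) {
  complex <- as_structure(complex)
  params <- helix_params(config$helix$twist, config$helix$rise)
  crit <- clash_criterion(config$clash$overlap_cutoff)
  spec <- dock_spec(complex)
  scan <- clash_vs_length_scan(spec, config$scan$lmin:config$scan$lmax,
                               criterion = crit, params = params,
                               coorient_tol = config$scan$coorient_tol)
  summary <- min_cooriented_clashfree(scan, config$scan$coorient_tol,
                                      config$scan$max_clashes)
  hash <- config_hash(config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(outdir, "scan.tsv")
    con <- file(tsv, "w")
    writeLines(sprintf("# spo11dock spacing scan | config %s", hash), con)
    utils::write.table(format(as.data.frame(scan), trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    jsonlite::write_json(
      list(config_hash = hash,
           min_cooriented_clashfree_bp = summary$min_length,
           qualifying_lengths_bp = summary$qualifying,
           qualifying_step_bp = summary$step,
           config = unclass(config)),
      file.path(outdir, "spacing_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(scan = scan, summary = summary, config = config,
                 config_hash = hash), class = "spacing_pipeline")
}

#' @export
print.spacing_pipeline <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Pre-break dimer pipeline
#'
#' Builds the B-form co-docked control dimer (clashing for real
#' complexes), then the template-guided dimer by domain-split rigid-body
#' alignment, and reports the dimer metrics plus the clash comparison.
#' Writes `dimer_metrics.json` when `outdir` is given.
#'
#' @param complex an [mmstruct] or path.
#' @param template dimeric template [mmstruct] or path.
#' @param split a [domain_split] for the complex.
#' @param mapping residue mapping data.frame or TSV path (see
#'   [build_topo6_templated_dimer()]).
#' @param template_chains length-2 protomer chain ids in `template`.
#' @param config a [run_config].
#' @param outdir output directory; NULL = no files.
#' @return List of class `dimer_pipeline`: `codocked`, `templated`,
#'   `metrics`, `clash_reduction` (codocked minus templated protein
#'   clash count), `config`.
#' @export
run_dimer_pipeline <- function(complex, template, split, mapping,
                               template_chains, config = run_config(),
                               outdir = NULL) {
  complex <- as_structure(complex)
  template <- as_structure(template)
  if (is.character(mapping)) mapping <- read_mapping(mapping)
  params <- helix_params(config$helix$twist, config$helix$rise)
  crit <- clash_criterion(config$clash$overlap_cutoff)
  codocked <- build_bform_codocked_dimer(complex, params, crit)
  templated <- build_topo6_templated_dimer(complex, template, split, mapping,
                                           template_chains, crit)
  m <- templated$metrics
  hash <- config_hash(config)
  out <- structure(list(codocked = codocked, templated = templated,
                        metrics = m,
                        clash_reduction = codocked$clashes$n_clashes -
                          templated$clashes$n_clashes,
                        config = config, config_hash = hash),
                   class = "dimer_pipeline")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config_hash = hash,
           rmsd_N = m$rmsd_N, n_pairs_N = m$n_pairs_N,
           rmsd_C = m$rmsd_C, n_pairs_C = m$n_pairs_C,
           wh_rotation_deg = m$wh_rotation,
           inter_dna_angle_deg = m$inter_dna_angle,
           axis_offset_A = m$axis_offset,
           end_separation_A = m$end_separation,
           templated_protein_clashes = templated$clashes$n_clashes,
           codocked_protein_clashes = codocked$clashes$n_clashes,
           codocked_protein_dna_clashes =
             codocked$dna_clashes[[1]]$n_clashes +
             codocked$dna_clashes[[2]]$n_clashes,
           config = unclass(config)),
      file.path(outdir, "dimer_metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.dimer_pipeline <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("clash reduction vs B-form co-dock: %d -> %d\n",
              x$codocked$clashes$n_clashes, x$templated$clashes$n_clashes))
  invisible(x)
}
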