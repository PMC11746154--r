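#' Atom-level structure container
#'
#' `mmstruct` is the uniform atom-level data model used throughout the
#' package: a flat atom table with chain id, author residue number, residue
#' name, atom name, element, coordinates (Angstrom), occupancy and a
#' hetero flag.  Author (deposited) numbering is the single numbering
#' scheme used everywhere.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`, and optionally `occ` (default 1) and `het`
#'   (default FALSE).
#' @param id short identifier.
#' @param source optional list recording file path and format.
#' @return Object of class `mmstruct`.
#' @export
mmstruct <- function(atoms, id = "", source = NULL) {
  req <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms <- atoms[c(req, "occ", "het")]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- toupper(as.character(atoms$resid))
  atoms$elety <- as.character(atoms$elety)
  atoms$elesy <- toupper(trimws(as.character(atoms$elesy)))
  if (nrow(atoms)) {
    if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
      stop("non-finite atom coordinates")
    if (any(!nzchar(atoms$elesy))) stop("empty element symbol")
  }
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source = source), class = "mmstruct")
}

#' @rdname mmstruct
#' @param s an `mmstruct`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinates of a structure
#' @param s an `mmstruct`.
#' @return numeric n x 3 matrix.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' @rdname coords
#' @param value n x 3 coordinate matrix.
#' @export
`coords<-` <- function(s, value) {
  stopifnot(nrow(value) == n_atoms(s), ncol(value) == 3)
  s$atoms[, c("x", "y", "z")] <- value
  s
}

#' Apply a rigid transform to a structure
#' @param s an `mmstruct`.
#' @param t a `rigid_xform`.
#' @return the transformed `mmstruct`.
#' @export
transform_structure <- function(s, t) {
  coords(s) <- rt_apply(t, coords(s))
  s
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "SEC", "PYL")
NUC <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "U", "I")
IONS <- c("MG", "ZN", "NA", "K", "CA", "MN", "FE", "CL", "CD", "NI", "CU")

#' Classify residue names
#'
#' Residues are classified as `protein`, `nucleic`, `ion` or `other`
#' (ligands, pseudo-atoms such as the synthetic `ENV` envelope) by their
#' residue name.
#'
#' @param resid character vector of residue names.
#' @return character vector of classes.
#' @export
residue_class <- function(resid) {
  resid <- toupper(resid)
  ifelse(resid %in% AA3, "protein",
         ifelse(resid %in% NUC, "nucleic",
                ifelse(resid %in% IONS, "ion", "other")))
}

#' Van der Waals radii
#'
#' Bondi-like element radii used for clash detection and surface areas:
#' C 1.70, N 1.55, O 1.52, P 1.80, S 1.80, Mg 1.73, anything else 1.70
#' Angstrom.  Hydrogens (absent from cryo-EM models) are ignored throughout.
#'
#' @param element character vector of element symbols.
#' @param table named radius table to override the default.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, table = vdw_radii_default()) {
  r <- table[toupper(element)]
  r[is.na(r)] <- attr(table, "default")
  unname(r)
}

#' @rdname vdw_radius
#' @export
vdw_radii_default <- function() {
  structure(c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, MG = 1.73),
            default = 1.70)
}

#' @export
print.mmstruct <- function(x, ...) {
  a <- x$atoms
  cl <- residue_class(a$resid)
  rid <- paste(a$chain, a$resno)
  cat(sprintf("mmstruct '%s': %d atoms, %d residues, %d chains\n",
              x$id, nrow(a), length(unique(rid)), length(unique(a$chain))))
  if (nrow(a)) {
    tab <- table(cl[!duplicated(rid)])
    cat("  residues by class:",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.mmstruct <- function(object, ...) {
  a <- object$atoms
  rid <- paste(a$chain, a$resno)
  res <- a[!duplicated(rid), c("chain", "resno", "resid")]
  res$class <- residue_class(res$resid)
  structure(list(id = object$id, n_atoms = nrow(a), residues = res,
                 chains = unique(a$chain)), class = "summary.mmstruct")
}

#' @export
print.summary.mmstruct <- function(x, ...) {
  cat(sprintf("mmstruct '%s': %d atoms\n", x$id, x$n_atoms))
  print(table(chain = x$residues$chain, class = x$residues$class))
  invisible(x)
}

#' Residue table of a structure
#'
#' One row per (chain, resno) with residue name and polymer class.
#' @param s an `mmstruct`.
#' @export
residues <- function(s) {
  a <- s$atoms
  rid <- paste(a$chain, a$resno)
  res <- a[!duplicated(rid), c("chain", "resno", "resid")]
  res$class <- residue_class(res$resid)
  rownames(res) <- NULL
  res
}

#' Merge structures into one assembly
#'
#' Concatenates atom tables.  If `disambiguate = TRUE`, chains of later
#' structures that collide with earlier chain ids are renamed to unused
#' single-character ids and the mapping is attached as attribute
#' `chain_map` (a named character vector per input).
#'
#' @param ... `mmstruct` objects.
#' @param id id for the merged structure.
#' @param disambiguate rename colliding chain ids?
#' @export
merge_structures <- function(..., id = "assembly", disambiguate = TRUE) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "mmstruct"))
    parts <- parts[[1]]
  pool <- c(LETTERS, letters, as.character(0:9))
  used <- character()
  maps <- vector("list", length(parts))
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    a <- parts[[i]]$atoms
    ch <- unique(a$chain)
    map <- stats::setNames(ch, ch)
    if (disambiguate) {
      for (c0 in ch) {
        if (map[[c0]] %in% used) {
          avail <- setdiff(pool, c(used, unname(map)))
          if (!length(avail)) stop("ran out of chain ids while disambiguating")
          map[[c0]] <- avail[1]
        }
      }
      a$chain <- unname(map[a$chain])
    }
    used <- c(used, unname(map))
    maps[[i]] <- map
    out[[i]] <- a
  }
  s <- mmstruct(do.call(rbind, out), id = id)
  attr(s, "chain_map") <- maps
  s
}
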