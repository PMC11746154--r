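#' Read a macromolecular structure
#'
#' Reads PDB or mmCIF files into the package's atom-level [mmstruct]
#' container.  Parsing of both formats is delegated to bio3d; alternate
#' locations are resolved to the highest-occupancy conformer (ties broken
#' by first altloc label alphabetically), and hydrogens are kept as read
#' (downstream clash/SASA code ignores them).
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension, falling
#'   back to content sniffing).
#' @param id structure id (default: file base name).
#' @return An [mmstruct].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  raw <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure in ", path)
  unq <- function(x) ifelse(grepl("^(['\"]).*\\1$", x),          # CIF quoting
                            substr(x, 2, nchar(x) - 1), x)
  a$elety <- unq(a$elety)
  a$resid <- unq(a$resid)
  elesy <- a$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(a))
  elesy <- ifelse(is.na(elesy) | !nzchar(trimws(elesy)),
                  guess_element(a$elety, a$resid), trimws(elesy))
  atoms <- data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
                      resno = a$resno, resid = a$resid, elety = a$elety,
                      elesy = toupper(elesy),
                      x = a$x, y = a$y, z = a$z,
                      occ = ifelse(is.na(a$o), 1, a$o),
                      het = a$type == "HETATM",
                      alt = ifelse(is.na(a$alt), "", a$alt),
                      stringsAsFactors = FALSE)
  atoms <- resolve_altlocs(atoms)
  mmstruct(atoms[setdiff(names(atoms), "alt")],
           id = if (is.null(id)) sub("\\.(pdb|ent|cif|mmcif)$", "",
                                     basename(path), ignore.case = TRUE) else id,
           source = list(path = path, format = format))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("cif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- readLines(path, n = 20L, warn = FALSE)
  if (any(grepl("^data_|^loop_|^_atom_site", head))) "cif" else "pdb"
}

# keep the highest-occupancy altloc per atom; ties -> first label alphabetically
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

guess_element <- function(elety, resid) {
  up <- toupper(resid)
  ion <- up %in% IONS & toupper(elety) == up
  e <- sub("^[0-9']*", "", toupper(elety))
  e <- substr(e, 1, 1)
  ifelse(ion, up, e)
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output goes through bio3d; mmCIF output writes a minimal
#' `atom_site` loop (category keys only, no header metadata).  Chain ids
#' longer than the PDB format allows are renamed to free single-character
#' ids with the mapping reported via `message()` and returned as attribute
#' `chain_map`.
#'
#' @param s an [mmstruct] (non-empty).
#' @param path output file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by extension).
#' @return `path`, invisibly (with attribute `chain_map` if renamed).
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (n_atoms(s) == 0) stop("refusing to write an empty structure")
  a <- s$atoms
  map <- NULL
  if (format == "pdb") {
    long <- unique(a$chain[nchar(a$chain) > 1])
    if (length(long)) {
      avail <- setdiff(c(LETTERS, letters, as.character(0:9)), unique(a$chain))
      if (length(avail) < length(long)) stop("too many chains to fit PDB format")
      map <- stats::setNames(avail[seq_along(long)], long)
      message("renaming chains for PDB output: ",
              paste(names(map), "->", map, collapse = ", "))
      a$chain <- ifelse(a$chain %in% long, map[a$chain], a$chain)
    }
    bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety, o = a$occ, b = rep(0, nrow(a)),
                     elesy = a$elesy, end = TRUE)
  } else {
    write_mmcif(a, path, id = if (nzchar(s$id)) s$id else "structure")
  }
  out <- invisible(path)
  attr(out, "chain_map") <- map
  out
}

# minimal mmCIF atom_site writer (no installed R package writes mmCIF);
# fields follow the canonical wwPDB column order
write_mmcif <- function(a, path, id) {
  q <- function(x) ifelse(grepl("['\" ]", x), paste0('"', x, '"'), x)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", id)),
    "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$elesy,
            q(a$elety), a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$occ, 0, a$resno, a$resid, a$chain, q(a$elety)),
    "#")
  writeLines(lines, path)
  invisible(path)
}

#' Extract the base sequence of a nucleic chain
#'
#' @param s an [mmstruct].
#' @param chain chain id.
#' @return single-letter base string in residue-number (5' to 3') order.
#' @export
dna_sequence <- function(s, chain) {
  res <- residues(s)
  res <- res[res$chain == chain & res$class == "nucleic", , drop = FALSE]
  if (!nrow(res)) stop("no nucleic residues in chain ", chain)
  res <- res[order(res$resno), ]
  paste(sub("^D", "", res$resid), collapse = "")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}
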