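#' Declarative atom selections
#'
#' `sel()` builds a composable filter over chain id, residue number,
#' residue name, atom name, polymer class and hetero flag.  Selections
#' combine with `&`, `|` and `!`, and are evaluated against a structure by
#' [select_atoms()] (returning a sub-structure) or [sel_mask()] (returning
#' a logical mask).  An empty `sel()` matches everything.
#'
#' @param chain chain ids to match.
#' @param resno residue numbers (vector; use `a:b` for ranges).
#' @param resid residue names (e.g. `"LYS"`, `"DA"`).
#' @param elety atom names (e.g. `"CA"`, `"P"`, `"C1'"`).
#' @param polymer polymer classes among `"protein"`, `"nucleic"`, `"ion"`,
#'   `"other"` (see [residue_class()]).
#' @param het match only hetero (TRUE) or only non-hetero (FALSE) atoms.
#' @return An object of class `atom_sel`.
#' @examples
#' s <- sel(chain = "A", polymer = "protein") & sel(elety = "CA")
#' @export
sel <- function(chain = NULL, resno = NULL, resid = NULL, elety = NULL,
                polymer = NULL, het = NULL) {
  structure(list(op = "leaf",
                 chain = chain, resno = resno,
                 resid = if (is.null(resid)) NULL else toupper(resid),
                 elety = elety, polymer = polymer, het = het),
            class = "atom_sel")
}

#' @rdname sel
#' @export
sel_all <- function() sel()

#' @rdname sel
#' @export
sel_none <- function() !sel()

#' @export
`&.atom_sel` <- function(e1, e2) structure(list(op = "and", a = e1, b = e2),
                                           class = "atom_sel")

#' @export
`|.atom_sel` <- function(e1, e2) structure(list(op = "or", a = e1, b = e2),
                                           class = "atom_sel")

#' @export
`!.atom_sel` <- function(x) structure(list(op = "not", a = x), class = "atom_sel")

#' Evaluate a selection as a logical mask
#' @param s an `mmstruct`.
#' @param selection an `atom_sel`.
#' @return logical vector over the atoms of `s`.
#' @export
sel_mask <- function(s, selection) {
  stopifnot(inherits(selection, "atom_sel"))
  a <- s$atoms
  eval_node <- function(node) {
    switch(node$op,
      leaf = {
        m <- rep(TRUE, nrow(a))
        if (!is.null(node$chain)) {
          if (!any(node$chain %in% a$chain))
            warning("selection references unknown chain(s): ",
                    paste(setdiff(node$chain, a$chain), collapse = ", "))
          m <- m & a$chain %in% node$chain
        }
        if (!is.null(node$resno)) m <- m & a$resno %in% node$resno
        if (!is.null(node$resid)) m <- m & a$resid %in% node$resid
        if (!is.null(node$elety)) m <- m & a$elety %in% node$elety
        if (!is.null(node$polymer)) m <- m & residue_class(a$resid) %in% node$polymer
        if (!is.null(node$het)) m <- m & a$het == node$het
        m
      },
      and = eval_node(node$a) & eval_node(node$b),
      or = eval_node(node$a) | eval_node(node$b),
      not = !eval_node(node$a),
      stop("unknown selection node"))
  }
  eval_node(selection)
}

#' Select a sub-structure
#'
#' Returns the atoms matching `selection`, preserving chain and residue
#' identity; the original structure is untouched.  Selecting everything is
#' the identity; selecting nothing yields an empty structure.
#'
#' @inheritParams sel_mask
#' @param id id for the returned structure (default: inherited).
#' @return An `mmstruct`.
#' @export
select_atoms <- function(s, selection, id = s$id) {
  mmstruct(s$atoms[sel_mask(s, selection), , drop = FALSE], id = id,
           source = s$source)
}

#' @export
print.atom_sel <- function(x, ...) {
  fmt <- function(node) {
    switch(node$op,
      leaf = {
        parts <- Filter(Negate(is.null),
                        node[c("chain", "resno", "resid", "elety", "polymer", "het")])
        if (!length(parts)) return("all")
        paste(mapply(function(n, v) {
          v <- if (is.numeric(v) && length(v) > 3)
            paste0(min(v), ":", max(v)) else paste(v, collapse = ",")
          paste0(n, "=", v)
        }, names(parts), parts), collapse = " ")
      },
      and = paste0("(", fmt(node$a), ") & (", fmt(node$b), ")"),
      or = paste0("(", fmt(node$a), ") | (", fmt(node$b), ")"),
      not = paste0("!(", fmt(node$a), ")"))
  }
  cat("atom selection:", fmt(x), "\n")
  invisible(x)
}
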