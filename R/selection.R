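#' Atom selections by chain, author residue number and atom name
#'
#' A selection names a chain, a set of author residue numbers (or all
#' residues of the chain) and one atom name per residue (default `"CA"`).
#' Resolving a selection is total: every requested residue is either
#' returned as a coordinate or reported in the `missing` list, never
#' silently dropped — so a mismatch between expected anchor numbering
#' (e.g. the POTRA anchors F24, T93, A175, Y266, N345, R421) and a
#' deposit's actual numbering is always visible.
#'
#' @param chain Chain identifier.
#' @param residues Integer vector of author residue numbers, or `NULL` for
#'   every residue in the chain.
#' @param atom Atom name (default `"CA"`).
#' @return An object of class `bam_selection`.
#' @export
selection <- function(chain, residues = NULL, atom = "CA") {
  stopifnot(length(chain) == 1, nchar(chain) >= 1, length(atom) == 1)
  if (!is.null(residues)) {
    residues <- as.integer(residues)
    if (length(residues) == 0) stop("empty residue set")
    residues <- sort(unique(residues))
  }
  structure(list(chain = chain, residues = residues, atom = atom),
            class = "bam_selection")
}

#' Parse a selection string
#'
#' Accepts `CHAIN:RESIDUES[:ATOM]`, where RESIDUES is a comma-separated
#' list of numbers and `lo-hi` ranges, or `all`. Examples:
#' `"A:24,93,175,266,345,421:CA"`, `"D:100-240"`, `"E:all"`.
#'
#' @param text Selection string.
#' @return A [selection()].
#' @export
parse_selection <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) > 3) {
    stop("selection must be CHAIN:RESIDUES[:ATOM], got '", text, "'")
  }
  atom <- if (length(parts) == 3) parts[3] else "CA"
  res_txt <- parts[2]
  if (identical(tolower(res_txt), "all")) {
    return(selection(parts[1], NULL, atom))
  }
  pieces <- strsplit(res_txt, ",", fixed = TRUE)[[1]]
  res <- unlist(lapply(pieces, function(p) {
    if (grepl("-", p, fixed = TRUE) && !grepl("^-", p)) {
      lohi <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (length(lohi) != 2 || anyNA(lohi)) stop("bad range '", p, "'")
      seq(lohi[1], lohi[2])
    } else {
      v <- suppressWarnings(as.integer(p))
      if (is.na(v)) stop("bad residue number '", p, "'")
      v
    }
  }))
  selection(parts[1], res, atom)
}

#' @export
print.bam_selection <- function(x, ...) {
  res <- if (is.null(x$residues)) "all" else {
    if (length(x$residues) > 8) {
      paste0(length(x$residues), " residues [",
             min(x$residues), "-", max(x$residues), "]")
    } else paste(x$residues, collapse = ",")
  }
  cat("<selection> chain ", x$chain, ", residues ", res, ", atom ",
      x$atom, "\n", sep = "")
  invisible(x)
}

#' Resolve a selection against a structure
#'
#' @param structure A [bam_structure()].
#' @param spec A [selection()].
#' @return A list with `points` (n x 3 matrix, ordered by author residue
#'   number), `resno` (residue number per row), `resid` (residue name per
#'   row, so anchor identity can be checked against expectation), and
#'   `missing` (requested residue numbers not present with the requested
#'   atom).
#' @export
resolve_selection <- function(structure, spec) {
  stopifnot(inherits(structure, "bam_structure"), inherits(spec, "bam_selection"))
  a <- structure$atoms
  ca <- a[a$chain == spec$chain, , drop = FALSE]
  if (nrow(ca) == 0) {
    stop("chain '", spec$chain, "' not present in structure '",
         structure$id, "'")
  }
  requested <- if (is.null(spec$residues)) sort(unique(ca$resno)) else spec$residues
  hit <- ca[ca$elety == spec$atom & ca$resno %in% requested, , drop = FALSE]
  hit <- hit[order(hit$resno, hit$insert), , drop = FALSE]
  ## one atom per residue number (first insertion code wins)
  hit <- hit[!duplicated(hit$resno), , drop = FALSE]
  missing <- setdiff(requested, hit$resno)
  pts <- as.matrix(hit[, c("x", "y", "z")])
  rownames(pts) <- hit$resno
  list(points = pts, resno = hit$resno, resid = hit$resid,
       missing = sort(missing))
}

## strict variant used where every residue is required
resolve_required <- function(structure, spec, what = "selection") {
  r <- resolve_selection(structure, spec)
  if (length(r$missing) > 0) {
    stop("missing residues for ", what, " on chain ", spec$chain, ": ",
         paste(r$missing, collapse = ", "))
  }
  r
}
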