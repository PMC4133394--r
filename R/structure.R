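#' @keywords internal
"_PACKAGE"

#' Construct a C-alpha structure object
#'
#' The central container of the package: a single-chain protein reduced to
#' one C-alpha atom per residue, with per-residue annotations used by the
#' contact-classification stages (secondary structure, terminal flag,
#' catalytic / active-site / mutated roles).
#'
#' @param id character label for the structure (e.g. a PDB accession).
#' @param residues data.frame with one row per residue and columns
#'   `resno` (author residue number, strictly increasing), `resid`
#'   (3-letter residue name), `x`, `y`, `z` (C-alpha coordinates in
#'   Angstrom), and optionally `ss` (one of `"helix"`, `"strand"`,
#'   `"loop"`), `is_terminal`, `catalytic`, `active_site`, `mutated`.
#'   Missing annotation columns are filled with defaults (`ss = "loop"`,
#'   flags `FALSE`).
#' @param ss_source one of `"pdb_header"`, `"external_file"`, `"none"`:
#'   where the secondary-structure labels came from.
#'
#' @return an object of class `ca_structure`.
#' @export
ca_structure <- function(id, residues, ss_source = "none") {
  stopifnot(is.character(id), length(id) == 1L, is.data.frame(residues))
  required <- c("resno", "resid", "x", "y", "z")
  missing_cols <- setdiff(required, names(residues))
  if (length(missing_cols) > 0L)
    stop("residues is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(residues) < 1L)
    stop("a structure must contain at least one residue")
  if (any(diff(residues$resno) <= 0L))
    stop("residue numbers must be strictly increasing along the chain")
  ss_source <- match.arg(ss_source, c("pdb_header", "external_file", "none"))

  n <- nrow(residues)
  residues$index <- seq_len(n)
  if (is.null(residues$ss)) residues$ss <- "loop"
  bad_ss <- !residues$ss %in% c("helix", "strand", "loop")
  if (any(bad_ss)) stop("unknown secondary-structure label: ",
                        paste(unique(residues$ss[bad_ss]), collapse = ", "))
  for (flag in c("is_terminal", "catalytic", "active_site", "mutated")) {
    if (is.null(residues[[flag]])) residues[[flag]] <- FALSE
  }
  rownames(residues) <- NULL
  out <- list(id = id,
              residues = residues[, c("index", "resno", "resid", "x", "y", "z",
                                      "ss", "is_terminal", "catalytic",
                                      "active_site", "mutated")],
              ss_source = ss_source)
  class(out) <- "ca_structure"
  out
}

#' Number of residues in a structure
#' @param x a `ca_structure`.
#' @return integer count.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "ca_structure"))
  nrow(x$residues)
}

#' C-alpha coordinate matrix
#' @param x a `ca_structure`.
#' @return numeric n-by-3 matrix (Angstrom), rows in chain order.
#' @export
ca_coords <- function(x) {
  stopifnot(inherits(x, "ca_structure"))
  m <- as.matrix(x$residues[, c("x", "y", "z")])
  rownames(m) <- x$residues$resno
  m
}

#' @export
print.ca_structure <- function(x, ...) {
  ss <- table(factor(x$residues$ss, levels = c("helix", "strand", "loop")))
  cat(sprintf("ca_structure '%s': %d residues (%d helix, %d strand, %d loop; ss from %s)\n",
              x$id, nrow(x$residues), ss[["helix"]], ss[["strand"]], ss[["loop"]],
              x$ss_source))
  invisible(x)
}

# run-length ids of secondary-structure elements; loops get NA so that
# "connects two regular elements" can require distinct element ids
ss_element_ids <- function(ss) {
  r <- rle(ss)
  ids <- rep(seq_along(r$lengths), r$lengths)
  ids[ss == "loop"] <- NA_integer_
  ids
}
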