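#' Build a protein contact network
#'
#' One node per residue (C-alpha); an undirected edge joins residues i and
#' j whenever their C-alpha distance is strictly below the cutoff
#' (default 7.0 A = 0.7 nm, the standard first-interaction-shell cutoff
#' for coarse-grained residue networks).  Sequence neighbours are included
#' like any other pair; no separation exclusion is applied.
#'
#' @param structure a [ca_structure()].
#' @param cutoff contact cutoff in Angstrom (> 0).
#' @return object of class `pcn`: list with `structure_id`, `n`, `cutoff`,
#'   `adjacency` (binary symmetric, zero diagonal), `distances`,
#'   `contacts` (data.frame `i`, `j` with `i < j`, `resno_i`, `resno_j`,
#'   `distance`, `separation`), and the `structure` itself.
#' @export
build_pcn <- function(structure, cutoff = 7.0) {
  stopifnot(inherits(structure, "ca_structure"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  d <- as.matrix(stats::dist(ca_coords(structure)))
  dimnames(d) <- NULL
  a <- (d < cutoff) * 1L
  diag(a) <- 0L
  idx <- which(a == 1L & upper.tri(a), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  contacts <- data.frame(i = idx[, 1], j = idx[, 2],
                         resno_i = structure$residues$resno[idx[, 1]],
                         resno_j = structure$residues$resno[idx[, 2]],
                         distance = d[idx],
                         separation = idx[, 2] - idx[, 1])
  structure(list(structure_id = structure$id, n = nrow(d), cutoff = cutoff,
                 adjacency = a, distances = d, contacts = contacts,
                 structure = structure),
            class = "pcn")
}

#' @export
print.pcn <- function(x, ...) {
  cat(sprintf("pcn '%s': %d nodes, %d contacts at %.2f A cutoff\n",
              x$structure_id, x$n, nrow(x$contacts), x$cutoff))
  invisible(x)
}

#' Classify contacts by sequence range and structural context
#'
#' Adds the flags used to categorise contact changes:
#' \describe{
#'   \item{range_class}{`"long"` when the sequence separation exceeds
#'     `long_range_threshold`, else `"short"`.  Helical contacts (up to
#'     i, i+4) are always short-range.}
#'   \item{involves_loop}{either endpoint is in a loop.}
#'   \item{involves_terminus}{either endpoint lies within the terminal
#'     window of a chain end.}
#'   \item{near_active_site}{either endpoint is an annotated active-site
#'     residue, or lies within `active_site_radius` of a catalytic
#'     C-alpha.}
#'   \item{connects_regular_ss}{both endpoints are in regular secondary
#'     structure (helix/strand) and in *different* elements.}
#' }
#'
#' @param pcn a [build_pcn()] network (its embedded structure supplies the
#'   annotations).
#' @param long_range_threshold sequence separation above which a contact
#'   counts as long-range (default 12).
#' @param active_site_radius Angstrom radius around catalytic C-alpha
#'   atoms for "near active site" (default 7.0, mirroring the contact
#'   cutoff).
#' @return the contact data.frame of `pcn` with classification columns
#'   appended.
#' @export
classify_contacts <- function(pcn, long_range_threshold = 12L,
                              active_site_radius = 7.0) {
  stopifnot(inherits(pcn, "pcn"))
  res <- pcn$structure$residues
  ct <- pcn$contacts
  if (nrow(ct) == 0L) {
    ct$range_class <- character(0); ct$involves_loop <- logical(0)
    ct$involves_terminus <- logical(0); ct$near_active_site <- logical(0)
    ct$connects_regular_ss <- logical(0)
    return(ct)
  }
  elem <- ss_element_ids(res$ss)
  near_cat <- rep(FALSE, nrow(res))
  cat_idx <- which(res$catalytic)
  if (length(cat_idx) > 0L)
    near_cat <- apply(pcn$distances[, cat_idx, drop = FALSE], 1,
                      function(v) any(v < active_site_radius))
  near_as <- res$active_site | near_cat

  i <- ct$i; j <- ct$j
  ct$range_class <- ifelse(ct$separation > long_range_threshold,
                           "long", "short")
  ct$involves_loop <- res$ss[i] == "loop" | res$ss[j] == "loop"
  ct$involves_terminus <- res$is_terminal[i] | res$is_terminal[j]
  ct$near_active_site <- near_as[i] | near_as[j]
  ct$connects_regular_ss <- res$ss[i] != "loop" & res$ss[j] != "loop" &
    !is.na(elem[i]) & !is.na(elem[j]) & elem[i] != elem[j]
  ct
}

#' Export a contact list as TSV
#' @param contacts (classified) contact data.frame.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_contacts_tsv <- function(contacts, file) {
  utils::write.table(contacts, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Export a network in GraphML format
#'
#' Nodes carry residue number and secondary structure; edges carry the
#' C-alpha distance and sequence separation.
#'
#' @param pcn a [build_pcn()] network.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_graphml <- function(pcn, file) {
  stopifnot(inherits(pcn, "pcn"))
  res <- pcn$structure$residues
  ct <- pcn$contacts
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="resno" for="node" attr.name="resno" attr.type="int"/>',
    '  <key id="ss" for="node" attr.name="ss" attr.type="string"/>',
    '  <key id="dist" for="edge" attr.name="distance" attr.type="double"/>',
    '  <key id="sep" for="edge" attr.name="separation" attr.type="int"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">', pcn$structure_id),
    sprintf('    <node id="n%d"><data key="resno">%d</data><data key="ss">%s</data></node>',
            res$index, res$resno, res$ss),
    sprintf('    <edge source="n%d" target="n%d"><data key="dist">%.3f</data><data key="sep">%d</data></edge>',
            ct$i, ct$j, ct$distance, ct$separation),
    '  </graph>', '</graphml>')
  writeLines(lines, file)
  invisible(file)
}
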