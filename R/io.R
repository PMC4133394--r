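#' Write a C-alpha structure as fixed-column PDB text
#'
#' Emits one `ATOM` record per residue (atom name `CA`, chain `A`, single
#' model), `HELIX`/`SHEET` header records for the runs of annotated
#' secondary structure, and `TER`/`END`.  The writer/parser pair
#' round-trips residue order, numbering, coordinates (to the 0.001 A PDB
#' column precision) and secondary-structure labels.
#'
#' @param structure a [ca_structure()].
#' @param file optional path; when given the text is written there.
#' @return character vector of PDB lines (invisibly when `file` is given).
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "ca_structure"))
  res <- structure$residues
  if (nrow(res) == 0L) stop("cannot write an empty structure")
  xyz <- as.matrix(res[, c("x", "y", "z")])
  if (any(xyz >= 10000 | xyz <= -1000))
    stop("coordinates exceed the PDB fixed-column width (%8.3f)")

  header <- character(0)
  runs <- rle(res$ss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  h <- which(runs$values == "helix")
  for (k in seq_along(h)) {
    s <- starts[h[k]]; e <- ends[h[k]]
    header <- c(header, sprintf(
      "HELIX  %3d %3s %3s %s %4d  %3s %s %4d %2d%30s%6d",
      k, sprintf("H%d", k), res$resid[s], "A", res$resno[s],
      res$resid[e], "A", res$resno[e], 1L, "", e - s + 1L))
  }
  sh <- which(runs$values == "strand")
  for (k in seq_along(sh)) {
    s <- starts[sh[k]]; e <- ends[sh[k]]
    header <- c(header, sprintf(
      "SHEET  %3d %3s%2d %3s %s%4d  %3s %s%4d %2d",
      k, sprintf("S%d", k), 1L, res$resid[s], "A", res$resno[s],
      res$resid[e], "A", res$resno[e], 0L))
  }
  atoms <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    res$index, res$resid, "A", res$resno, res$x, res$y, res$z, 1, 0, "C")
  lines <- c(header, atoms, "TER", "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Annotation configuration for residue roles
#'
#' Declares which author residue numbers carry functional roles.  Every
#' number must resolve to a residue of the structure it annotates;
#' [parse_structure()] rejects the configuration otherwise.  The catalytic
#' set is always included in the active-site set.
#'
#' @param catalytic integer residue numbers of the catalytic residues.
#' @param active_site integer residue numbers of the wider active site.
#' @param mutated mutation strings such as `"N166Y"` (parsed with
#'   [parse_mutation_string()]) or plain integer residue numbers.
#' @param terminal_window residues within this many positions of either
#'   chain end are flagged terminal (default 4).
#' @return an object of class `annotation_config`.
#' @export
annotation_config <- function(catalytic = integer(0),
                              active_site = integer(0),
                              mutated = integer(0),
                              terminal_window = 4L) {
  if (is.character(mutated)) mutated <- parse_mutation_string(mutated)$position
  stopifnot(terminal_window >= 0)
  structure(list(catalytic = as.integer(catalytic),
                 active_site = sort(unique(as.integer(c(catalytic, active_site)))),
                 mutated = as.integer(mutated),
                 terminal_window = as.integer(terminal_window)),
            class = "annotation_config")
}

#' Parse a point-mutation string
#'
#' `"N166Y"` means wild-type residue N at author position 166 replaced by
#' Y.  Vectorised.
#'
#' @param s character vector of mutation strings.
#' @return data.frame with columns `wild`, `position`, `mutant`.
#' @export
parse_mutation_string <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed mutation string(s): ", paste(s[bad], collapse = ", "))
  data.frame(wild = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 3L)),
             mutant = vapply(m, `[`, "", 4L))
}

read_pdb_input <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
    return(bio3d::read.pdb(pdb, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), tmp)
  bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
}

#' Parse a PDB file into a C-alpha structure
#'
#' Reads a PDB coordinate file (path or text), selects one protein chain,
#' keeps one C-alpha per residue, fills secondary structure from the
#' `HELIX`/`SHEET` header records (or an external two-column file), and
#' applies the role annotations of an [annotation_config()].
#'
#' Conventions: HETATM records (waters, ligands) are ignored; for
#' alternate locations the highest-occupancy conformer is kept, ties going
#' to altLoc `"A"`; only the first MODEL of a multi-model file is read;
#' the chain defaults to the first chain containing C-alpha atoms.
#'
#' @param pdb path to a PDB file, or PDB text (single string with
#'   newlines, or a character vector of lines).
#' @param config optional [annotation_config()].
#' @param chain chain identifier; default first protein chain.
#' @param ss_file optional path to a whitespace-separated two-column file
#'   (author residue number, one of `H`/`E`/`C`) overriding the header
#'   secondary structure.
#' @param id structure label; defaults to the file base name or `"pdb"`.
#' @return a [ca_structure()].
#' @export
parse_structure <- function(pdb, config = NULL, chain = NULL, ss_file = NULL,
                            id = NULL) {
  if (is.null(id)) {
    id <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
      sub("\\.(pdb|ent)$", "", basename(pdb)) else "pdb"
  }
  p <- read_pdb_input(pdb)
  at <- p$atom
  at <- at[at$type == "ATOM" & at$elety == "CA" & !at$resid %in% "HOH", ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("no C-alpha atoms found: empty structure")
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no C-alpha atoms in chain ", chain)

  # altLoc resolution: highest occupancy wins, ties prefer altLoc "A"
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(rows) {
      if (length(rows) == 1L) return(rows)
      alt <- at$alt[rows]
      if (all(is.na(alt)))
        stop("duplicate C-alpha for residue ", at$resno[rows[1L]],
             " without altLoc: malformed file")
      occ <- at$o[rows]
      occ[is.na(occ)] <- 0
      best <- rows[occ == max(occ)]
      if (length(best) > 1L) {
        pref <- best[which(at$alt[best] %in% "A")]
        best <- if (length(pref)) pref[1L] else best[1L]
      }
      best
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  n <- nrow(at)
  ss <- rep("loop", n)
  ss_source <- "none"
  if (!is.null(ss_file)) {
    tab <- utils::read.table(ss_file, header = FALSE,
                             col.names = c("resno", "ss"),
                             colClasses = c("integer", "character"))
    m <- match(at$resno, tab$resno)
    code <- c(H = "helix", E = "strand", C = "loop")
    hit <- !is.na(m)
    ss[hit] <- code[tab$ss[m[hit]]]
    ss_source <- "external_file"
  } else {
    fill <- function(rec, label) {
      if (is.null(rec) || length(rec$start) == 0L) return()
      for (k in seq_along(rec$start)) {
        if (!is.null(rec$chain) && !rec$chain[k] %in% chain) next
        hit <- at$resno >= as.integer(rec$start[k]) &
               at$resno <= as.integer(rec$end[k])
        ss[hit] <<- label
      }
    }
    fill(p$helix, "helix")
    fill(p$sheet, "strand")
    if (any(ss != "loop")) ss_source <- "pdb_header"
  }

  res <- data.frame(resno = as.integer(at$resno), resid = at$resid,
                    x = at$x, y = at$y, z = at$z, ss = ss)
  s <- ca_structure(id, res, ss_source = ss_source)
  annotate_structure(s, config)
}

#' Apply role annotations to a structure
#'
#' @param structure a [ca_structure()].
#' @param config an [annotation_config()] or `NULL` (terminal window 4,
#'   no roles).
#' @return the annotated structure.
#' @export
annotate_structure <- function(structure, config = NULL) {
  if (is.null(config)) config <- annotation_config()
  stopifnot(inherits(config, "annotation_config"))
  res <- structure$residues
  for (role in c("catalytic", "active_site", "mutated")) {
    nums <- config[[role]]
    missing <- setdiff(nums, res$resno)
    if (length(missing) > 0L)
      stop("annotation rejected: residue number(s) ",
           paste(missing, collapse = ", "), " (", role,
           ") not present in structure ", structure$id)
    res[[role]] <- res$resno %in% nums
  }
  w <- config$terminal_window
  res$is_terminal <- res$index <= w | res$index > nrow(res) - w
  structure$residues <- res
  structure
}

#' Pair residues of two structures by author residue number
#'
#' Downstream differential operations act on the matched intersection;
#' residues present in only one structure are listed separately and never
#' silently dropped into made/lost sets.
#'
#' @param ref,other [ca_structure()] objects.
#' @return object of class `residue_map`: list with `matched` (data.frame
#'   `resno`, `index_ref`, `index_other`), `unmatched_ref`,
#'   `unmatched_other` (residue numbers).
#' @export
map_residues <- function(ref, other) {
  stopifnot(inherits(ref, "ca_structure"), inherits(other, "ca_structure"))
  shared <- intersect(ref$residues$resno, other$residues$resno)
  if (length(shared) == 0L)
    stop("no residues in common between ", ref$id, " and ", other$id)
  matched <- data.frame(resno = shared,
                        index_ref = match(shared, ref$residues$resno),
                        index_other = match(shared, other$residues$resno))
  structure(list(matched = matched,
                 unmatched_ref = setdiff(ref$residues$resno, shared),
                 unmatched_other = setdiff(other$residues$resno, shared)),
            class = "residue_map")
}
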