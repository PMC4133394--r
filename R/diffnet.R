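# Differential contact analysis: which contacts a mutant makes and loses
# relative to a reference structure, with structural classification of
# each change and residue-wise metric deltas.

contact_keys <- function(contacts) {
  paste(pmin(contacts$resno_i, contacts$resno_j),
        pmax(contacts$resno_i, contacts$resno_j), sep = "-")
}

#' Contacts made and lost between a reference and a mutant network
#'
#' A contact is *made* when the residue pair (identified by author
#' residue numbers) is under the cutoff only in the mutant, *lost* when
#' only in the reference.  Comparison is restricted to the residues
#' matched between the two structures; contacts touching unmatched
#' residues are reported separately, never counted as changes.  Made
#' contacts are classified on the mutant structure (where they exist),
#' lost contacts on the reference.  Residue-wise deltas (mutant minus
#' reference) of degree, clustering, betweenness and closeness are
#' attached.
#'
#' @param ref_pcn,mut_pcn [build_pcn()] networks built at the same cutoff
#'   (comparing networks across cutoffs is refused).
#' @param long_range_threshold,active_site_radius passed to
#'   [classify_contacts()].
#' @param compute_metrics set `FALSE` to skip the per-residue metric
#'   deltas (the contact sets alone are much cheaper).
#' @return object of class `diff_report`: list with `ref_id`, `mut_id`,
#'   `cutoff`, `made`, `lost` (classified contact data.frames),
#'   `excluded` (contacts at unmatched residues), `metric_deltas`
#'   (data.frame `resno`, `d_degree`, `d_clustering`, `d_betweenness`,
#'   `d_closeness`), and `tallies` (category counts for made and lost).
#' @export
diff_contacts <- function(ref_pcn, mut_pcn, long_range_threshold = 12L,
                          active_site_radius = 7.0, compute_metrics = TRUE) {
  stopifnot(inherits(ref_pcn, "pcn"), inherits(mut_pcn, "pcn"))
  if (!isTRUE(all.equal(ref_pcn$cutoff, mut_pcn$cutoff)))
    stop("networks were built at different cutoffs (", ref_pcn$cutoff,
         " vs ", mut_pcn$cutoff, " A); differential comparison is forbidden")
  mp <- map_residues(ref_pcn$structure, mut_pcn$structure)
  matched <- mp$matched$resno

  ref_ct <- classify_contacts(ref_pcn, long_range_threshold, active_site_radius)
  mut_ct <- classify_contacts(mut_pcn, long_range_threshold, active_site_radius)

  in_matched <- function(ct) ct$resno_i %in% matched & ct$resno_j %in% matched
  ref_ok <- in_matched(ref_ct); mut_ok <- in_matched(mut_ct)
  with_origin <- function(ct, origin) {
    ct$origin <- rep(origin, nrow(ct))
    ct
  }
  excluded <- rbind(with_origin(ref_ct[!ref_ok, , drop = FALSE], "reference"),
                    with_origin(mut_ct[!mut_ok, , drop = FALSE], "mutant"))
  ref_ct <- ref_ct[ref_ok, , drop = FALSE]
  mut_ct <- mut_ct[mut_ok, , drop = FALSE]

  ref_keys <- contact_keys(ref_ct)
  mut_keys <- contact_keys(mut_ct)
  made <- mut_ct[!mut_keys %in% ref_keys, , drop = FALSE]
  lost <- ref_ct[!ref_keys %in% mut_keys, , drop = FALSE]
  rownames(made) <- rownames(lost) <- NULL

  deltas <- NULL
  if (compute_metrics) {
    ref_m <- metric_table(ref_pcn)
    mut_m <- metric_table(mut_pcn)
    ir <- match(matched, ref_m$resno); im <- match(matched, mut_m$resno)
    deltas <- data.frame(
      resno = matched,
      d_degree = mut_m$degree[im] - ref_m$degree[ir],
      d_clustering = mut_m$clustering[im] - ref_m$clustering[ir],
      d_betweenness = mut_m$betweenness[im] - ref_m$betweenness[ir],
      d_closeness = mut_m$closeness[im] - ref_m$closeness[ir])
  }

  structure(list(ref_id = ref_pcn$structure_id,
                 mut_id = mut_pcn$structure_id,
                 cutoff = ref_pcn$cutoff,
                 made = made, lost = lost, excluded = excluded,
                 metric_deltas = deltas,
                 tallies = list(made = tally_contacts(made),
                                lost = tally_contacts(lost))),
            class = "diff_report")
}

tally_contacts <- function(ct) {
  list(n = nrow(ct),
       long_range = sum(ct$range_class == "long"),
       short_range = sum(ct$range_class == "short"),
       involves_loop = sum(ct$involves_loop),
       involves_terminus = sum(ct$involves_terminus),
       near_active_site = sum(ct$near_active_site),
       connects_regular_ss = sum(ct$connects_regular_ss))
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf("diff_report %s vs %s (cutoff %.2f A): %d made, %d lost\n",
              x$mut_id, x$ref_id, x$cutoff, nrow(x$made), nrow(x$lost)))
  invisible(x)
}

#' Union of contact changes across a mutant series
#'
#' Deduplicates the made and lost sets of several [diff_contacts()]
#' reports sharing one reference, keyed on the author residue-number
#' pair.  Classification flags of a deduplicated contact are taken from
#' the first report in which it occurs; an `n_mutants` column counts in
#' how many mutants the change appears.
#'
#' @param reports list of `diff_report`s with identical `ref_id` and
#'   cutoff.
#' @return object of class `union_report`: list with `ref_id`,
#'   `unique_made`, `unique_lost` (classified contact data.frames) and
#'   `tallies`.
#' @export
union_contacts <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "diff_report")))
  refs <- unique(vapply(reports, function(r) r$ref_id, ""))
  if (length(refs) != 1L)
    stop("all reports must share one reference (got: ",
         paste(refs, collapse = ", "), ")")
  cuts <- unique(vapply(reports, function(r) r$cutoff, 0))
  if (length(cuts) != 1L) stop("all reports must share one cutoff")

  dedupe <- function(field) {
    all_ct <- do.call(rbind, lapply(reports, function(r) r[[field]]))
    if (is.null(all_ct) || nrow(all_ct) == 0L) {
      out <- reports[[1L]][[field]][0, , drop = FALSE]
      out$n_mutants <- integer(0)
      return(out)
    }
    keys <- contact_keys(all_ct)
    first <- !duplicated(keys)
    out <- all_ct[first, , drop = FALSE]
    out$n_mutants <- as.integer(table(keys)[keys[first]])
    out <- out[order(out$resno_i, out$resno_j), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  unique_made <- dedupe("made")
  unique_lost <- dedupe("lost")
  structure(list(ref_id = refs, cutoff = cuts,
                 n_mutants = length(reports),
                 unique_made = unique_made, unique_lost = unique_lost,
                 tallies = list(made = tally_contacts(unique_made),
                                lost = tally_contacts(unique_lost))),
            class = "union_report")
}

#' @export
print.union_report <- function(x, ...) {
  cat(sprintf("union_report over %d mutants vs %s: %d unique made, %d unique lost\n",
              x$n_mutants, x$ref_id, nrow(x$unique_made), nrow(x$unique_lost)))
  invisible(x)
}

#' Degree-change summary across mutants
#'
#' @param reports list of [diff_contacts()] reports.
#' @return data.frame with one row per mutant (`mut_id`,
#'   `frac_changed` = fraction of matched residues with any degree
#'   change, `max_abs_change`), plus the cross-mutant averages in
#'   `attr(, "average")`.
#' @export
degree_change_summary <- function(reports) {
  stopifnot(length(reports) >= 1L)
  rows <- do.call(rbind, lapply(reports, function(r) {
    dd <- r$metric_deltas$d_degree
    data.frame(mut_id = r$mut_id,
               frac_changed = mean(dd != 0),
               max_abs_change = if (length(dd)) max(abs(dd)) else 0)
  }))
  rownames(rows) <- NULL
  attr(rows, "average") <- list(frac_changed = mean(rows$frac_changed),
                                max_abs_change = max(rows$max_abs_change))
  rows
}

#' Residues ranked by betweenness gain
#'
#' @param report a [diff_contacts()] report.
#' @param top_k how many residues to return (descending betweenness
#'   delta, ties broken on residue number); truncated with a warning when
#'   larger than the matched residue count.
#' @return data.frame `resno`, `d_betweenness`.
#' @export
bc_gain_ranking <- function(report, top_k = 10L) {
  stopifnot(inherits(report, "diff_report"))
  d <- report$metric_deltas
  if (top_k > nrow(d)) {
    warning("top_k exceeds the number of matched residues; truncating")
    top_k <- nrow(d)
  }
  ord <- order(-d$d_betweenness, d$resno)
  out <- d[ord[seq_len(top_k)], c("resno", "d_betweenness"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a diff report (JSON summary plus made/lost TSV edge lists)
#'
#' @param report a [diff_contacts()] report.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_diff_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(report$mut_id, "_vs_", report$ref_id))
  write_contacts_tsv(report$made, paste0(stem, "_made.tsv"))
  write_contacts_tsv(report$lost, paste0(stem, "_lost.tsv"))
  jsonlite::write_json(
    list(ref_id = report$ref_id, mut_id = report$mut_id,
         cutoff = report$cutoff, tallies = report$tallies),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = 10)
  invisible(dir)
}
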