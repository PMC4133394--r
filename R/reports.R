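# Ring-graph layout and the end-to-end pipeline: parse -> networks ->
# metrics -> communities -> superposition -> differential reports, with
# deterministic TSV/JSON exports.

#' Ring-graph layout of a contact network
#'
#' Places node i at angle 2*pi*(i-1)/n on the unit circle, in sequence
#' order, and lists every contact as a chord.  Short-range (helical)
#' contacts hug the circle boundary; long-range tertiary contacts cross
#' the centre.  When a [diff_contacts()] report is supplied its made and
#' lost contacts are added as chords with class `"made"` / `"lost"`
#' alongside the network's own `"intra"` chords.
#'
#' @param pcn a [build_pcn()] network.
#' @param diff optional `diff_report`.
#' @return object of class `ring_layout`: list with `nodes` (data.frame
#'   `index`, `resno`, `angle`) and `chords` (data.frame `i`, `j`,
#'   `class`, `chord_length` on the unit circle).
#' @export
ring_layout <- function(pcn, diff = NULL) {
  stopifnot(inherits(pcn, "pcn"))
  n <- pcn$n
  nodes <- data.frame(index = seq_len(n),
                      resno = pcn$structure$residues$resno,
                      angle = 2 * pi * (seq_len(n) - 1) / n)
  chord <- function(i, j, cls) {
    if (length(i) == 0L)
      return(data.frame(i = integer(0), j = integer(0),
                        class = character(0), chord_length = numeric(0)))
    dtheta <- abs(nodes$angle[j] - nodes$angle[i])
    dtheta <- pmin(dtheta, 2 * pi - dtheta)
    data.frame(i = i, j = j, class = cls,
               chord_length = 2 * sin(dtheta / 2))
  }
  chords <- chord(pcn$contacts$i, pcn$contacts$j, "intra")
  if (!is.null(diff)) {
    stopifnot(inherits(diff, "diff_report"))
    resno <- pcn$structure$residues$resno
    add <- function(ct, cls) {
      ii <- match(ct$resno_i, resno); jj <- match(ct$resno_j, resno)
      ok <- !is.na(ii) & !is.na(jj)
      chord(ii[ok], jj[ok], cls)
    }
    chords <- rbind(chords, add(diff$made, "made"), add(diff$lost, "lost"))
  }
  rownames(chords) <- NULL
  structure(list(structure_id = pcn$structure_id, nodes = nodes,
                 chords = chords),
            class = "ring_layout")
}

#' Plot a ring layout to an SVG file
#'
#' Write-only convenience wrapper around base graphics; all information
#' in the figure comes from the exported layout tables.
#'
#' @param layout a [ring_layout()].
#' @param file SVG output path.
#' @return the path, invisibly.
#' @export
plot_ring <- function(layout, file) {
  stopifnot(inherits(layout, "ring_layout"))
  grDevices::svg(file, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  nd <- layout$nodes
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(cos(nd$angle), sin(nd$angle), asp = 1, pch = 16, cex = 0.5,
                 axes = FALSE, xlab = "", ylab = "",
                 main = layout$structure_id)
  cols <- c(intra = "grey80", made = "blue", lost = "red")
  ch <- layout$chords
  ord <- order(factor(ch$class, levels = c("intra", "made", "lost")))
  for (k in ord) {
    graphics::segments(cos(nd$angle[ch$i[k]]), sin(nd$angle[ch$i[k]]),
                       cos(nd$angle[ch$j[k]]), sin(nd$angle[ch$j[k]]),
                       col = cols[[ch$class[k]]],
                       lwd = if (ch$class[k] == "intra") 0.4 else 1.2)
  }
  invisible(file)
}

#' Pipeline configuration
#'
#' @param cutoff contact cutoff, Angstrom.
#' @param long_range_threshold sequence separation above which a contact
#'   is long-range.
#' @param terminal_window residues within this many positions of a chain
#'   end are terminal.
#' @param bc_z,cc_z z-score thresholds for betweenness / clustering
#'   outlier selection.
#' @param annotation an [annotation_config()] or `NULL`.
#' @param active_site_radius Angstrom radius for "near active site".
#' @param seed integer seed recorded in the output bundle.
#' @return object of class `run_config`.
#' @export
run_config <- function(cutoff = 7.0, long_range_threshold = 12L,
                       terminal_window = 4L, bc_z = 2.5, cc_z = 2.0,
                       annotation = NULL, active_site_radius = 7.0,
                       seed = 1L) {
  stopifnot(cutoff > 0, long_range_threshold >= 1, terminal_window >= 0)
  if (!is.null(annotation)) stopifnot(inherits(annotation, "annotation_config"))
  structure(list(cutoff = cutoff,
                 long_range_threshold = as.integer(long_range_threshold),
                 terminal_window = as.integer(terminal_window),
                 bc_z = bc_z, cc_z = cc_z, annotation = annotation,
                 active_site_radius = active_site_radius,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full differential-network pipeline
#'
#' For every structure: contact network, per-residue metrics with z-score
#' selections, fast-greedy communities, ring layout.  Across structures:
#' cross-structure RMSD matrix, residue-wise RMSD, one differential
#' report per mutant, the union report and the degree-change summary.
#' When `out_dir` is given every table is exported (TSV for per-residue
#' data, JSON for summaries) together with the resolved configuration;
#' re-running with identical inputs produces byte-identical files.
#'
#' @param ref reference structure: a [ca_structure()] or a PDB file path.
#' @param mutants list of mutant structures (same types); may be empty.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return a list bundle with elements `config`, `structures`, `pcns`,
#'   `metrics`, `bc_selection`, `cc_selection`, `partitions`, `layouts`,
#'   `rmsd`, `residuewise_rmsd`, `diffs`, `union`, `degree_summary`.
#' @export
run_pipeline <- function(ref, mutants = list(), config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  load1 <- function(x) {
    if (inherits(x, "ca_structure")) {
      ann <- config$annotation
      if (is.null(ann))
        ann <- annotation_config(terminal_window = config$terminal_window)
      annotate_structure(x, ann)
    } else {
      parse_structure(x, config = config$annotation)
    }
  }
  ref_s <- load1(ref)
  mut_s <- lapply(mutants, load1)
  all_s <- c(list(ref_s), mut_s)
  message("pipeline: ", length(all_s), " structure(s), cutoff ",
          config$cutoff, " A")

  pcns <- lapply(all_s, build_pcn, cutoff = config$cutoff)
  metrics <- lapply(pcns, metric_table)
  bc_sel <- lapply(metrics, function(m)
    zscore_select(m$betweenness, config$bc_z, m$resno))
  cc_sel <- lapply(metrics, function(m)
    zscore_select(m$clustering, config$cc_z, m$resno))
  partitions <- lapply(pcns, fast_greedy)

  diffs <- lapply(pcns[-1L], function(p)
    diff_contacts(pcns[[1L]], p,
                  long_range_threshold = config$long_range_threshold,
                  active_site_radius = config$active_site_radius))
  layouts <- c(list(ring_layout(pcns[[1L]])),
               mapply(ring_layout, pcns[-1L], diffs, SIMPLIFY = FALSE))

  rmsd <- if (length(all_s) >= 2L) rmsd_matrix(all_s) else NULL
  rw_rmsd <- if (length(all_s) >= 2L) residuewise_rmsd(all_s) else NULL
  union <- if (length(diffs) > 0L) union_contacts(diffs) else NULL
  deg_sum <- if (length(diffs) > 0L) degree_change_summary(diffs) else NULL

  bundle <- list(config = config, structures = all_s, pcns = pcns,
                 metrics = metrics, bc_selection = bc_sel,
                 cc_selection = cc_sel, partitions = partitions,
                 layouts = layouts, rmsd = rmsd, residuewise_rmsd = rw_rmsd,
                 diffs = diffs, union = union, degree_summary = deg_sum)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  cfg_list$annotation <- if (is.null(cfg$annotation)) NULL else
    unclass(cfg$annotation)
  jsonlite::write_json(cfg_list, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  for (k in seq_along(bundle$pcns)) {
    p <- bundle$pcns[[k]]
    sdir <- file.path(out_dir, p$structure_id)
    dir.create(sdir, showWarnings = FALSE)
    write_metrics_tsv(bundle$metrics[[k]], file.path(sdir, "metrics.tsv"))
    write_contacts_tsv(classify_contacts(p, cfg$long_range_threshold,
                                         cfg$active_site_radius),
                       file.path(sdir, "contacts.tsv"))
    write_communities_tsv(bundle$partitions[[k]],
                          p$structure$residues$resno,
                          file.path(sdir, "communities.tsv"))
    write_graphml(p, file.path(sdir, "network.graphml"))
  }
  if (!is.null(bundle$rmsd)) {
    utils::write.table(round(bundle$rmsd, 6),
                       file.path(out_dir, "rmsd_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(bundle$residuewise_rmsd))
    utils::write.table(bundle$residuewise_rmsd,
                       file.path(out_dir, "residuewise_rmsd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(bundle$diffs) > 0L) {
    ddir <- file.path(out_dir, "diff")
    for (d in bundle$diffs) write_diff_report(d, ddir)
    jsonlite::write_json(
      list(ref_id = bundle$union$ref_id,
           n_mutants = bundle$union$n_mutants,
           n_unique_made = nrow(bundle$union$unique_made),
           n_unique_lost = nrow(bundle$union$unique_lost),
           tallies = bundle$union$tallies,
           degree_summary = bundle$degree_summary,
           degree_average = attr(bundle$degree_summary, "average")),
      file.path(ddir, "union.json"), auto_unbox = TRUE, digits = 10)
  }
  invisible(out_dir)
}
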