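# Study roster and annotation defaults for Bacillus subtilis Lipase A
# (wild type plus six in-vitro evolved thermostable mutants).

#' Lipase A structure roster
#'
#' The wild type and the six thermostable mutants of *Bacillus subtilis*
#' Lipase A, with their PDB accessions and cumulative mutation lists
#' (each successive mutant retains the earlier mutations).
#'
#' @return data.frame with columns `name`, `pdb_id`, `mutations`
#'   (comma-separated mutation strings; empty for the wild type).
#' @export
lipase_structures <- function() {
  data.frame(
    name = c("WT", "DM", "TM", "1-17A4", "2D9", "4D3", "6B"),
    pdb_id = c("1I6W", "1T4M", "1T2N", "3D2A", "3D2B", "3D2C", "3QMM"),
    mutations = c(
      "",
      "N166Y,A132D",
      "N166Y,A132D,L114P",
      "N166Y,A132D,L114P,I157M",
      "N166Y,A132D,L114P,I157M,F17S,N89Y",
      "N166Y,A132D,L114P,I157M,F17S,N89Y,A15S,A20E,G111D",
      "N166Y,A132D,L114P,I157M,F17S,N89Y,A15S,A20E,G111D,M134E,M137P,S163P"))
}

#' Default Lipase A annotation
#'
#' Catalytic triad S77, D133, H156; the wider active-site set adds the
#' residues repeatedly implicated around the catalytic pocket (I12, G14,
#' A15, N18, N106, L108, S131, M134, I135, V136, G153).  Both sets are
#' configurable — the active-site membership in particular is assembled
#' from the running description of the pocket, not from a published
#' enumeration.
#'
#' @param mutations character vector (or single comma-separated string)
#'   of mutation strings for the structure being annotated.
#' @param terminal_window terminal window (default 4).
#' @return an [annotation_config()].
#' @export
lipase_annotation <- function(mutations = character(0), terminal_window = 4L) {
  if (length(mutations) == 1L && grepl(",", mutations))
    mutations <- strsplit(mutations, ",")[[1L]]
  mutations <- mutations[nzchar(mutations)]
  annotation_config(
    catalytic = c(77L, 133L, 156L),
    active_site = c(12L, 14L, 15L, 18L, 106L, 108L, 131L, 134L, 135L, 136L,
                    153L),
    mutated = if (length(mutations)) parse_mutation_string(mutations)$position
              else integer(0),
    terminal_window = terminal_window)
}

#' Reproduce the Lipase A differential-network analysis
#'
#' Runs the full pipeline on the seven crystal structures of the Lipase A
#' thermostability series.  The PDB coordinate files are not distributed
#' with the package; download entries 1I6W, 1T4M, 1T2N, 3D2A, 3D2B, 3D2C
#' and 3QMM from the Protein Data Bank into `pdb_dir` (file names
#' `<id>.pdb`, case-insensitive).
#'
#' @param pdb_dir directory containing the seven PDB files.
#' @param config a [run_config()]; the per-structure mutation annotation
#'   is filled in from [lipase_structures()].
#' @param out_dir optional output directory for the report bundle.
#' @return the [run_pipeline()] bundle, with a `headline` element
#'   summarising the quantities of interest (node count, made/lost for
#'   the most thermostable mutant, union counts and category fractions,
#'   community counts, maximum cross-structure RMSD).
#' @export
reproduce_lipase <- function(pdb_dir, config = run_config(), out_dir = NULL) {
  roster <- lipase_structures()
  find_file <- function(id) {
    hits <- list.files(pdb_dir, pattern = paste0("(?i)^", id, "\\.(pdb|ent)$"),
                       full.names = TRUE)
    if (length(hits) == 0L)
      stop("PDB file for ", id, " not found in ", pdb_dir)
    hits[1L]
  }
  files <- vapply(roster$pdb_id, find_file, "")
  structures <- lapply(seq_len(nrow(roster)), function(k)
    parse_structure(files[k],
                    config = lipase_annotation(roster$mutations[k],
                                               config$terminal_window),
                    id = roster$pdb_id[k]))
  bundle <- run_pipeline(structures[[1L]], structures[-1L], config = config,
                         out_dir = out_dir)
  six_b <- which(roster$pdb_id[-1L] == "3QMM")
  d6b <- bundle$diffs[[six_b]]
  deg_avg <- attr(bundle$degree_summary, "average")
  bundle$headline <- list(
    n_residues_wt = n_residues(bundle$structures[[1L]]),
    made_6b = nrow(d6b$made),
    lost_6b = nrow(d6b$lost),
    made_6b_loop = d6b$tallies$made$involves_loop,
    lost_6b_loop = d6b$tallies$lost$involves_loop,
    unique_made = nrow(bundle$union$unique_made),
    unique_lost = nrow(bundle$union$unique_lost),
    made_long_range = bundle$union$tallies$made$long_range,
    made_loop = bundle$union$tallies$made$involves_loop,
    lost_short_range = bundle$union$tallies$lost$short_range,
    max_abs_degree_change = deg_avg$max_abs_change,
    mean_degree_change_fraction = deg_avg$frac_changed,
    wt_n_communities = bundle$partitions[[1L]]$n_communities,
    max_rmsd = max(bundle$rmsd))
  bundle
}
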