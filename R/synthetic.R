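#' Ideal alpha-helical C-alpha trace
#'
#' Places `n` C-alpha atoms on a regular helix.  The default geometry
#' (rise 1.5 A per residue, 100 degrees twist, 2.3 A radius) is the
#' canonical alpha-helix, for which every (i, i+1) ... (i, i+4) pair falls
#' under the 7 A contact cutoff while (i, i+5) and beyond do not — the
#' short-range "n to n+4" contact pattern helices show in contact maps.
#'
#' @param n number of residues (>= 1).
#' @param rise translation per residue along the helix axis, Angstrom.
#' @param twist rotation per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param origin 3-vector added to all coordinates.
#' @param id structure label.
#' @return a [ca_structure()] with all residues labelled `ss = "helix"`.
#' @export
make_ideal_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                             origin = c(0, 0, 0), id = "ideal-helix") {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (rise <= 0 || radius <= 0) stop("rise and radius must be positive")
  i <- seq_len(n) - 1
  theta <- i * twist * pi / 180
  res <- data.frame(resno = seq_len(n), resid = "ALA",
                    x = radius * cos(theta) + origin[1],
                    y = radius * sin(theta) + origin[2],
                    z = i * rise + origin[3],
                    ss = "helix")
  ca_structure(id, res, ss_source = "none")
}

segment_coords <- function(kind, len) {
  i <- seq_len(len) - 1
  switch(kind,
    helix = {
      theta <- i * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), i * 1.5)
    },
    strand = cbind(rep(0, len), 0.5 * (i %% 2), i * 3.3),
    stop("unknown segment kind: ", kind))
}

segment_radius <- function(kind) if (kind == "helix") 2.3 else 0.5

#' Specification for a synthetic single-chain backbone
#'
#' @param segments data.frame (or list coercible to one) with columns
#'   `kind` (`"helix"`, `"strand"` or `"coil"`) and `length`; segment
#'   lengths must sum to `n_residues`.
#' @param n_residues total residue count.
#' @param contact_edits data.frame with columns `i`, `j` (residue numbers)
#'   and `action` (`"inject"` or `"remove"`), or `NULL` for none.  Inject
#'   and remove pairs must be disjoint and inside `[1, n_residues]`.
#' @param seed integer seed for the coordinate jitter (required for
#'   reproducibility).
#' @param noise_sd standard deviation of isotropic coordinate jitter,
#'   Angstrom.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(segments, n_residues = sum(segments$length),
                           contact_edits = NULL, seed = 1L, noise_sd = 0) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("kind", "length") %in% names(segments)))
  if (!all(segments$kind %in% c("helix", "strand", "coil")))
    stop("segment kinds must be helix, strand or coil")
  if (sum(segments$length) != n_residues)
    stop("segment lengths must sum to n_residues")
  if (!is.null(contact_edits)) {
    contact_edits <- as.data.frame(contact_edits)
    stopifnot(all(c("i", "j", "action") %in% names(contact_edits)))
    if (!all(contact_edits$action %in% c("inject", "remove")))
      stop("contact_edits$action must be 'inject' or 'remove'")
    idx <- c(contact_edits$i, contact_edits$j)
    if (any(idx < 1 | idx > n_residues))
      stop("contact_edits indices must lie in [1, n_residues]")
    key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
    inj <- key(contact_edits[contact_edits$action == "inject", , drop = FALSE])
    rem <- key(contact_edits[contact_edits$action == "remove", , drop = FALSE])
    if (length(intersect(inj, rem)) > 0L)
      stop("inject and remove pair lists must be disjoint")
    if (anyDuplicated(c(inj, rem)))
      stop("duplicate pair in contact_edits")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(segments = segments, n_residues = as.integer(n_residues),
                 contact_edits = contact_edits, seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "synthetic_spec")
}

#' Generate a synthetic reference backbone
#'
#' Lays the regular segments (helices/strands) of a [synthetic_spec()] as
#' an antiparallel meander: each runs vertically, alternating up and
#' down, with a lateral axis spacing of about 4 A plus the packing radii
#' of the two neighbours, so that the chain acquires both the short-range
#' intra-helix contact pattern and long-range contacts across the packed
#' interface.  Coil segments bridge the lateral gap between consecutive
#' regular segments.  Coordinates are jittered with seeded Gaussian noise
#' of sd `noise_sd`.
#'
#' @param spec a [synthetic_spec()].
#' @param id structure label.
#' @return a [ca_structure()] with per-residue `ss` set from the segment
#'   kinds (`coil` maps to `loop`).
#' @export
make_synthetic_structure <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  segs <- spec$segments
  nseg <- nrow(segs)
  # lateral gap each junction must cover: packing radii of the flanking
  # regular segments plus ~4.2 A so the closest CA pairs fall under 7 A
  next_regular <- function(k) {
    while (k <= nseg && segs$kind[k] == "coil") k <- k + 1L
    if (k <= nseg) segs$kind[k] else "coil"
  }
  coords <- matrix(numeric(0), ncol = 3)
  pos <- c(0, 0, 0)
  updir <- 1
  prev_kind <- NULL
  for (k in seq_len(nseg)) {
    kind <- segs$kind[k]
    len <- segs$length[k]
    if (kind == "coil") {
      span <- segment_radius(if (is.null(prev_kind)) "coil" else prev_kind) +
        segment_radius(next_regular(k + 1L)) + 4.2
      i <- seq_len(len)
      placed <- cbind(pos[1] + span * i / (len + 1),
                      pos[2] + 2.5 * sin(pi * i / (len + 1)),
                      pos[3] + 1.2 * updir * i / len)
    } else {
      local <- segment_coords(kind, len)
      if (updir < 0) local[, 3] <- -local[, 3]
      start <- pos
      if (!is.null(prev_kind) && prev_kind != "coil") {
        start <- start + c(segment_radius(prev_kind) + segment_radius(kind) +
                             4.2, 0, 0)
      } else {
        start <- start + c(if (is.null(prev_kind)) 0 else 1.5, 0, 2 * updir)
      }
      placed <- sweep(local, 2, start - local[1, ], "+")
      updir <- -updir
    }
    coords <- rbind(coords, placed)
    pos <- placed[len, ]
    prev_kind <- kind
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, spec$noise_sd),
                              ncol = 3)
  }
  ss_map <- c(helix = "helix", strand = "strand", coil = "loop")
  ss <- rep(ss_map[segs$kind], segs$length)
  res <- data.frame(resno = seq_len(spec$n_residues), resid = "ALA",
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    ss = unname(ss))
  ca_structure(id, res, ss_source = "none")
}

#' A lipase-sized alpha/beta synthetic fold specification
#'
#' A 181-residue single-chain layout echoing the topology of a small
#' alpha/beta hydrolase: six strands and five helices alternating along
#' the chain, joined by nine-residue loops.  Used as the standard
#' synthetic reference for end-to-end validation of the differential
#' pipeline at the size of a real lipase chain.
#'
#' @param seed jitter seed.
#' @param noise_sd coordinate jitter sd in Angstrom (default 0.2,
#'   roughly the coordinate spread seen among closely related crystal
#'   structures).
#' @return a [synthetic_spec()] with 181 residues.
#' @export
lipase_like_spec <- function(seed = 1L, noise_sd = 0.2) {
  kinds <- character(0)
  lens <- integer(0)
  for (k in 1:5) {
    kinds <- c(kinds, "strand", "coil", "helix", "coil")
    lens <- c(lens, 6L, 9L, 11L, 9L)
  }
  kinds <- c(kinds, "strand")
  lens <- c(lens, 6L)
  synthetic_spec(data.frame(kind = kinds, length = lens),
                 seed = seed, noise_sd = noise_sd)
}

#' Candidate contact edits near the cutoff
#'
#' Residue pairs whose C-alpha distance is just above (injectable) or just
#' below (removable) the contact cutoff; small coordinate moves on these
#' pairs are the least likely to disturb other contacts.
#'
#' @param structure a [ca_structure()].
#' @param cutoff contact cutoff in Angstrom.
#' @param window how far from the cutoff (Angstrom) a pair may be.
#' @param min_separation minimum |i - j| (chain neighbours are excluded by
#'   default since moving them almost always has side effects).
#' @return data.frame with columns `i`, `j`, `distance`, `action`.
#' @export
feasible_edit_candidates <- function(structure, cutoff = 7.0, window = 1.0,
                                     min_separation = 3L) {
  d <- as.matrix(stats::dist(ca_coords(structure)))
  n <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[idx]
  sep <- abs(idx[, 1] - idx[, 2])
  inj <- dd >= cutoff & dd <= cutoff + window & sep >= min_separation
  rem <- dd < cutoff & dd >= cutoff - window & sep >= min_separation
  out <- data.frame(i = idx[, 1], j = idx[, 2], distance = dd,
                    action = ifelse(inj, "inject", ifelse(rem, "remove", NA)))
  out <- out[!is.na(out$action), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample a feasible ground-truth edit set
#'
#' Draws a random set of injectable and removable residue pairs from
#' [feasible_edit_candidates()], constrained so that no residue appears
#' in more than one edit and so that the accumulated set remains jointly
#' feasible (verified by applying it with [make_mutant()] as candidates
#' are added).  The draw is seeded and reproducible.
#'
#' @param structure a [ca_structure()].
#' @param n_inject,n_remove how many contacts to inject / remove.
#' @param seed integer seed.
#' @param cutoff,window passed to [feasible_edit_candidates()].
#' @return data.frame with columns `i`, `j`, `action`; fewer rows than
#'   requested if the candidate pool is exhausted.
#' @export
sample_edit_set <- function(structure, n_inject = 2L, n_remove = 1L,
                            seed = 1L, cutoff = 7.0, window = 0.8) {
  cand <- feasible_edit_candidates(structure, cutoff = cutoff,
                                   window = window)
  set.seed(seed)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  used <- integer(0)
  picked <- integer(0)
  need <- c(inject = n_inject, remove = n_remove)
  for (r in seq_len(nrow(cand))) {
    act <- cand$action[r]
    if (need[[act]] == 0L) next
    if (cand$i[r] %in% used || cand$j[r] %in% used) next
    # keep the candidate only if the accumulated set stays jointly
    # feasible (a clean flip of exactly the requested pairs)
    trial <- cand[c(picked, r), c("i", "j", "action"), drop = FALSE]
    ok <- tryCatch({make_mutant(structure, trial, cutoff = cutoff); TRUE},
                   error = function(e) FALSE)
    if (!ok) next
    picked <- c(picked, r)
    used <- c(used, cand$i[r], cand$j[r])
    need[[act]] <- need[[act]] - 1L
    if (all(need == 0L)) break
  }
  out <- cand[picked, c("i", "j", "action"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply ground-truth contact edits to a reference structure
#'
#' Produces a "mutant" whose contact network at `cutoff` differs from the
#' reference's by exactly the requested edits.  An injection moves one
#' endpoint along the line towards the other until the pair distance is
#' `cutoff - margin`; a removal moves it away to `cutoff + margin`.  After
#' all edits, the full contact maps are compared by brute force; if any
#' pair other than the requested ones changed cutoff status (or a
#' requested one failed to change), the edit set is infeasible and an
#' error is raised — edits are never silently partially applied.
#'
#' @param ref reference [ca_structure()].
#' @param edits data.frame with columns `i`, `j`, `action`
#'   (`"inject"`/`"remove"`), or a [synthetic_spec()] whose
#'   `contact_edits` are used.
#' @param cutoff contact cutoff, Angstrom.
#' @param margin how far inside/outside the cutoff the edited pair lands.
#' @param id label of the resulting structure.
#' @return a [ca_structure()]; the applied edit set is stored in
#'   `attr(, "contact_edits")` as ground truth for validation.
#' @export
make_mutant <- function(ref, edits, cutoff = 7.0, margin = 0.3,
                        id = paste0(ref$id, "-mut")) {
  stopifnot(inherits(ref, "ca_structure"))
  if (inherits(edits, "synthetic_spec")) {
    if (edits$n_residues != n_residues(ref))
      stop("spec n_residues does not match the reference structure")
    edits <- edits$contact_edits
  }
  mut <- ref
  mut$id <- id
  n <- n_residues(ref)
  if (is.null(edits) || nrow(edits) == 0L) {
    attr(mut, "contact_edits") <- data.frame(i = integer(0), j = integer(0),
                                             action = character(0))
    return(mut)
  }
  edits <- as.data.frame(edits)
  coords <- ca_coords(ref)
  adjacency_of <- function(xyz) {
    a <- as.matrix(stats::dist(xyz)) < cutoff
    diag(a) <- FALSE
    a
  }
  for (k in seq_len(nrow(edits))) {
    i <- edits$i[k]; j <- edits$j[k]; action <- edits$action[k]
    if (i < 1 || j < 1 || i > n || j > n || i == j)
      stop("invalid edit indices (", i, ", ", j, ")")
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    target <- if (action == "inject") cutoff - margin else cutoff + margin
    if (action == "inject" && d < cutoff)
      stop("pair (", i, ", ", j, ") is already a contact; cannot inject")
    if (action == "remove" && d >= cutoff)
      stop("pair (", i, ", ", j, ") is not a contact; cannot remove")
    # candidate moves: pull/push one endpoint along the pair axis, or
    # split the motion between both; keep the first that flips exactly
    # the (i, j) pair relative to the current coordinates
    before <- adjacency_of(coords)
    move <- function(a, b, frac) {
      out <- coords
      dir <- (coords[b, ] - coords[a, ]) / d
      out[b, ] <- coords[b, ] + dir * (target - d) * frac
      out[a, ] <- coords[a, ] - dir * (target - d) * (1 - frac)
      out
    }
    accepted <- FALSE
    for (cand in list(move(i, j, 1), move(j, i, 1), move(i, j, 0.5))) {
      after <- adjacency_of(cand)
      flips <- which(before != after & upper.tri(before), arr.ind = TRUE)
      if (nrow(flips) == 1L && flips[1L, 1L] == min(i, j) &&
          flips[1L, 2L] == max(i, j)) {
        coords <- cand
        accepted <- TRUE
        break
      }
    }
    if (!accepted)
      stop("infeasible edit (", i, ", ", j, "): no side-effect-free ",
           "placement found")
  }
  mut$residues$x <- coords[, 1]
  mut$residues$y <- coords[, 2]
  mut$residues$z <- coords[, 3]

  # brute-force feasibility audit: the contact map must differ by exactly
  # the requested edit set
  a_ref <- as.matrix(stats::dist(ca_coords(ref))) < cutoff
  a_mut <- as.matrix(stats::dist(coords)) < cutoff
  diag(a_ref) <- diag(a_mut) <- FALSE
  changed <- which(a_ref != a_mut & upper.tri(a_ref), arr.ind = TRUE)
  got <- paste(changed[, 1], changed[, 2])
  want <- paste(pmin(edits$i, edits$j), pmax(edits$i, edits$j))
  if (!setequal(got, want) || length(got) != nrow(edits)) {
    extra <- setdiff(got, want); missed <- setdiff(want, got)
    stop("infeasible edit set: applying it perturbs other contacts ",
         "(unintended changes: ",
         if (length(extra)) paste(extra, collapse = "; ") else "none",
         "; unachieved edits: ",
         if (length(missed)) paste(missed, collapse = "; ") else "none", ")")
  }
  attr(mut, "contact_edits") <-
    data.frame(i = pmin(edits$i, edits$j), j = pmax(edits$i, edits$j),
               action = edits$action)
  mut
}
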