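# Fast-greedy modularity communities (Clauset-Newman-Moore agglomeration)
# implemented on the community-fraction matrix e, with deterministic
# lexicographic tie-breaking so repeated runs are bit-identical.

#' Modularity of a partition
#'
#' Q = sum over communities c of (e_cc - a_c^2), where e_cc is the
#' fraction of edges with both ends in c and a_c the fraction of edge
#' ends attached to c.  An edgeless network has Q = 0 by convention.
#'
#' @param network a [build_pcn()] network or adjacency matrix.
#' @param membership integer community id per node.
#' @return modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(network, membership) {
  a <- as_adjacency(network)
  n <- nrow(a)
  if (length(membership) != n)
    stop("membership length (", length(membership),
         ") does not match node count (", n, ")")
  m2 <- sum(a)                      # 2m
  if (m2 == 0) return(0)
  comms <- unique(membership)
  q <- 0
  for (cc in comms) {
    idx <- which(membership == cc)
    e_cc <- sum(a[idx, idx, drop = FALSE]) / m2
    a_c <- sum(a[idx, , drop = FALSE]) / m2
    q <- q + e_cc - a_c^2
  }
  q
}

#' Fast-greedy community detection
#'
#' Clauset-Newman-Moore agglomeration: starting from singleton
#' communities, repeatedly merge the connected pair of communities with
#' the largest modularity gain, and return the partition with maximal Q
#' along the merge sequence.  Ties in the gain are broken on the
#' lexicographically smallest (min id, max id) community-id pair, making
#' the algorithm deterministic.  Communities never span disconnected
#' components (merging unconnected communities always lowers Q).
#'
#' @param network a [build_pcn()] network or adjacency matrix.
#' @return object of class `community_partition`: list with
#'   `structure_id`, `membership` (1-based ids in order of first
#'   appearance), `n_communities`, `modularity`, and `q_trace` (Q after
#'   each merge).
#' @export
fast_greedy <- function(network) {
  a <- as_adjacency(network)
  n <- nrow(a)
  sid <- if (inherits(network, "pcn")) network$structure_id else "network"
  if (n == 0L) stop("empty network")
  m2 <- sum(a)
  if (m2 == 0) {
    return(new_partition(sid, seq_len(n), 0, numeric(0)))
  }
  e <- a / m2                        # e[i, j]: fraction of edges between i, j
  av <- rowSums(e)                   # a_i: fraction of edge ends in i
  active <- rep(TRUE, n)
  comm_of <- seq_len(n)              # community id per node (id = min node)
  q <- sum(diag(e)) - sum(av^2)
  best_q <- q
  best_membership <- comm_of
  q_trace <- numeric(0)
  tol <- 1e-12

  repeat {
    ids <- which(active)
    if (length(ids) < 2L) break
    esub <- e[ids, ids, drop = FALSE]
    conn <- esub > 0
    conn[lower.tri(conn, diag = TRUE)] <- FALSE
    if (!any(conn)) break            # only unconnected components remain
    dq <- 2 * (esub - outer(av[ids], av[ids]))
    dq[!conn] <- -Inf
    best <- max(dq)
    cand <- which(dq >= best - tol, arr.ind = TRUE)
    # lexicographic tie-break on the (smaller id, larger id) pair
    ci <- ids[cand[, 1]]; cj <- ids[cand[, 2]]
    ord <- order(pmin(ci, cj), pmax(ci, cj))
    i <- min(ci[ord[1L]], cj[ord[1L]])
    j <- max(ci[ord[1L]], cj[ord[1L]])

    gain <- 2 * (e[i, j] - av[i] * av[j])
    row_new <- e[i, ] + e[j, ]
    eii_new <- e[i, i] + e[j, j] + 2 * e[i, j]
    e[i, ] <- row_new; e[, i] <- row_new
    e[i, i] <- eii_new
    e[j, ] <- 0; e[, j] <- 0
    av[i] <- av[i] + av[j]; av[j] <- 0
    active[j] <- FALSE
    comm_of[comm_of == j] <- i
    q <- q + gain
    q_trace <- c(q_trace, q)
    if (q > best_q + tol) {
      best_q <- q
      best_membership <- comm_of
    }
  }
  new_partition(sid, best_membership, best_q, q_trace)
}

new_partition <- function(structure_id, membership, q, q_trace) {
  relabel <- match(membership, unique(membership))
  structure(list(structure_id = structure_id,
                 membership = relabel,
                 n_communities = length(unique(relabel)),
                 modularity = q,
                 q_trace = q_trace),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition '%s': %d communities, Q = %.4f\n",
              x$structure_id, x$n_communities, x$modularity))
  invisible(x)
}

#' Compare two community partitions
#'
#' Matches communities greedily by maximum residue overlap (adequate for
#' the handful of communities a contact network has), then reports which
#' residues changed community, which reference communities were split
#' (>= 2 counterpart communities overlapping by at least `min_overlap`
#' residues), and the symmetric merge events.  The comparison is
#' invariant under relabelling of community ids.
#'
#' @param ref,other [fast_greedy()] partitions.
#' @param mapping optional [map_residues()] correspondence; by default
#'   nodes are paired positionally (both partitions over the same nodes).
#' @param min_overlap minimum shared residues for a split/merge target
#'   (default 3, filtering single-residue flicker).
#' @return object of class `partition_comparison`: list with `overlap`
#'   (contingency matrix), `matched_pairs`, `n_reassigned`, `reassigned`
#'   (node positions in the matched set), `splits`, `merges`.
#' @export
compare_partitions <- function(ref, other, mapping = NULL, min_overlap = 3L) {
  stopifnot(inherits(ref, "community_partition"),
            inherits(other, "community_partition"))
  if (is.null(mapping)) {
    if (length(ref$membership) != length(other$membership))
      stop("partitions cover different node counts; supply a residue mapping")
    mr <- ref$membership
    mo <- other$membership
    labels <- seq_along(mr)
  } else {
    stopifnot(inherits(mapping, "residue_map"))
    if (nrow(mapping$matched) == 0L) stop("empty residue correspondence")
    mr <- ref$membership[mapping$matched$index_ref]
    mo <- other$membership[mapping$matched$index_other]
    labels <- mapping$matched$resno
  }
  tab <- table(ref = mr, other = mo)
  stopifnot(sum(tab) == length(mr))

  # greedy maximum-overlap matching
  work <- tab
  pairs <- data.frame(ref_comm = integer(0), other_comm = integer(0),
                      overlap = integer(0))
  while (any(work > 0)) {
    cell <- which(work == max(work), arr.ind = TRUE)[1L, , drop = FALSE]
    rc <- rownames(work)[cell[1L]]; oc <- colnames(work)[cell[2L]]
    pairs <- rbind(pairs, data.frame(ref_comm = as.integer(rc),
                                     other_comm = as.integer(oc),
                                     overlap = as.integer(work[cell])))
    work[cell[1L], ] <- 0L
    work[, cell[2L]] <- 0L
  }
  match_of <- pairs$other_comm[match(mr, pairs$ref_comm)]
  reassigned <- which(is.na(match_of) | match_of != mo)

  split_of <- function(t, min_ov) {
    out <- list()
    for (r in rownames(t)) {
      targets <- colnames(t)[t[r, ] >= min_ov]
      if (length(targets) >= 2L)
        out[[r]] <- as.integer(targets)
    }
    out
  }
  structure(list(overlap = tab,
                 matched_pairs = pairs,
                 n_reassigned = length(reassigned),
                 reassigned = labels[reassigned],
                 splits = split_of(tab, min_overlap),
                 merges = split_of(t(tab), min_overlap)),
            class = "partition_comparison")
}

#' Export community membership as TSV
#' @param partition a [fast_greedy()] partition.
#' @param resno residue numbers for the nodes.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_communities_tsv <- function(partition, resno, file) {
  utils::write.table(
    data.frame(resno = resno, community = partition$membership),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
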