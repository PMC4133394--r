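# Residue-level network metrics, implemented directly on the adjacency
# matrix (Brandes accumulation for betweenness, BFS for distances).  An
# independent graph library is used only as a cross-validation oracle in
# the test suite.

as_adjacency <- function(x) {
  if (inherits(x, "pcn")) return(x$adjacency)
  a <- as.matrix(x)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (any(a != t(a))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  (a != 0) * 1L
}

neighbour_list <- function(a) lapply(seq_len(nrow(a)), function(i) which(a[i, ] != 0L))

#' Node degree
#' @param network a [build_pcn()] network or adjacency matrix.
#' @return integer vector of row sums of the adjacency matrix.
#' @export
pcn_degree <- function(network) {
  a <- as_adjacency(network)
  as.integer(rowSums(a))
}

#' Watts-Strogatz local clustering coefficient
#'
#' C_i = 2 e_i / (k_i (k_i - 1)) where e_i counts edges among the
#' neighbours of i; nodes of degree < 2 get C_i = 0.
#'
#' @inheritParams pcn_degree
#' @return numeric vector in \[0, 1\].
#' @export
pcn_clustering <- function(network) {
  a <- as_adjacency(network)
  k <- rowSums(a)
  vapply(seq_len(nrow(a)), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(a[i, ] != 0L)
    sum(a[nb, nb]) / (k[i] * (k[i] - 1))
  }, numeric(1))
}

#' Betweenness centrality (Brandes)
#'
#' BC_i = sum over unordered pairs (s, t), s != i != t, of the fraction
#' of shortest s-t paths passing through i, accumulated with Brandes'
#' dependency recursion on BFS trees (unweighted graph).
#'
#' @inheritParams pcn_degree
#' @param normalized divide by (n-1)(n-2)/2, the number of pairs a node
#'   could lie between.
#' @return numeric vector, >= 0.
#' @export
pcn_betweenness <- function(network, normalized = FALSE) {
  a <- as_adjacency(network)
  n <- nrow(a)
  nbrs <- neighbour_list(a)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    order_visited <- integer(0)
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          tail <- tail + 1L; queue[tail] <- w
          dist[w] <- dist[v] + 1L
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2           # each unordered pair accumulated from both ends
  if (normalized) {
    n_pairs <- (n - 1) * (n - 2) / 2
    if (n_pairs > 0) bc <- bc / n_pairs
  }
  bc
}

bfs_distances <- function(nbrs, s, n) {
  dist <- rep(NA_integer_, n); dist[s] <- 0L
  queue <- integer(n); queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in nbrs[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      tail <- tail + 1L; queue[tail] <- w
    }
  }
  dist
}

#' All-pairs shortest hop distances
#'
#' @inheritParams pcn_degree
#' @return symmetric numeric matrix of BFS hop counts, `Inf` for
#'   unreachable pairs, zero diagonal.  The characteristic path length is
#'   the mean over reachable off-diagonal pairs.
#' @export
pcn_shortest_paths <- function(network) {
  a <- as_adjacency(network)
  n <- nrow(a)
  nbrs <- neighbour_list(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    ds <- bfs_distances(nbrs, s, n)
    d[s, !is.na(ds)] <- ds[!is.na(ds)]
  }
  d
}

#' Closeness centrality
#'
#' For node i with r reachable other nodes at total hop distance S,
#' closeness is r / S (the standard (n-1)/S on a connected graph,
#' restricted to the node's component otherwise).  Isolated nodes get 0.
#'
#' @inheritParams pcn_degree
#' @return numeric vector.
#' @export
pcn_closeness <- function(network) {
  a <- as_adjacency(network)
  n <- nrow(a)
  nbrs <- neighbour_list(a)
  vapply(seq_len(n), function(s) {
    ds <- bfs_distances(nbrs, s, n)
    reach <- which(!is.na(ds) & seq_len(n) != s)
    if (length(reach) == 0L) return(0)
    length(reach) / sum(ds[reach])
  }, numeric(1))
}

#' Per-residue metric table with global summary
#'
#' @param pcn a [build_pcn()] network.
#' @param normalized_bc report normalized betweenness.
#' @return data.frame with one row per residue (`index`, `resno`,
#'   `degree`, `clustering`, `betweenness`, `closeness`, `eccentricity`);
#'   the global summary (mean degree, mean clustering, characteristic
#'   path length, diameter) is attached as `attr(, "global")`.
#' @export
metric_table <- function(pcn, normalized_bc = FALSE) {
  stopifnot(inherits(pcn, "pcn"))
  d <- pcn_shortest_paths(pcn)
  finite_off <- d[is.finite(d) & row(d) != col(d)]
  ecc <- apply(d, 1, function(v) {
    f <- v[is.finite(v)]
    if (length(f) == 0L) 0 else max(f)
  })
  out <- data.frame(index = seq_len(pcn$n),
                    resno = pcn$structure$residues$resno,
                    degree = pcn_degree(pcn),
                    clustering = pcn_clustering(pcn),
                    betweenness = pcn_betweenness(pcn, normalized = normalized_bc),
                    closeness = pcn_closeness(pcn),
                    eccentricity = ecc)
  attr(out, "global") <- list(
    structure_id = pcn$structure_id,
    n = pcn$n,
    n_contacts = nrow(pcn$contacts),
    mean_degree = mean(out$degree),
    mean_clustering = mean(out$clustering),
    char_path_length = if (length(finite_off)) mean(finite_off) else NA_real_,
    diameter = if (length(finite_off)) max(finite_off) else NA_real_)
  out
}

#' Z-score outlier selection within one network
#'
#' Standardises a per-residue metric within the structure's own residue
#' population (population standard deviation) and selects residues with
#' z strictly above the threshold — the convention used to call out
#' residues with significantly high betweenness (z > 2.5) or clustering
#' (z > 2.0).
#'
#' @param values numeric per-residue series (length >= 2).
#' @param threshold z-score threshold (strict >).
#' @param resno optional residue numbers labelling the series.
#' @return object of class `zscore_selection`: data.frame of the selected
#'   residues (`resno`, `value`, `z`), with the full z vector as
#'   `attr(, "z")`.  A constant series yields an empty selection with a
#'   warning.
#' @export
zscore_select <- function(values, threshold, resno = seq_along(values)) {
  stopifnot(length(values) >= 2L, length(resno) == length(values))
  mu <- mean(values)
  sdev <- sqrt(mean((values - mu)^2))
  if (sdev == 0) {
    warning("constant series: standard deviation is zero, nothing selected")
    z <- rep(0, length(values))
  } else {
    z <- (values - mu) / sdev
  }
  sel <- which(z > threshold)
  out <- data.frame(resno = resno[sel], value = values[sel], z = z[sel])
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "z") <- z
  attr(out, "threshold") <- threshold
  class(out) <- c("zscore_selection", "data.frame")
  out
}

#' Export a metric table as TSV (plus its global summary as JSON)
#' @param metrics a [metric_table()].
#' @param file TSV path; the summary goes to `<file>.summary.json`.
#' @return the TSV path, invisibly.
#' @export
write_metrics_tsv <- function(metrics, file) {
  utils::write.table(metrics, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- attr(metrics, "global")
  if (!is.null(g))
    jsonlite::write_json(g, paste0(file, ".summary.json"), auto_unbox = TRUE,
                         digits = 10)
  invisible(file)
}
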