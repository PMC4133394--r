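# Fixtures and independent oracles shared across the suite.  All fixtures
# are built in code; the graph oracles deliberately use either a
# different algorithm (Floyd-Warshall, exhaustive enumeration) or an
# independent library (igraph) so they share no code path with the
# package implementations.

# mixed helix/strand/coil fold used as the standard synthetic reference
toy_fold <- function(seed = 42, noise_sd = 0.15, id = "toy") {
  spec <- synthetic_spec(
    data.frame(kind = c("helix", "coil", "strand", "coil", "strand",
                        "coil", "helix"),
               length = c(12, 5, 8, 4, 8, 5, 12)),
    seed = seed, noise_sd = noise_sd)
  make_synthetic_structure(spec, id = id)
}

# two ideal helices on one chain, second displaced by `offset`
helix_pair <- function(n = 10, offset = c(30, 0, 0)) {
  h1 <- make_ideal_helix(n)
  h2 <- make_ideal_helix(n, origin = offset)
  res <- rbind(h1$residues[, c("resno", "resid", "x", "y", "z", "ss")],
               h2$residues[, c("resno", "resid", "x", "y", "z", "ss")])
  res$resno <- seq_len(2 * n)
  ca_structure("helix-pair", res, ss_source = "none")
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(stats::rbinom(n * n, 1, p), n)
  a <- 1L * ((a + t(a)) > 0)
  diag(a) <- 0L
  a
}

ig_graph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# O(n^3) all-pairs shortest paths, independent of the package's BFS
floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# brute-force O(n^2) contact set oracle from raw coordinates
brute_force_contacts <- function(structure, cutoff) {
  xyz <- ca_coords(structure)
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff)
      out <- rbind(out, c(i, j))
  }
  out
}

# all set partitions of n elements as restricted-growth membership vectors
all_partitions <- function(n) {
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    k <- max(prefix) + 1L
    unlist(lapply(seq_len(k), function(v) grow(c(prefix, v))),
           recursive = FALSE)
  }
  grow(1L)
}

two_cliques <- function(k = 4, bridge = TRUE) {
  n <- 2 * k
  a <- matrix(0L, n, n)
  a[seq_len(k), seq_len(k)] <- 1L
  a[(k + 1):n, (k + 1):n] <- 1L
  diag(a) <- 0L
  if (bridge) a[k, k + 1] <- a[k + 1, k] <- 1L
  a
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}
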