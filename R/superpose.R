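#' Optimal least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two matched coordinate sets via SVD of the cross-covariance matrix,
#' with the standard reflection guard (if the determinant of the optimal
#' orthogonal matrix is negative, the smallest singular direction is
#' flipped so that a proper rotation is returned).
#'
#' @param ref n-by-3 matrix of reference coordinates (Angstrom).
#' @param mov n-by-3 matrix of moving coordinates, same row order.
#' @return object of class `kabsch_fit`: list with `rotation` (3x3,
#'   orthogonal, det +1), `translation` (3-vector), `rmsd` (Angstrom) and
#'   `n_matched`.  `rotation %*% x + translation` maps moving onto
#'   reference coordinates.
#' @export
kabsch <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!identical(dim(ref), dim(mov)))
    stop("coordinate sets must have identical dimensions")
  n <- nrow(ref)
  if (n < 3L) stop("at least 3 matched points are required")
  cref <- colMeans(ref); cmov <- colMeans(mov)
  p <- sweep(mov, 2, cmov); q <- sweep(ref, 2, cref)
  h <- t(p) %*% q
  s <- svd(h)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-300))
    stop("degenerate (collinear) coordinates: superposition is not unique")
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cref - rot %*% cmov),
                 rmsd = rmsd, n_matched = n),
            class = "kabsch_fit")
}

#' Apply a superposition to coordinates
#' @param coords n-by-3 matrix.
#' @param fit a [kabsch()] result.
#' @return transformed n-by-3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Superpose two structures on their matched residues
#'
#' @param ref,other [ca_structure()] objects; residues are paired by
#'   author number with [map_residues()].
#' @return a [kabsch()] fit over the matched C-alpha pairs.
#' @export
superpose_structures <- function(ref, other) {
  mp <- map_residues(ref, other)
  kabsch(ca_coords(ref)[mp$matched$index_ref, , drop = FALSE],
         ca_coords(other)[mp$matched$index_other, , drop = FALSE])
}

#' Cross-structure RMSD matrix
#'
#' Pairwise C-alpha RMSD after least-squares superposition on the matched
#' residues of each pair, laid out as the symmetric matrix used for
#' cross-structure comparison of a mutant series.
#'
#' @param structures list of [ca_structure()] objects (>= 2).
#' @return symmetric numeric matrix (Angstrom) with structure ids as
#'   dimnames and zero diagonal.
#' @export
rmsd_matrix <- function(structures) {
  if (length(structures) < 2L) stop("need at least two structures")
  ids <- vapply(structures, function(s) s$id, "")
  k <- length(structures)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
    fit <- tryCatch(superpose_structures(structures[[a]], structures[[b]]),
                    error = function(e) stop("superposition failed for pair (",
                                             ids[a], ", ", ids[b], "): ",
                                             conditionMessage(e)))
    m[a, b] <- m[b, a] <- fit$rmsd
  }
  m
}

#' Residue-wise RMSD over an aligned ensemble
#'
#' Each structure is superposed onto the reference over the residues
#' common to the whole set; the per-residue value is the root-mean-square
#' deviation of that residue's C-alpha about its ensemble-mean position
#' (reference included), the usual picture of which residues differ most
#' across a set of crystal structures.
#'
#' @param structures list of [ca_structure()] objects.
#' @param reference the structure to superpose onto (default the first).
#' @return data.frame with columns `resno`, `rmsd` (Angstrom).
#' @export
residuewise_rmsd <- function(structures, reference = structures[[1L]]) {
  stopifnot(length(structures) >= 1L)
  shared <- Reduce(intersect, lapply(structures, function(s) s$residues$resno))
  shared <- intersect(shared, reference$residues$resno)
  if (length(shared) == 0L) stop("no residues common to all structures")
  ref_xyz <- ca_coords(reference)[match(shared, reference$residues$resno), ,
                                  drop = FALSE]
  aligned <- lapply(structures, function(s) {
    xyz <- ca_coords(s)[match(shared, s$residues$resno), , drop = FALSE]
    apply_transform(xyz, kabsch(ref_xyz, xyz))
  })
  arr <- simplify2array(aligned)                      # n x 3 x k
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply(arr, 3, function(x) rowSums((x - mean_pos)^2))
  data.frame(resno = shared, rmsd = sqrt(rowMeans(as.matrix(dev2))))
}
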