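test_that("ideal helix geometry produces the n to n+4 contact pattern", {
  h <- make_ideal_helix(10)
  xyz <- ca_coords(h)
  # consecutive CA spacing is constant on a regular helix
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_lt(diff(range(steps)), 1e-10)
  # brute-force pairwise distances: separations 1..4 under 7 A, > 6 never
  for (i in 1:9) for (j in (i + 1):10) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (j - i <= 4) expect_lt(d, 7.0) else if (j - i > 6) expect_gt(d, 7.0)
  }
  p <- build_pcn(h, 7.0)
  expect_setequal(unique(p$contacts$separation), 1:4)
})

test_that("a single residue yields a trivial edgeless network", {
  h <- make_ideal_helix(1)
  expect_equal(n_residues(h), 1L)
  expect_equal(nrow(build_pcn(h)$contacts), 0L)
})

test_that("helix generator rejects invalid geometry", {
  expect_error(make_ideal_helix(0), "positive")
  expect_error(make_ideal_helix(5, rise = -1), "positive")
  expect_error(make_ideal_helix(5, radius = 0), "positive")
})

test_that("two helices 30 A apart share no inter-helix contacts", {
  s <- helix_pair(10, offset = c(30, 0, 0))
  p <- build_pcn(s, 7.0)
  inter <- p$contacts$i <= 10 & p$contacts$j > 10
  expect_false(any(inter))
})

test_that("synthetic fold has short- and long-range structure", {
  s <- toy_fold()
  p <- build_pcn(s)
  expect_equal(n_residues(s), 54L)
  expect_true(any(p$contacts$separation > 12))
  helix_res <- which(s$residues$ss == "helix")
  expect_true(all(1:4 %in% p$contacts$separation))
  expect_identical(unname(as.matrix(p$contacts[, c("i", "j")])),
                   unname(brute_force_contacts(s, 7.0)))
})

test_that("synthetic_spec validates its invariants", {
  segs <- data.frame(kind = c("helix", "coil"), length = c(10, 5))
  expect_error(synthetic_spec(segs, n_residues = 14), "sum")
  expect_error(synthetic_spec(segs, contact_edits = data.frame(
    i = 1, j = 99, action = "inject")), "\\[1, n_residues\\]")
  expect_error(synthetic_spec(segs, contact_edits = data.frame(
    i = c(1, 1), j = c(9, 9), action = c("inject", "remove"))), "disjoint")
  expect_silent(synthetic_spec(segs, seed = 3))
})

test_that("make_mutant applies exactly the requested contact edits", {
  ref <- toy_fold()
  ref_pcn <- build_pcn(ref)

  # empty edit set: identical networks
  m0 <- make_mutant(ref, NULL)
  d0 <- diff_contacts(ref_pcn, build_pcn(m0))
  expect_equal(nrow(d0$made), 0L)
  expect_equal(nrow(d0$lost), 0L)

  # ground truth equals diff output for seeded random edit sets
  for (seed in 1:25) {
    edits <- sample_edit_set(ref, n_inject = 2, n_remove = 2, seed = seed)
    mut <- make_mutant(ref, edits, id = sprintf("mut%d", seed))
    gt <- attr(mut, "contact_edits")
    d <- diff_contacts(ref_pcn, build_pcn(mut))
    made_keys <- paste(d$made$resno_i, d$made$resno_j)
    lost_keys <- paste(d$lost$resno_i, d$lost$resno_j)
    inj <- gt[gt$action == "inject", ]
    rem <- gt[gt$action == "remove", ]
    expect_setequal(made_keys, paste(inj$i, inj$j))
    expect_setequal(lost_keys, paste(rem$i, rem$j))
  }
})

test_that("make_mutant refuses nonsensical or infeasible edits", {
  ref <- toy_fold()
  p <- build_pcn(ref)
  ct1 <- p$contacts[1, ]
  expect_error(make_mutant(ref, data.frame(i = ct1$i, j = ct1$j,
                                           action = "inject")),
               "already a contact")
  cand2 <- feasible_edit_candidates(ref)
  non <- cand2[cand2$action == "inject", ][1, ]
  expect_error(make_mutant(ref, data.frame(i = non$i, j = non$j,
                                           action = "remove")),
               "not a contact")
  # removing a tight helical (i, i+1) contact needs a move so large it
  # cannot be side-effect free in a dense fold
  expect_error(make_mutant(ref, data.frame(i = 5, j = 6, action = "remove")),
               "infeasible")
})

test_that("PDB writer round-trips structure, numbering and annotation", {
  s <- toy_fold()
  lines <- write_pdb(s)
  expect_equal(sum(grepl("^ATOM", lines)), n_residues(s))
  s2 <- parse_structure(lines)
  expect_equal(s2$residues$resno, s$residues$resno)
  expect_equal(s2$residues$resid, s$residues$resid)
  expect_lt(max(abs(ca_coords(s2) - ca_coords(s))), 1e-3)
  expect_identical(s2$residues$ss, s$residues$ss)
  expect_equal(s2$ss_source, "pdb_header")

  one <- make_ideal_helix(1)
  l1 <- write_pdb(one)
  expect_equal(sum(grepl("^ATOM", l1)), 1L)
  expect_match(l1[grepl("^ATOM", l1)], " CA ")

  far <- make_ideal_helix(3, origin = c(99999, 0, 0))
  expect_error(write_pdb(far), "column")
})

test_that("round-trip holds under fuzzed geometries", {
  for (seed in 1:8) {
    s <- toy_fold(seed = seed, noise_sd = 0.3, id = sprintf("fuzz%d", seed))
    s2 <- parse_structure(write_pdb(s), id = s$id)
    expect_lt(max(abs(ca_coords(s2) - ca_coords(s))), 1e-3)
    expect_identical(s2$residues$ss, s$residues$ss)
  }
})
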