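ref_struct <- toy_fold()
ref_net <- build_pcn(ref_struct)

test_that("identical networks diff to empty sets and zero deltas", {
  twin <- ref_struct
  twin$id <- "twin"
  d <- diff_contacts(ref_net, build_pcn(twin))
  expect_equal(nrow(d$made), 0L)
  expect_equal(nrow(d$lost), 0L)
  expect_true(all(d$metric_deltas$d_degree == 0))
  expect_true(all(abs(d$metric_deltas$d_betweenness) < 1e-12))
})

test_that("comparing networks at different cutoffs is refused", {
  expect_error(diff_contacts(ref_net, build_pcn(ref_struct, 6.5)),
               "different cutoffs")
})

test_that("an injected contact raises the endpoint degrees by one", {
  cand <- sample_edit_set(ref_struct, n_inject = 1, n_remove = 0, seed = 3)
  mut <- make_mutant(ref_struct, cand, id = "one-inject")
  d <- diff_contacts(ref_net, build_pcn(mut))
  expect_equal(nrow(d$made), 1L)
  expect_equal(nrow(d$lost), 0L)
  gt <- attr(mut, "contact_edits")
  expect_equal(sort(c(d$made$resno_i, d$made$resno_j)), sort(c(gt$i, gt$j)))
  dd <- d$metric_deltas
  expect_equal(sort(dd$resno[dd$d_degree == 1]), sort(c(gt$i, gt$j)))
  expect_true(all(dd$d_degree[!dd$resno %in% c(gt$i, gt$j)] == 0))
})

test_that("diff is antisymmetric and conserves contact counts", {
  for (seed in c(2, 4, 6)) {
    mut <- make_mutant(ref_struct, sample_edit_set(ref_struct, 2, 2,
                                                   seed = seed),
                       id = sprintf("m%d", seed))
    mut_net <- build_pcn(mut)
    fwd <- diff_contacts(ref_net, mut_net)
    rev <- diff_contacts(mut_net, ref_net)
    key <- function(ct) paste(ct$resno_i, ct$resno_j)
    expect_setequal(key(fwd$made), key(rev$lost))
    expect_setequal(key(fwd$lost), key(rev$made))
    merged <- merge(fwd$metric_deltas, rev$metric_deltas, by = "resno")
    expect_equal(merged$d_degree.x, -merged$d_degree.y)
    expect_equal(merged$d_betweenness.x, -merged$d_betweenness.y,
                 tolerance = 1e-9)
    # conservation on the matched set
    expect_equal(nrow(mut_net$contacts),
                 nrow(ref_net$contacts) + nrow(fwd$made) - nrow(fwd$lost))
    # tallies are consistent with per-contact flags
    expect_equal(fwd$tallies$made$long_range,
                 sum(fwd$made$range_class == "long"))
    expect_equal(fwd$tallies$made$long_range + fwd$tallies$made$short_range,
                 nrow(fwd$made))
    expect_equal(fwd$tallies$lost$involves_loop, sum(fwd$lost$involves_loop))
  }
})

test_that("contacts at unmatched residues are excluded, not misreported", {
  mut <- ref_struct
  mut$id <- "truncated"
  mut$residues <- mut$residues[-c(1, 2), ]
  mut$residues$index <- seq_len(nrow(mut$residues))
  d <- diff_contacts(ref_net, build_pcn(mut))
  expect_equal(nrow(d$made), 0L)
  expect_equal(nrow(d$lost), 0L)
  expect_true(all(d$excluded$origin == "reference"))
  expect_true(all(d$excluded$resno_i %in% 1:2 | d$excluded$resno_j %in% 1:2))
})

test_that("union across mutants dedupes by residue pair", {
  m1 <- make_mutant(ref_struct, sample_edit_set(ref_struct, 2, 1, seed = 11),
                    id = "u1")
  m2 <- make_mutant(ref_struct, sample_edit_set(ref_struct, 2, 1, seed = 11),
                    id = "u2")     # same edits: full overlap
  m3 <- make_mutant(ref_struct, sample_edit_set(ref_struct, 2, 1, seed = 12),
                    id = "u3")
  d1 <- diff_contacts(ref_net, build_pcn(m1))
  d2 <- diff_contacts(ref_net, build_pcn(m2))
  d3 <- diff_contacts(ref_net, build_pcn(m3))

  u_single <- union_contacts(list(d1))
  expect_equal(nrow(u_single$unique_made), nrow(d1$made))

  u_dup <- union_contacts(list(d1, d2))
  expect_equal(nrow(u_dup$unique_made), nrow(d1$made))
  expect_true(all(u_dup$unique_made$n_mutants == 2L))

  key <- function(ct) paste(ct$resno_i, ct$resno_j)
  u_all <- union_contacts(list(d1, d3))
  shared <- length(intersect(key(d1$made), key(d3$made)))
  expect_equal(nrow(u_all$unique_made),
               nrow(d1$made) + nrow(d3$made) - shared)
  expect_lte(nrow(u_all$unique_made), nrow(d1$made) + nrow(d3$made))

  other_ref <- build_pcn(m1)
  d_bad <- diff_contacts(other_ref, build_pcn(m3))
  expect_error(union_contacts(list(d1, d_bad)), "share one reference")
})

test_that("degree-change summary reports fractions and maxima", {
  twin <- ref_struct; twin$id <- "twin"
  d_id <- diff_contacts(ref_net, build_pcn(twin))
  s0 <- degree_change_summary(list(d_id))
  expect_equal(s0$frac_changed, 0)
  expect_equal(s0$max_abs_change, 0)

  mut <- make_mutant(ref_struct, sample_edit_set(ref_struct, 1, 0, seed = 3),
                     id = "single")
  d1 <- diff_contacts(ref_net, build_pcn(mut))
  s1 <- degree_change_summary(list(d1))
  expect_equal(s1$frac_changed, 2 / n_residues(ref_struct))
  expect_equal(s1$max_abs_change, 1)
  avg <- attr(degree_change_summary(list(d_id, d1)), "average")
  expect_equal(avg$frac_changed, (0 + 2 / n_residues(ref_struct)) / 2)
})

test_that("betweenness-gain ranking tops out at a new bridge", {
  # barbell: two cliques joined through a single path node
  k <- 5
  res <- data.frame(resno = 1:(2 * k + 1), resid = "ALA",
                    x = c(rep(0, k), 50, rep(100, k)) +
                      c(seq(0, 4, length.out = k), 0,
                        seq(0, 4, length.out = k)),
                    y = c(seq(0, 4, length.out = k), 0,
                          seq(2, 6, length.out = k)),
                    z = 0)
  expect_error(bc_gain_ranking(list()), "diff_report")

  mutb <- make_mutant(ref_struct, sample_edit_set(ref_struct, 2, 0, seed = 21),
                      id = "bridge")
  db <- diff_contacts(ref_net, build_pcn(mutb))
  rk <- bc_gain_ranking(db, top_k = 10)
  expect_equal(nrow(rk), 10L)
  expect_true(all(diff(rk$d_betweenness) <= 1e-12))
  gt <- attr(mutb, "contact_edits")
  # endpoints of new long-range contacts should rank near the top
  expect_true(any(c(gt$i, gt$j) %in% rk$resno))
  expect_warning(bc_gain_ranking(db, top_k = 1000), "truncating")
})
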