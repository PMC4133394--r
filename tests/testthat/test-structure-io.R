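minimal_ca_line <- function(resno, x = 0, y = 0, z = 0, alt = " ", occ = 1,
                            chain = "A", serial = 1) {
  sprintf("ATOM  %5d  CA %s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, alt, "ALA", chain, resno, x, y, z, occ, 0, "C")
}

test_that("a minimal one-CA file parses to a single loop residue", {
  s <- parse_structure(c(minimal_ca_line(1), "END"))
  expect_equal(n_residues(s), 1L)
  expect_equal(s$residues$ss, "loop")
  expect_equal(s$ss_source, "none")
})

test_that("parsing fails cleanly without CA atoms", {
  expect_error(parse_structure(c("REMARK nothing here", "END")))
})

test_that("HETATM and waters are ignored", {
  lines <- c(minimal_ca_line(1), minimal_ca_line(2, x = 3.8, serial = 2),
             "HETATM    3  CA  HOH A   4      20.000  20.000  20.000  1.00  0.00           C",
             "END")
  s <- parse_structure(lines)
  expect_equal(n_residues(s), 2L)
})

test_that("altLoc conformers resolve to highest occupancy, ties to A", {
  lines <- c(minimal_ca_line(1, x = 0.0, alt = "A", occ = 0.4, serial = 1),
             minimal_ca_line(1, x = 5.0, alt = "B", occ = 0.6, serial = 2),
             minimal_ca_line(2, x = 3.8, alt = "A", occ = 0.5, serial = 3),
             minimal_ca_line(2, x = 9.9, alt = "B", occ = 0.5, serial = 4),
             "END")
  s <- parse_structure(lines)
  expect_equal(n_residues(s), 2L)
  expect_equal(s$residues$x, c(5.0, 3.8))   # B wins on occupancy, A on tie
})

test_that("duplicate residues without altLoc are a format error", {
  lines <- c(minimal_ca_line(1, serial = 1),
             minimal_ca_line(1, x = 2, serial = 2), "END")
  expect_error(parse_structure(lines), "altLoc")
})

test_that("chain selection defaults to the first chain with CA atoms", {
  lines <- c(minimal_ca_line(1, chain = "B", serial = 1),
             minimal_ca_line(2, x = 3.8, chain = "B", serial = 2),
             minimal_ca_line(7, x = 30, chain = "C", serial = 3),
             "END")
  s <- parse_structure(lines)
  expect_equal(s$residues$resno, c(1L, 2L))
  s_c <- parse_structure(lines, chain = "C")
  expect_equal(s_c$residues$resno, 7L)
})

test_that("external secondary-structure file overrides the header", {
  s <- toy_fold()
  lines <- write_pdb(s)
  ss_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%d\t%s", s$residues$resno,
                     c(H = "H", E = "E", C = "C")[
                       c(helix = "H", strand = "E", loop = "C")[s$residues$ss]]),
             ss_file)
  # flip everything to strand via the external file
  writeLines(sprintf("%d\tE", s$residues$resno), ss_file)
  s2 <- parse_structure(lines, ss_file = ss_file)
  expect_true(all(s2$residues$ss == "strand"))
  expect_equal(s2$ss_source, "external_file")
})

test_that("mutation strings parse to (wild, position, mutant)", {
  m <- parse_mutation_string(c("N166Y", "L114P"))
  expect_equal(m$wild, c("N", "L"))
  expect_equal(m$position, c(166L, 114L))
  expect_equal(m$mutant, c("Y", "P"))
  expect_error(parse_mutation_string("X0"), "malformed")
  expect_error(parse_mutation_string("166Y"), "malformed")
})

test_that("annotation resolves roles and enforces closure", {
  s <- toy_fold()
  cfg <- annotation_config(catalytic = 10L, active_site = c(20L, 30L),
                           mutated = "A25S", terminal_window = 4L)
  sa <- annotate_structure(s, cfg)
  expect_true(sa$residues$catalytic[sa$residues$resno == 10])
  # catalytic is contained in active_site
  expect_true(all(which(sa$residues$catalytic) %in%
                  which(sa$residues$active_site)))
  expect_true(sa$residues$mutated[sa$residues$resno == 25])
  expect_equal(sum(sa$residues$is_terminal), 8L)
  bad <- annotation_config(catalytic = 999L)
  expect_error(annotate_structure(s, bad), "not present")
})

test_that("residue mapping pairs by author number and lists the rest", {
  s <- toy_fold()
  mp <- map_residues(s, s)
  expect_equal(nrow(mp$matched), n_residues(s))
  expect_equal(mp$matched$index_ref, mp$matched$index_other)
  expect_length(mp$unmatched_ref, 0)

  trimmed <- s
  trimmed$residues <- trimmed$residues[-1, ]
  trimmed$residues$index <- seq_len(nrow(trimmed$residues))
  mp2 <- map_residues(s, trimmed)
  expect_equal(nrow(mp2$matched), n_residues(s) - 1L)
  expect_equal(mp2$unmatched_ref, 1L)

  other <- s
  other$residues$resno <- other$residues$resno + 1000L
  expect_error(map_residues(s, other), "common")
})

test_that("the Lipase A roster and annotation defaults are consistent", {
  roster <- lipase_structures()
  expect_equal(nrow(roster), 7L)
  expect_equal(roster$pdb_id[roster$name == "WT"], "1I6W")
  expect_equal(roster$pdb_id[roster$name == "6B"], "3QMM")
  # each successive mutant retains the earlier mutations
  muts <- strsplit(roster$mutations, ",")
  for (k in 3:7) expect_true(all(muts[[k - 1]] %in% muts[[k]]))
  ann <- lipase_annotation(roster$mutations[7])
  expect_setequal(ann$catalytic, c(77L, 133L, 156L))
  expect_true(all(ann$catalytic %in% ann$active_site))
  expect_equal(length(ann$mutated), 12L)
})
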