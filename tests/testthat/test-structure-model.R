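test_that("parse_structure handles minimal input, gaps and REMARK 465", {
  ch <- parse_structure(pdb_chain_text(5L), "A", "one")
  expect_s3_class(ch, "chain_structure")
  expect_equal(nrow(ch$residues), 1L)
  expect_equal(ch$residues$resno, 5L)
  expect_true(ch$residues$has_ca)

  # numbering gap 50 -> 61 yields missing range (51, 60)
  ch <- parse_structure(pdb_chain_text(c(48:50, 61:63)), "A")
  expect_equal(ch$missing_ranges, data.frame(start = 51L, end = 60L))

  # REMARK 465 outside numbering gaps is merged in
  ch <- parse_structure(pdb_chain_text(2:6, remark465 = c(7L, 8L)), "A")
  expect_true(any(ch$missing_ranges$start == 7L & ch$missing_ranges$end == 8L))

  expect_error(parse_structure(pdb_chain_text(1:3), "B"), "chain 'B'")
})

test_that("parse_structure flags hydrogens non-heavy and keeps the highest-occupancy altloc", {
  extra <- data.frame(resno = 1L, elety = c("H", "CB"),
                      element = c("H", "C"), x = c(4.0, 4.5), y = 0, z = 0)
  ch <- parse_structure(pdb_chain_text(1L, extra_atoms = extra), "A")
  expect_equal(sum(ch$atoms$is_heavy), 2L)  # CA + CB
  expect_true("H" %in% ch$atoms$elety)
  expect_false(ch$atoms$is_heavy[ch$atoms$elety == "H"])

  # two conformers of the same atom: highest occupancy wins
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.3),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.7),
    "END")
  ch <- parse_structure(lines, "A")
  expect_equal(nrow(ch$atoms), 1L)
  expect_equal(ch$atoms$x, 9)
})

test_that("synthetic round trip preserves residue and atom counts", {
  dp <- fix_pair()
  f <- tempfile(fileext = ".pdb")
  write_entry_pdb(dp$chain, f)
  ch <- parse_structure(readLines(f), "A", "FIX1")
  expect_equal(nrow(ch$residues), nrow(dp$chain$residues))
  expect_equal(nrow(ch$atoms), nrow(dp$chain$atoms))
  expect_equal(ch$missing_ranges, dp$chain$missing_ranges)
})

test_that("apply_domain_definitions materializes, orders and validates domains", {
  ch <- parse_structure(pdb_chain_text(1:30), "A")
  one <- apply_domain_definitions(ch, domain_definition("e", 1L, "1-30"))
  expect_length(one$domains, 1L)
  expect_equal(one$domains[[1]]$length, 30L)

  two <- apply_domain_definitions(ch, list(
    domain_definition("e", 2L, "16-30"), domain_definition("e", 1L, "1-15")))
  expect_equal(vapply(two$domains, function(d) d$domain_number, 1L), 1:2)

  disc <- apply_domain_definitions(ch, list(
    domain_definition("e", 1L, "1-10,21-30"),
    domain_definition("e", 2L, "11-20")))
  expect_equal(disc$domains[[1]]$length, 20L)
  expect_equal(classify_continuity(disc$domains[[1]]), "discontinuous")
  expect_equal(classify_continuity(disc$domains[[2]]), "continuous")

  # idempotent
  again <- apply_domain_definitions(disc, lapply(disc$domains,
                                                 function(d) d$definition))
  expect_equal(again$domains[[1]]$ord, disc$domains[[1]]$ord)

  expect_error(
    apply_domain_definitions(ch, domain_definition("e", 1L, "40-50")),
    "zero resolved")
})

test_that("linker_length counts by numbering, including missing residues", {
  mk <- function(resno) {
    ch <- parse_structure(pdb_chain_text(resno), "A")
    apply_domain_definitions(ch, list(
      domain_definition("e", 1L, "1-10"),
      domain_definition("e", 2L, sprintf("%d-%d", max(resno) - 9L,
                                         max(resno)))))
  }
  ch <- mk(1:20)  # abutting
  expect_identical(linker_length(ch, ch$domains[[1]], ch$domains[[2]]), 0L)

  ch <- mk(1:25)  # 5 resolved linker residues
  expect_identical(linker_length(ch, ch$domains[[1]], ch$domains[[2]]), 5L)
  # argument order does not matter
  expect_identical(linker_length(ch, ch$domains[[2]], ch$domains[[1]]), 5L)

  ch <- mk(c(1:10, 21:30))  # 10 unresolved positions
  expect_identical(linker_length(ch, ch$domains[[1]], ch$domains[[2]]), 10L)

  # overlapping domains error
  ch2 <- parse_structure(pdb_chain_text(1:20), "A")
  ch2 <- apply_domain_definitions(ch2, list(
    domain_definition("e", 1L, "1-12"), domain_definition("e", 2L, "10-20")))
  expect_error(linker_length(ch2, ch2$domains[[1]], ch2$domains[[2]]),
               "overlap")

  # intervening classified domain -> undefined
  ch3 <- parse_structure(pdb_chain_text(1:30), "A")
  ch3 <- apply_domain_definitions(ch3, list(
    domain_definition("e", 1L, "1-10"), domain_definition("e", 2L, "11-20"),
    domain_definition("e", 3L, "21-30")))
  expect_true(is.na(linker_length(ch3, ch3$domains[[1]], ch3$domains[[3]])))
})

test_that("is_consecutive_pair applies the linker cutoff only when residues are missing", {
  mk <- function(resno, last) {
    ch <- parse_structure(pdb_chain_text(resno), "A")
    apply_domain_definitions(ch, list(
      domain_definition("e", 1L, "1-10"),
      domain_definition("e", 2L, sprintf("%d-%d", last - 9L, last))))
  }
  # fully resolved 20-residue linker: consecutive regardless of length
  ch <- mk(1:40, 40L)
  expect_true(is_consecutive_pair(ch, ch$domains[[1]], ch$domains[[2]]))
  # ... unless the rule is configured to apply to resolved linkers too
  expect_false(is_consecutive_pair(ch, ch$domains[[1]], ch$domains[[2]],
                                   ddi_params(linker_rule_resolved = TRUE)))

  # missing-residue linker of exactly 13: consecutive
  ch <- mk(c(1:10, 24:33), 33L)
  expect_true(is_consecutive_pair(ch, ch$domains[[1]], ch$domains[[2]]))

  # missing-residue linker of 14: not consecutive (boundary flips)
  ch <- mk(c(1:10, 25:34), 34L)
  expect_false(is_consecutive_pair(ch, ch$domains[[1]], ch$domains[[2]]))
})

test_that("select_major_segment enforces length, coverage and interface rules", {
  seg_dom <- function(len1, len2, ifc_count) {
    resno <- c(seq_len(len1), (len1 + 50L) + seq_len(len2))
    segs <- data.frame(start = c(1L, len1 + 51L),
                       end = c(len1, len1 + 50L + len2))
    d <- toy_domain("e", 1L, resno, segments = segs)
    # interface with ifc_count residues inside segment 1
    xa <- matrix(runif(3 * max(ifc_count, 3)), ncol = 3)
    ifc <- toy_interface(xa, xa + 10, cbind(seq_len(nrow(xa)),
                                            seq_len(nrow(xa))))
    ifc$entry_a <- "e"; ifc$number_a <- 1L
    ifc$side_a$resno <- seq_len(nrow(xa))  # all inside segment 1
    list(d = d, ifc = ifc)
  }
  ok <- seg_dom(120L, 80L, 25L)
  seg <- select_major_segment(ok$d, ok$ifc)
  expect_equal(seg$start, 1L)
  expect_equal(seg$end, 120L)

  # longest segment 99 residues: rejected
  short <- seg_dom(99L, 80L, 25L)
  expect_null(select_major_segment(short$d, short$ifc))

  # longest segment 150 but only 45% coverage: rejected
  lowcov <- seg_dom(150L, 184L, 25L)
  expect_null(select_major_segment(lowcov$d, lowcov$ifc))

  # fewer than 20 interface residues contributed: rejected
  fewifc <- seg_dom(120L, 80L, 19L)
  expect_null(select_major_segment(fewifc$d, fewifc$ifc))
})
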