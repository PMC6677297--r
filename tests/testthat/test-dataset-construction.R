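test_that("pairwise identity reflects controlled mutation levels", {
  s <- paste(sample(c("A", "C", "D", "E", "F"), 100, replace = TRUE),
             collapse = "")
  expect_equal(pairwise_identity(s, s), 100)

  # mutate exactly 60 of 100 positions -> about 40% identity
  set.seed(51)
  fam <- make_sequence_family(100L, 1L, 0.40, seed = 52)
  expect_gte(pairwise_identity(fam[1], fam[2]), 38)
  expect_lte(pairwise_identity(fam[1], fam[2]), 42)

  # unrelated random sequences score low
  seeds <- sample.int(1e6, 20)
  ids <- vapply(1:10, function(i) {
    f1 <- make_sequence_family(100L, 0L, 1, seed = seeds[2 * i - 1])
    f2 <- make_sequence_family(100L, 0L, 1, seed = seeds[2 * i])
    pairwise_identity(f1[1], f2[1])
  }, 1)
  expect_lt(mean(ids), 30)
  expect_error(pairwise_identity("", "AAA"), "empty")
})

test_that("greedy clustering joins at the 40% boundary inclusively", {
  doms <- data.frame(entry_id = c("P1", "P2", "P3"),
                     domain_number = 1L,
                     sequence = rep(strrep("ACDEF", 10), 3))
  cl <- cluster_domains(doms)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 3L)
  expect_equal(cl[[1]]$cluster_id, 1L)

  # two families with low cross-identity form two clusters
  f1 <- make_sequence_family(60L, 2L, 0.8, seed = 61)
  f2 <- make_sequence_family(60L, 2L, 0.8, seed = 62)
  doms2 <- data.frame(entry_id = sprintf("P%d", 1:6), domain_number = 1L,
                      sequence = c(f1, f2))
  cl2 <- cluster_domains(doms2)
  expect_length(cl2, 2L)
  # clustering partitions the input
  expect_equal(sum(vapply(cl2, function(c) nrow(c$members), 1L)), 6L)

  # a domain at exactly the threshold identity joins (inclusive)
  rep_seq <- strrep("ACDEFGHIKL", 5)          # 50 residues
  exact40 <- paste0(substr(rep_seq, 1, 20), strrep("W", 30))  # 20/50 = 40%
  expect_equal(pairwise_identity(rep_seq, exact40), 40)
  cl3 <- cluster_domains(data.frame(
    entry_id = c("A", "B"), domain_number = 1L,
    sequence = c(rep_seq, exact40)))
  expect_length(cl3, 1L)
})

test_that("non-redundant selection follows the cluster-pair rules", {
  # two clusters; P1 (1.8 A) and P2 (2.4 A) both span them -> P1 selected
  clusters <- list(
    list(cluster_id = 1L,
         members = data.frame(entry_id = c("P1", "P2"),
                              domain_number = c(1L, 1L))),
    list(cluster_id = 2L,
         members = data.frame(entry_id = c("P1", "P2"),
                              domain_number = c(2L, 2L))))
  records <- list(toy_record("P1", res = 1.8), toy_record("P2", res = 2.4))
  sel <- select_nonredundant_pairs(clusters, records)
  expect_length(sel, 1L)
  expect_equal(sel[[1]]$entry_id, "P1")

  # a single common entry is selected as is
  sel1 <- select_nonredundant_pairs(clusters, records[1])
  expect_length(sel1, 1L)

  # reversed domain order is kept as a distinct pair
  clusters_rev <- list(
    list(cluster_id = 1L,
         members = data.frame(entry_id = c("P1", "P2"),
                              domain_number = c(1L, 2L))),
    list(cluster_id = 2L,
         members = data.frame(entry_id = c("P1", "P2"),
                              domain_number = c(2L, 1L))))
  sel2 <- select_nonredundant_pairs(clusters_rev, records)
  expect_length(sel2, 2L)

  # unclustered record errors
  expect_error(select_nonredundant_pairs(clusters,
                                         list(toy_record("P9"))),
               "not in any cluster")
})

test_that("non-redundant selection equals brute-force enumeration", {
  for (seed in 1:6) {
    inst <- random_nr_instance(n_clusters = sample(3:6, 1),
                               n_records = sample(8:15, 1), seed = seed)
    got <- select_nonredundant_pairs(inst$clusters, inst$records)
    want <- nonredundant_oracle(inst$clusters, inst$records)
    got_ids <- sort(vapply(got, function(r) r$record_id, ""))
    want_ids <- sort(vapply(inst$records[want], function(r) r$record_id, ""))
    expect_equal(got_ids, want_ids)
  }
})

test_that("representative selection ranks by resolution then length", {
  mk <- function(id, res, n) {
    ch <- parse_structure(pdb_chain_text(seq_len(n)), "A", id)
    ch$resolution <- res
    ch
  }
  picked <- representative_for_protein(list(mk("a", 2.0, 30), mk("b", 2.4, 50)))
  expect_equal(picked$entry_id, "a")
  picked <- representative_for_protein(list(mk("a", 2.0, 30), mk("b", 2.0, 50)))
  expect_equal(picked$entry_id, "b")
  single <- mk("only", 2.2, 10)
  expect_equal(representative_for_protein(list(single))$entry_id, "only")
  # configurable priority
  picked <- representative_for_protein(
    list(mk("a", 2.0, 30), mk("b", 2.4, 50)),
    ddi_params(representative_priority = "length"))
  expect_equal(picked$entry_id, "b")
})

test_that("pair enumeration applies class, interface-size and segment rules", {
  dp <- fix_pair()
  recs <- enumerate_pairs(list(dp$chain), "CC-2")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$pair_class, "CC-2")
  expect_true(is_interacting_pair(recs[[1]]$interface))

  # the same 2-domain chain contributes nothing to multi-domain classes
  expect_length(enumerate_pairs(list(dp$chain), "CC-M"), 0L)
  expect_length(enumerate_pairs(list(dp$chain), "CD-2"), 0L)

  # resolution filter: an entry beyond 2.5 A is excluded
  over <- dp$chain; over$resolution <- 2.7
  expect_length(enumerate_pairs(list(over), "CC-2"), 0L)

  # small interface excluded by the 20-residue rule
  small <- cached("small_pair", make_domain_pair(
    "SMALL", target_L = 14L, seed = 17,
    params = ddi_params(min_interface_residues = 10L)))
  expect_lt(small$interface$L, 20L)
  expect_length(enumerate_pairs(list(small$chain), "CC-2"), 0L)

  # a discontinuous domain whose major segment is too short is rejected
  disc_small <- cached("disc_small", make_domain_pair(
    "DISCS", n_a = 110L, style_a = "beta-sandwich",
    discontinuous = list(longest_fraction = 0.65), seed = 5))
  expect_length(enumerate_pairs(list(disc_small$chain), "CD-2"), 0L)

  # discontinuous entry passing the major-segment rules: CD-2 keeps it,
  # CC-2 does not
  disc <- cached("disc_pair", make_domain_pair(
    "DISC", n_a = 170L, style_a = "beta-sandwich",
    style_b = "helix-bundle", n_b = 80L, target_L = 50L,
    discontinuous = list(longest_fraction = 0.7), seed = 5))
  expect_length(enumerate_pairs(list(disc$chain), "CC-2"), 0L)
  cd <- enumerate_pairs(list(disc$chain), "CD-2")
  expect_length(cd, 1L)
  # the discontinuous domain's clustering sequence is its major segment
  dnum <- if (classify_continuity(cd[[1]]$domain_a) == "discontinuous")
    "domain_a" else "domain_b"
  d <- cd[[1]][[dnum]]
  expect_lt(nchar(d$cluster_sequence), d$length)
})

test_that("multi-domain enumeration matches a direct bookkeeping oracle", {
  tri <- cached("tri_chain", ddiscape:::.extend_with_third_domain(
    make_domain_pair("TRI", "helix-bundle", "mixed", n_a = 55L, n_b = 55L,
                     seed = 71, fold_a = "3.1.1", fold_b = "3.1.2"),
    seed = 72, fold_c = "3.1.3", target_L = 24L, params = ddi_params()))
  ch <- tri$chain
  ccm <- enumerate_pairs(list(ch), "CC-M")
  cum <- enumerate_pairs(list(ch), "CU-M")
  # oracle: count qualifying pairs directly from the rules
  n_ccm <- 0L; n_cum <- 0L
  for (i in 1:2) for (j in (i + 1):3) {
    da <- ch$domains[[i]]; db <- ch$domains[[j]]
    if (classify_continuity(da) != "continuous" ||
        classify_continuity(db) != "continuous") next
    ifc <- build_interface(da, db)
    if (!is_interacting_pair(ifc)) next
    n_cum <- n_cum + 1L
    if (is_consecutive_pair(ch, da, db)) n_ccm <- n_ccm + 1L
  }
  expect_length(ccm, n_ccm)
  expect_length(cum, n_cum)
  expect_gte(length(cum), length(ccm))
})

test_that("template libraries enforce the three dissimilarity rules", {
  dp <- fix_pair()       # helix-bundle + beta-sandwich hosts
  dp2 <- fix_pair2()     # mixed + helix-bundle
  q <- pair_record(dp$chain$domains[[1]], dp$chain$domains[[2]],
                   interface = dp$interface)
  same_fold <- q
  tm_sim <- pair_record(dp2$chain$domains[[1]], dp2$chain$domains[[2]],
                        interface = dp2$interface)
  # rule a: a pool member sharing a fold label with the query is excluded
  shared <- tm_sim
  shared$entry_id <- "SHARED"
  shared$domain_a$fold_label <- q$domain_a$fold_label
  lib <- build_template_library(q, list(shared))
  expect_length(lib$templates, 0L)
  expect_false(lib$filters$fold_ok[1])

  # rule c: structural similarity (here a helix bundle against the query's
  # helix bundle, TM >= 0.4) excludes the member
  lib2 <- build_template_library(q, list(tm_sim))
  expect_length(lib2$templates, 0L)
  expect_true(lib2$filters$fold_ok[1])
  expect_true(lib2$filters$seq_ok[1])
  expect_false(lib2$filters$tm_ok[1])
  # ... but with the filter relaxed above the measured similarity it passes
  lib3 <- build_template_library(q, list(tm_sim),
                                 ddi_params(tm_threshold = 0.99))
  expect_length(lib3$templates, 1L)
  expect_true(all(unlist(lib3$filters[1, c("fold_ok", "seq_ok", "tm_ok")])))

  # rule b: high sequence identity excludes even unrelated structures
  seqsim <- tm_sim
  seqsim$domain_a$cluster_sequence <- q$domain_a$cluster_sequence
  lib4 <- build_template_library(q, list(seqsim))
  expect_length(lib4$templates, 0L)
  expect_false(lib4$filters$seq_ok[1])

  # the query's own entry never enters its library
  lib5 <- build_template_library(q, list(same_fold))
  expect_length(lib5$templates, 0L)
})
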