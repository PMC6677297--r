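test_that("best_match returns the exact copy and respects ties deterministically", {
  dp <- fix_pair(); dp2 <- fix_pair2()
  q <- pair_record(dp$chain$domains[[1]], dp$chain$domains[[2]],
                   interface = dp$interface)
  copy <- q; copy$record_id <- "copy"; copy$entry_id <- "COPY"
  decoy <- pair_record(dp2$chain$domains[[1]], dp2$chain$domains[[2]],
                       interface = dp2$interface)
  r <- best_match(q, list(decoy, copy))
  expect_equal(r$best_template_id, "copy")
  expect_equal(r$scores$IS_score, 1, tolerance = 1e-9)

  # empty library -> explicit empty result
  r0 <- best_match(q, list())
  expect_true(is.na(r0$best_template_id))
  expect_equal(r0$n_templates, 0L)
})

test_that("enlarging a library never decreases the best IS-score", {
  dp <- fix_pair()
  q <- pair_record(dp$chain$domains[[1]], dp$chain$domains[[2]],
                   interface = dp$interface)
  lib <- list()
  prev <- 0
  pool <- list(fix_pair2(),
               cached("sup_pair3", make_domain_pair(
                 "SUP3", style_a = "beta-sandwich", style_b = "mixed",
                 seed = 23)),
               cached("plant05", plant_similar_interface(
                 dp$interface, host_styles = c("mixed", "mixed"),
                 noise_sigma = 0.5, seed = 9,
                 source_domains = dp$chain$domains)))
  for (i in seq_along(pool)) {
    e <- pool[[i]]
    lib[[i]] <- structure(list(
      record_id = paste0("T", i), entry_id = paste0("T", i),
      domain_a = e$chain$domains[[1]], domain_b = e$chain$domains[[2]],
      pair_class = "CC-2", interface = e$interface, resolution = 2.0,
      total_length = 100L), class = "domain_pair_record")
    cur <- best_match(q, lib)$scores$IS_score
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
  # the planted template (last added) wins
  expect_equal(best_match(q, lib)$best_template_id, "T3")
})

test_that("summary statistics use the sample (n-1) convention", {
  mk <- function(is) structure(list(
    query_id = "q", best_template_id = "t",
    scores = list(IS_score = is, rmsd = 3, f_res = 0.8, f_con = 0.5,
                  n_aligned = 10L, p_value = 0.01),
    significant = TRUE, n_templates = 5L), class = "search_result")
  one <- summarize_results(list(mk(0.5)))
  expect_equal(one$mean_IS, 0.5)
  expect_equal(one$sd_IS, 0)

  two <- summarize_results(list(mk(0.2), mk(0.4)))
  expect_equal(two$mean_IS, 0.3)
  expect_equal(two$sd_IS, 0.1414, tolerance = 1e-3)
  expect_equal(two$fraction_significant, 1)
  expect_error(summarize_results(list()), "no results")
})

test_that("cross-search: merged library best equals max of single libraries", {
  dp <- fix_pair()
  q <- pair_record(dp$chain$domains[[1]], dp$chain$domains[[2]],
                   interface = dp$interface)
  mkrec <- function(e, id) structure(list(
    record_id = id, entry_id = id, domain_a = e$chain$domains[[1]],
    domain_b = e$chain$domains[[2]], pair_class = "CC-2",
    interface = e$interface, resolution = 2.0, total_length = 100L),
    class = "domain_pair_record")
  libA <- list(mkrec(fix_pair2(), "A1"))
  libB <- list(mkrec(cached("plant05", plant_similar_interface(
    dp$interface, host_styles = c("mixed", "mixed"), noise_sigma = 0.5,
    seed = 9, source_domains = dp$chain$domains)), "B1"))
  cs <- cross_search(list(q), list(intra = libA, inter = libB))
  expect_true(all(cs$merged_is_max))
  expect_equal(cs$per_query$merged,
               pmax(cs$per_query$intra, cs$per_query$inter))
  # planted match lives only in library B; merged finds it
  expect_gte(cs$per_library$merged$mean_IS, cs$per_library$intra$mean_IS)
  expect_equal(cs$per_library$merged$mean_IS, cs$per_library$inter$mean_IS)

  # identical libraries give identical statistics
  cs2 <- cross_search(list(q), list(intra = libA, inter = libA))
  expect_equal(cs2$per_library$intra, cs2$per_library$inter)
})

test_that("dataset search reports results and skips empty libraries", {
  dp <- fix_pair(); dp2 <- fix_pair2()
  q1 <- pair_record(dp$chain$domains[[1]], dp$chain$domains[[2]],
                    interface = dp$interface)
  q2 <- pair_record(dp2$chain$domains[[1]], dp2$chain$domains[[2]],
                    interface = dp2$interface)
  builder <- function(q) if (q$entry_id == "FIX1") list(q2) else list()
  out <- run_dataset_search(list(q1, q2), builder)
  expect_length(out$results, 1L)
  expect_equal(out$skipped, q2$record_id)
  tab <- results_table(out$results)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("IS_score", "rmsd", "f_res", "f_con") %in% names(tab)))
})
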