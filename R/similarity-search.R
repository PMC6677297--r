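# Similarity search: closest structural match of each query interface in a
# template library, per-dataset summary statistics and cross-library
# comparisons.

#' Best structural match of a query interface in a library
#'
#' Aligns the query interface against every template with
#' [align_interfaces()] and returns the template maximizing the IS-score
#' (ties broken by first template id). When a significance model is given,
#' the match is annotated with its p-value and significance call.
#'
#' @param query a `domain_pair_record`.
#' @param library a `template_library` or plain list of
#'   `domain_pair_record`s.
#' @param params a [ddi_params()] object.
#' @param sig_model optional `ddi_significance` model.
#' @return Object of class `search_result` (fields `query_id`,
#'   `best_template_id`, `scores`, `significant`, `n_templates`), or an
#'   empty result (`best_template_id = NA`) for an empty library.
#' @export
best_match <- function(query, library, params = ddi_params(),
                       sig_model = NULL) {
  templates <- if (inherits(library, "template_library")) library$templates
               else library
  if (length(templates) == 0L)
    return(structure(list(query_id = query$record_id,
                          best_template_id = NA_character_, scores = NULL,
                          significant = NA, n_templates = 0L),
                     class = "search_result"))
  best <- NULL
  for (tr in templates) {
    al <- align_interfaces(query$interface, tr$interface, params)
    if (is.null(best) || al$scores$IS_score > best$scores$IS_score + 1e-12) {
      best <- al
      best$template_id <- tr$record_id
    }
  }
  sc <- best$scores
  sig <- NA
  if (!is.null(sig_model)) {
    sc$p_value <- significance_pvalue(sig_model, sc$IS_score)
    sig <- sc$p_value < sig_model$alpha
  }
  structure(list(query_id = query$record_id,
                 best_template_id = best$template_id,
                 scores = sc, alignment = best$alignment,
                 significant = sig, n_templates = length(templates)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  if (is.na(x$best_template_id)) {
    cat("search_result", x$query_id, ": empty library\n")
  } else {
    cat(sprintf("search_result %s -> %s  IS = %.4f (p = %.3g)\n",
                x$query_id, x$best_template_id, x$scores$IS_score,
                x$scores$p_value))
  }
  invisible(x)
}

#' Search a whole dataset, one template library per query
#'
#' @param records list of `domain_pair_record` queries.
#' @param library_builder function(query) returning the query's
#'   `template_library` (or list of records).
#' @param params a [ddi_params()] object.
#' @param sig_model optional `ddi_significance` model.
#' @return List with `results` (one `search_result` per query with a
#'   nonempty library) and `skipped` (query ids with empty libraries).
#' @export
run_dataset_search <- function(records, library_builder,
                               params = ddi_params(), sig_model = NULL) {
  results <- list(); skipped <- character()
  for (q in records) {
    lib <- library_builder(q)
    r <- best_match(q, lib, params, sig_model)
    if (is.na(r$best_template_id)) skipped <- c(skipped, q$record_id)
    else results[[length(results) + 1L]] <- r
  }
  list(results = results, skipped = skipped)
}

#' Summary statistics of best-match search results
#'
#' Sample means and standard deviations (n-1 convention) of the IS-score,
#' RMSD, residue coverage and contact coverage of the best matches, plus
#' the fraction of significant matches.
#'
#' @param results list of `search_result`s.
#' @return One-row data frame of class `summary_stats`.
#' @export
summarize_results <- function(results) {
  if (length(results) == 0L) stop("no results to summarize")
  g <- function(f) vapply(results, function(r) as.numeric(f(r$scores)), 1)
  is_ <- g(function(s) s$IS_score); rm_ <- g(function(s) s$rmsd)
  fr <- g(function(s) s$f_res); fc <- g(function(s) s$f_con)
  sig <- vapply(results, function(r) isTRUE(r$significant), TRUE)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(data.frame(
    n = length(results),
    mean_IS = mean(is_), sd_IS = sd0(is_),
    mean_rmsd = mean(rm_), sd_rmsd = sd0(rm_),
    mean_f_res = mean(fr), sd_f_res = sd0(fr),
    mean_f_con = mean(fc), sd_f_con = sd0(fc),
    fraction_significant = mean(sig)
  ), class = c("summary_stats", "data.frame"))
}

#' Results table (one row per query)
#'
#' @param results list of `search_result`s.
#' @return Data frame with query, template, IS-score, RMSD, N_a, f_res,
#'   f_con and p-value columns.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    query = r$query_id, template = r$best_template_id,
    IS_score = r$scores$IS_score, rmsd = r$scores$rmsd,
    N_a = r$scores$n_aligned, f_res = r$scores$f_res,
    f_con = r$scores$f_con, p_value = r$scores$p_value,
    significant = r$significant, stringsAsFactors = FALSE)))
}

#' Cross-search against intra-chain, inter-chain and merged libraries
#'
#' Runs the same query set against each named library and against their
#' union, returning per-library summary statistics and the per-query check
#' that the merged best equals the maximum of the single-library bests.
#'
#' @param queries list of `domain_pair_record`s.
#' @param libraries named list of template record lists sharing the query
#'   set (typically `intra` and `inter`).
#' @param params a [ddi_params()] object.
#' @param sig_model optional significance model.
#' @return List with `per_library` (summary stats per library and merged),
#'   `per_query` (data frame of best IS-scores), and `merged_is_max`
#'   (logical vector of the superset check).
#' @export
cross_search <- function(queries, libraries, params = ddi_params(),
                         sig_model = NULL) {
  stopifnot(length(libraries) >= 2L, !is.null(names(libraries)))
  libs <- c(libraries, list(merged = do.call(c, unname(libraries))))
  per_query <- data.frame(query = vapply(queries, function(q) q$record_id, ""))
  per_library <- list()
  for (nm in names(libs)) {
    res <- lapply(queries, function(q) best_match(q, libs[[nm]], params,
                                                  sig_model))
    per_library[[nm]] <- summarize_results(res)
    per_query[[nm]] <- vapply(res, function(r) r$scores$IS_score, 1)
  }
  single <- as.matrix(per_query[names(libraries)])
  check <- abs(per_query$merged - apply(single, 1L, max)) < 1e-9
  list(per_library = per_library, per_query = per_query,
       merged_is_max = check)
}

#' Paired t-test between two score vectors (reporting utility)
#'
#' @param x,y paired numeric vectors (e.g. best IS-scores of the same
#'   queries under two libraries).
#' @return The `htest` object from [stats::t.test()] with `paired = TRUE`.
#' @export
paired_score_test <- function(x, y) stats::t.test(x, y, paired = TRUE)
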