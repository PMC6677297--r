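# Dataset construction: pair enumeration by topology class, representative
# selection, domain-level sequence clustering and non-redundant pair
# selection, and per-query structurally-unrelated template libraries.

#' Percent sequence identity from a global alignment
#'
#' Global (Needleman-Wunsch) alignment with match 1, mismatch 0 and affine
#' gap costs, via Biostrings; identity is the number of identical aligned
#' positions over the alignment length (including internal gaps).
#'
#' @param seq1,seq2 nonempty protein sequences (character).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq1, seq2) {
  if (nchar(seq1) == 0L || nchar(seq2) == 0L) stop("empty sequence")
  letters <- unique(strsplit(paste0(seq1, seq2), "")[[1]])
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(seq1, seq2, type = "global",
                                       substitutionMatrix = m,
                                       gapOpening = 10, gapExtension = 0.5)
  as.numeric(Biostrings::pid(aln, type = "PID1"))
}

#' Greedy sequence clustering of domains
#'
#' CD-HIT-style greedy incremental clustering: domains are processed by
#' decreasing sequence length; each joins the first existing cluster whose
#' representative shares at least `identity_threshold` percent identity
#' (inclusive boundary), otherwise it founds a new cluster. Clusters are
#' numbered 1..N in order of creation.
#'
#' @param domains data frame with columns `entry_id`, `domain_number`,
#'   `sequence` (one row per domain), or a list of `domain_instance`
#'   objects (their `cluster_sequence` is used).
#' @param identity_threshold percent identity for membership (default 40).
#' @return List of clusters, each a list with `cluster_id`, `members`
#'   (data frame `entry_id`, `domain_number`) and `representative`
#'   (one-row data frame).
#' @export
cluster_domains <- function(domains, identity_threshold = 40) {
  if (!is.data.frame(domains)) {
    domains <- data.frame(
      entry_id = vapply(domains, function(d) d$entry_id, ""),
      domain_number = vapply(domains, function(d) d$domain_number, 1L),
      sequence = vapply(domains, function(d) d$cluster_sequence, ""),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("entry_id", "domain_number", "sequence") %in%
                  names(domains)))
  domains <- domains[order(-nchar(domains$sequence), domains$entry_id,
                           domains$domain_number), , drop = FALSE]
  reps <- character()
  members <- list()
  for (i in seq_len(nrow(domains))) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(domains$sequence[i], reps[k]) >=
          identity_threshold) {
        members[[k]] <- rbind(members[[k]], domains[i, , drop = FALSE])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, domains$sequence[i])
      members[[length(reps)]] <- domains[i, , drop = FALSE]
    }
  }
  lapply(seq_along(members), function(k) {
    m <- members[[k]][, c("entry_id", "domain_number")]
    rownames(m) <- NULL
    list(cluster_id = k, members = m,
         representative = m[1L, , drop = FALSE])
  })
}

#' Construct a domain pair record
#'
#' Bundles a pair of domains, their interface and bookkeeping fields into
#' the record type handled by dataset and search operations.
#'
#' @param domA,domB `domain_instance` objects (annotated order preserved).
#' @param pair_class one of `"CC-2"`, `"CC-M"`, `"CU-M"`, `"CD-2"`, `"PPI"`.
#' @param interface optional precomputed `domain_interface`; built from the
#'   domains when `NULL`.
#' @param params a [ddi_params()] object.
#' @return Object of class `domain_pair_record`.
#' @export
pair_record <- function(domA, domB, pair_class = "CC-2", interface = NULL,
                        params = ddi_params()) {
  if (is.null(interface))
    interface <- build_interface(domA, domB, params$contact_cutoff)
  structure(list(
    record_id = interface$pair_id,
    entry_id = domA$entry_id,
    domain_a = domA, domain_b = domB,
    pair_class = pair_class,
    interface = interface,
    resolution = domA$resolution,
    total_length = domA$length + domB$length
  ), class = "domain_pair_record")
}

#' @export
print.domain_pair_record <- function(x, ...) {
  cat(sprintf("domain_pair_record %s [%s] L = %d res = %.2f\n",
              x$record_id, x$pair_class, x$interface$L, x$resolution))
  invisible(x)
}

#' Enumerate interacting domain pairs of one topology class
#'
#' From structures annotated with domains, builds `domain_pair_record`s of
#' the requested class: `CC-2` (two-domain entries, both domains continuous
#' and consecutive), `CC-M` (consecutive continuous pairs from entries with
#' three or more domains), `CU-M` (all interacting continuous pairs,
#' consecutive or not, from entries with three or more domains) and `CD-2`
#' (two-domain entries with at least one discontinuous domain, each
#' discontinuous domain passing the major-segment rules; its clustering
#' sequence is restricted to the major segment). Every retained pair is
#' interacting (>= `min_interface_residues` interfacial residues) and, when
#' resolution is known, within the resolution filter.
#'
#' @param entries list of `chain_structure` objects with domains attached.
#' @param mode pair class to enumerate.
#' @param params a [ddi_params()] object.
#' @return List of `domain_pair_record`s.
#' @export
enumerate_pairs <- function(entries, mode = c("CC-2", "CC-M", "CU-M", "CD-2"),
                            params = ddi_params()) {
  mode <- match.arg(mode)
  out <- list()
  for (ch in entries) {
    nd <- length(ch$domains)
    if (nd < 2L) next
    if (!is.na(ch$resolution) && ch$resolution > params$resolution_max) next
    want2 <- mode %in% c("CC-2", "CD-2")
    if (want2 && nd != 2L) next
    if (!want2 && nd < 3L) next
    cont <- vapply(ch$domains, function(d)
      classify_continuity(d) == "continuous", TRUE)
    idx <- combn(nd, 2L)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1L, k]; j <- idx[2L, k]
      da <- ch$domains[[i]]; db <- ch$domains[[j]]
      if (mode %in% c("CC-2", "CC-M")) {
        if (!cont[i] || !cont[j]) next
        if (!is_consecutive_pair(ch, da, db, params)) next
      } else if (mode == "CU-M") {
        if (!cont[i] || !cont[j]) next
      } else {  # CD-2
        if (cont[i] && cont[j]) next
      }
      ifc <- build_interface(da, db, params$contact_cutoff)
      if (!is_interacting_pair(ifc, params$min_interface_residues)) next
      if (mode == "CD-2") {
        ok <- TRUE
        for (d in list(da, db)) {
          if (classify_continuity(d) == "discontinuous") {
            seg <- select_major_segment(d, ifc, params)
            if (is.null(seg)) { ok <- FALSE; break }
            sel <- d$residues$resno >= seg$start & d$residues$resno <= seg$end
            cs <- paste(d$residues$aa[sel], collapse = "")
            if (d$domain_number == da$domain_number) da$cluster_sequence <- cs
            else db$cluster_sequence <- cs
          }
        }
        if (!ok) next
      }
      out[[length(out) + 1L]] <- pair_record(da, db, mode, ifc, params)
    }
  }
  out
}

#' Representative structure for a protein
#'
#' Among candidate structures of the same protein, selects the
#' representative by best (lowest) resolution first, breaking ties by the
#' longest chain and then lexicographic entry id. Set
#' `params$representative_priority = "length"` to rank by length first.
#'
#' @param candidates list of `chain_structure` objects.
#' @param params a [ddi_params()] object.
#' @return The selected `chain_structure`.
#' @export
representative_for_protein <- function(candidates, params = ddi_params()) {
  stopifnot(length(candidates) >= 1L)
  res <- vapply(candidates, function(x) as.numeric(x$resolution), 1)
  len <- vapply(candidates, function(x) nrow(x$residues), 1L)
  ids <- vapply(candidates, function(x) x$entry_id, "")
  o <- if (params$representative_priority == "resolution")
    order(res, -len, ids) else order(-len, res, ids)
  candidates[[o[1L]]]
}

#' Non-redundant domain pair selection over cluster combinations
#'
#' For every ordered cluster combination (i < j), entries present in both
#' clusters with different domain numbers are collected; with no common
#' entry nothing is selected, a single common entry is selected as is, and
#' among several the one with the best resolution and the longest total
#' length is kept. Entries whose two domains appear in reversed order are
#' treated as distinct pairs and a representative is kept for each order.
#'
#' @param clusters list of clusters from [cluster_domains()].
#' @param records list of `domain_pair_record`s whose domains are all
#'   cluster members.
#' @param params a [ddi_params()] object.
#' @return List of selected `domain_pair_record`s.
#' @export
select_nonredundant_pairs <- function(clusters, records,
                                      params = ddi_params()) {
  key <- function(e, d) paste(e, d, sep = "#")
  memb <- new.env(parent = emptyenv())
  for (cl in clusters)
    for (r in seq_len(nrow(cl$members)))
      assign(key(cl$members$entry_id[r], cl$members$domain_number[r]),
             cl$cluster_id, envir = memb)
  getcl <- function(e, d) {
    k <- key(e, d)
    if (!exists(k, envir = memb))
      stop("domain ", k, " of a record is not in any cluster")
    get(k, envir = memb)
  }
  recs <- data.frame(
    idx = seq_along(records),
    entry = vapply(records, function(r) r$entry_id, ""),
    na = vapply(records, function(r) r$domain_a$domain_number, 1L),
    nb = vapply(records, function(r) r$domain_b$domain_number, 1L),
    res = vapply(records, function(r) as.numeric(r$resolution), 1),
    len = vapply(records, function(r) r$total_length, 1L),
    stringsAsFactors = FALSE)
  recs$cl_a <- mapply(getcl, recs$entry, recs$na)
  recs$cl_b <- mapply(getcl, recs$entry, recs$nb)

  pick <- function(sub) {
    o <- order(sub$res, -sub$len, sub$entry)
    sub$idx[o[1L]]
  }
  sel <- integer()
  cl_pairs <- unique(rbind(
    data.frame(i = pmin(recs$cl_a, recs$cl_b),
               j = pmax(recs$cl_a, recs$cl_b))))
  cl_pairs <- cl_pairs[cl_pairs$i < cl_pairs$j, , drop = FALSE]
  for (r in seq_len(nrow(cl_pairs))) {
    i <- cl_pairs$i[r]; j <- cl_pairs$j[r]
    fwd <- recs[recs$cl_a == i & recs$cl_b == j & recs$na != recs$nb, ,
                drop = FALSE]
    rev <- recs[recs$cl_a == j & recs$cl_b == i & recs$na != recs$nb, ,
                drop = FALSE]
    if (nrow(fwd) > 0L) sel <- c(sel, pick(fwd))
    if (nrow(rev) > 0L) sel <- c(sel, pick(rev))
  }
  records[sort(unique(sel))]
}

# topology level of a hierarchical fold label: first three dot-separated
# fields when the label is CATH-formatted, else the full label
fold_topology <- function(label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  if (length(parts) >= 3L) paste(parts[1:3], collapse = ".") else label
}

#' Build the structurally-unrelated template library of one query
#'
#' Retains pool members that pass, against BOTH query domains (all four
#' cross-domain combinations for the sequence and structure rules):
#' (a) no domain within the query's fold topology, (b) no significant
#' sequence similarity (pairwise identity below
#' `identity_surrogate_threshold`, or a user-supplied dissimilarity
#' predicate), and (c) no significant structural similarity (all
#' cross-domain TM-scores below `tm_threshold`). The query's own entry is
#' always excluded.
#'
#' @param query a `domain_pair_record`.
#' @param pool list of candidate `domain_pair_record`s.
#' @param params a [ddi_params()] object.
#' @param seq_dissim_fn optional function(seq_template, seq_query) returning
#'   `TRUE` when the two sequences are dissimilar; defaults to the pairwise
#'   identity surrogate.
#' @return Object of class `template_library` with `query`, `templates`
#'   and a `filters` data frame tracing each rule per pool member.
#' @export
build_template_library <- function(query, pool, params = ddi_params(),
                                   seq_dissim_fn = NULL) {
  if (is.null(seq_dissim_fn))
    seq_dissim_fn <- function(st, sq)
      pairwise_identity(st, sq) < params$identity_surrogate_threshold
  qd <- list(query$domain_a, query$domain_b)
  qtopo <- vapply(qd, function(d) fold_topology(d$fold_label), "")
  trace <- data.frame(template_id = vapply(pool, function(r) r$record_id, ""),
                      fold_ok = NA, seq_ok = NA, tm_ok = NA,
                      stringsAsFactors = FALSE)
  templates <- list()
  for (k in seq_along(pool)) {
    tr <- pool[[k]]
    if (tr$entry_id == query$entry_id) next
    td <- list(tr$domain_a, tr$domain_b)
    ttopo <- vapply(td, function(d) fold_topology(d$fold_label), "")
    trace$fold_ok[k] <- !any(ttopo %in% qtopo)
    if (!trace$fold_ok[k]) next
    seq_ok <- TRUE
    for (a in td) for (b in qd)
      if (!seq_dissim_fn(a$cluster_sequence, b$cluster_sequence)) {
        seq_ok <- FALSE
      }
    trace$seq_ok[k] <- seq_ok
    if (!seq_ok) next
    tm_ok <- TRUE
    for (a in td) for (b in qd) {
      if (!tm_ok) break
      if (tm_score_domains(a, b, params) >= params$tm_threshold)
        tm_ok <- FALSE
    }
    trace$tm_ok[k] <- tm_ok
    if (!tm_ok) next
    templates[[length(templates) + 1L]] <- tr
  }
  structure(list(query = query, templates = templates, filters = trace),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("template_library for %s: %d/%d pool members retained\n",
              x$query$record_id, length(x$templates), nrow(x$filters)))
  invisible(x)
}

#' Read a domain boundary table
#'
#' Reads the TSV format `entry_id, chain, domain_number, segments,
#' fold_label, resolution` where `segments` is `"start-end[,start-end]"`.
#'
#' @param file path to the TSV.
#' @return Data frame with those columns.
#' @export
read_domain_table <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(chain = "character"))
  stopifnot(all(c("entry_id", "chain", "domain_number", "segments",
                  "fold_label", "resolution") %in% names(df)))
  df
}

#' Attach the domains listed in a domain table to a parsed chain
#'
#' @param chain a `chain_structure`.
#' @param table data frame from [read_domain_table()].
#' @return The chain with matching domain definitions applied.
#' @export
annotate_from_table <- function(chain, table) {
  rows <- table[table$entry_id == chain$entry_id &
                  table$chain == chain$chain_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no domain rows for entry ", chain$entry_id)
  defs <- lapply(seq_len(nrow(rows)), function(i)
    domain_definition(chain$entry_id, rows$domain_number[i],
                      rows$segments[i], rows$fold_label[i],
                      rows$resolution[i]))
  chain$resolution <- rows$resolution[1L]
  apply_domain_definitions(chain, defs)
}

#' Write a dataset manifest TSV
#'
#' One row per record: entry, domain numbers, fold labels, pair class,
#' interface size, resolution.
#'
#' @param records list of `domain_pair_record`s.
#' @param file output TSV path.
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset_manifest <- function(records, file) {
  df <- data.frame(
    record_id = vapply(records, function(r) r$record_id, ""),
    entry_id = vapply(records, function(r) r$entry_id, ""),
    domain_a = vapply(records, function(r) r$domain_a$domain_number, 1L),
    domain_b = vapply(records, function(r) r$domain_b$domain_number, 1L),
    fold_a = vapply(records, function(r) r$domain_a$fold_label, ""),
    fold_b = vapply(records, function(r) r$domain_b$fold_label, ""),
    pair_class = vapply(records, function(r) r$pair_class, ""),
    L = vapply(records, function(r) r$interface$L, 1L),
    resolution = vapply(records, function(r) as.numeric(r$resolution), 1),
    stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write sequence clusters as TSV
#'
#' @param clusters list from [cluster_domains()].
#' @param file output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_clusters_tsv <- function(clusters, file) {
  df <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id,
               entry_id = cl$members$entry_id,
               domain_number = cl$members$domain_number,
               is_representative = seq_len(nrow(cl$members)) == 1L)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
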