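# Structure model: chains, residues, domain definitions, and the
# topological classification of domain pairs (continuous/discontinuous,
# consecutive via linker rules).

#' Parse a PDB-format structure into a chain model
#'
#' Reads standard PDB coordinate records (via bio3d) and materializes a
#' single chain as an ordered residue table plus an atom table. Hydrogens
#' are retained but flagged as non-heavy; alternate locations are resolved
#' by keeping the highest-occupancy conformer (ties: first encountered);
#' HETATM records are kept only for residues that carry a C-alpha (waters
#' and ligands are dropped). Unresolved stretches are derived from gaps in
#' author residue numbering and from REMARK 465 records when present.
#'
#' @param pdb_text character scalar (or vector of lines) with PDB records.
#' @param chain_id single chain identifier to extract.
#' @param entry_id optional structure identifier; defaults to `"entry"`.
#' @param resolution optional resolution in Angstrom attached to the chain.
#' @return An object of class `chain_structure` with elements `entry_id`,
#'   `chain_id`, `residues` (ordered data frame: `ord`, `resno`, `ins`,
#'   `aa`, `has_ca`, `ca_x/y/z`), `atoms` (data frame keyed by residue
#'   ordinal), `missing_ranges`, `domains` (empty list) and `resolution`.
#' @export
parse_structure <- function(pdb_text, chain_id, entry_id = "entry",
                            resolution = NA_real_) {
  if (length(pdb_text) == 1L) pdb_text <- strsplit(pdb_text, "\n")[[1]]
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("unreadable PDB records: ", conditionMessage(e),
                             call. = FALSE))
  at <- pdb$atom
  if (!chain_id %in% unique(at$chain))
    stop("chain '", chain_id, "' not present in structure (chains: ",
         paste(unique(at$chain), collapse = ", "), ")", call. = FALSE)
  at <- at[at$chain == chain_id, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""

  # altloc: keep highest occupancy per (resno, insert, elety), ties first
  at$o[is.na(at$o)] <- 1
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord0 <- order(match(key, unique(key)), -at$o)
  at <- at[ord0, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "|")), ,
           drop = FALSE]
  at <- at[order(match(paste(at$resno, at$insert, sep = "|"),
                       unique(paste(at$resno, at$insert, sep = "|")))), ,
           drop = FALSE]

  # drop HETATM residues without a C-alpha (waters, ligands)
  rkey <- paste(at$resno, at$insert, sep = "|")
  has_ca <- tapply(at$elety == "CA", rkey, any)
  is_het <- tapply(at$type == "HETATM", rkey, all)
  keep_res <- names(has_ca)[has_ca | !is_het]
  at <- at[rkey %in% keep_res, , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein residues on chain ", chain_id)

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9]", "", at$elety[bad]), 1, 1)
  is_heavy <- toupper(elem) != "H"

  rkey <- paste(at$resno, at$insert, sep = "|")
  ukeys <- unique(rkey)
  ord <- match(rkey, ukeys)
  first <- !duplicated(rkey)
  aa3 <- at$resid[first]
  aa1 <- suppressWarnings(bio3d::aa321(aa3))
  aa1[is.na(aa1)] <- "X"
  ca_idx <- match(paste(ukeys, "CA"), paste(rkey, at$elety))
  residues <- data.frame(
    ord = seq_along(ukeys),
    resno = at$resno[first],
    ins = at$insert[first],
    aa = aa1,
    has_ca = !is.na(ca_idx),
    ca_x = at$x[ca_idx], ca_y = at$y[ca_idx], ca_z = at$z[ca_idx],
    stringsAsFactors = FALSE)
  atoms <- data.frame(
    ord = ord, elety = at$elety, element = toupper(elem),
    is_heavy = is_heavy, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))

  missing_ranges <- .numbering_gaps(residues$resno)
  rem <- .parse_remark465(pdb_text, chain_id)
  if (nrow(rem) > 0L)
    missing_ranges <- .merge_ranges(rbind(missing_ranges, rem))

  structure(list(entry_id = entry_id, chain_id = chain_id,
                 residues = residues, atoms = atoms,
                 missing_ranges = missing_ranges,
                 domains = list(), resolution = resolution),
            class = "chain_structure")
}

.numbering_gaps <- function(resno) {
  d <- diff(resno)
  i <- which(d > 1L)
  data.frame(start = resno[i] + 1L, end = resno[i + 1L] - 1L)
}

.parse_remark465 <- function(lines, chain_id) {
  rl <- grep("^REMARK 465", lines, value = TRUE)
  m <- regmatches(rl, regexec(
    "^REMARK 465\\s+([A-Z]{3})\\s+([A-Za-z0-9])\\s+(-?[0-9]+)\\s*$", rl))
  hit <- vapply(m, length, 1L) == 4L
  if (!any(hit)) return(data.frame(start = integer(), end = integer()))
  ch <- vapply(m[hit], `[`, "", 3L)
  num <- as.integer(vapply(m[hit], `[`, "", 4L))
  num <- sort(unique(num[ch == chain_id]))
  if (length(num) == 0L) return(data.frame(start = integer(), end = integer()))
  brk <- c(0L, which(diff(num) > 1L), length(num))
  data.frame(start = num[head(brk, -1L) + 1L], end = num[tail(brk, -1L)])
}

.merge_ranges <- function(rg) {
  if (nrow(rg) <= 1L) return(rg)
  rg <- rg[order(rg$start), , drop = FALSE]
  out <- rg[1L, , drop = FALSE]
  for (i in seq_len(nrow(rg))[-1L]) {
    k <- nrow(out)
    if (rg$start[i] <= out$end[k] + 1L) out$end[k] <- max(out$end[k], rg$end[i])
    else out <- rbind(out, rg[i, ])
  }
  rownames(out) <- NULL
  out
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("chain_structure %s chain %s: %d residues, %d atoms, %d domain(s)\n",
              x$entry_id, x$chain_id, nrow(x$residues), nrow(x$atoms),
              length(x$domains)))
  invisible(x)
}

#' Create a domain definition
#'
#' A CATH-style delineation of one structural domain: one or more residue
#' segments (author numbering, inclusive), a hierarchical fold label and
#' the crystallographic resolution of the parent entry.
#'
#' @param entry_id structure identifier (entry + chain).
#' @param domain_number ordinal of the domain within the chain.
#' @param segments data frame with columns `start` and `end`, or a string
#'   like `"1-100,151-200"`.
#' @param fold_label hierarchical classification string (topology level is
#'   what the template-library fold rule compares).
#' @param resolution resolution in Angstrom.
#' @return Object of class `domain_definition`.
#' @export
domain_definition <- function(entry_id, domain_number, segments,
                              fold_label = "unclassified",
                              resolution = NA_real_) {
  if (is.character(segments)) segments <- parse_segments(segments)
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            all(segments$start <= segments$end))
  segments <- segments[order(segments$start), c("start", "end"), drop = FALSE]
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)]))
    stop("overlapping segments in domain definition ", entry_id, ":",
         domain_number)
  structure(list(entry_id = entry_id,
                 domain_number = as.integer(domain_number),
                 segments = segments, fold_label = fold_label,
                 resolution = resolution),
            class = "domain_definition")
}

#' Parse a segment string like "1-100,151-200"
#' @param x character scalar.
#' @return data frame with `start`, `end` columns.
#' @export
parse_segments <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*(-?[0-9]+)-(-?[0-9]+)\\s*$", parts))
  if (any(vapply(m, length, 1L) != 3L)) stop("cannot parse segments: ", x)
  data.frame(start = as.integer(vapply(m, `[`, "", 2L)),
             end = as.integer(vapply(m, `[`, "", 3L)))
}

#' Materialize domain definitions on a parsed chain
#'
#' Resolves each definition's segments against the chain's residues and
#' attaches the resulting `domain_instance` objects, sorted from N- to
#' C-terminus by first residue. Idempotent: any previously attached domains
#' are replaced.
#'
#' @param chain a `chain_structure`.
#' @param defs list of `domain_definition` objects.
#' @return The chain with `domains` populated.
#' @export
apply_domain_definitions <- function(chain, defs) {
  stopifnot(inherits(chain, "chain_structure"))
  if (inherits(defs, "domain_definition")) defs <- list(defs)
  doms <- lapply(defs, function(d) .materialize_domain(chain, d))
  first_ord <- vapply(doms, function(d) d$ord[1L], 1L)
  chain$domains <- doms[order(first_ord)]
  chain
}

.materialize_domain <- function(chain, def) {
  res <- chain$residues
  in_seg <- function(s) which(res$resno >= s[["start"]] & res$resno <= s[["end"]])
  per_seg <- lapply(seq_len(nrow(def$segments)), function(i)
    in_seg(def$segments[i, ]))
  empty <- vapply(per_seg, length, 1L) == 0L
  if (any(empty))
    stop("domain ", def$entry_id, ":", def$domain_number,
         " has segment(s) with zero resolved residues: ",
         paste(sprintf("%d-%d", def$segments$start[empty],
                       def$segments$end[empty]), collapse = ", "))
  ord <- sort(unique(unlist(per_seg)))
  sub <- res[ord, , drop = FALSE]
  ca_rows <- sub[sub$has_ca, , drop = FALSE]
  structure(list(
    definition = def,
    entry_id = def$entry_id,
    domain_number = def$domain_number,
    ord = ord,
    sequence = paste(sub$aa, collapse = ""),
    cluster_sequence = paste(sub$aa, collapse = ""),
    length = nrow(sub),
    residues = sub,
    ca = as.matrix(ca_rows[, c("ca_x", "ca_y", "ca_z")]),
    ca_ord = ca_rows$ord,
    atoms = chain$atoms[chain$atoms$ord %in% ord, , drop = FALSE],
    fold_label = def$fold_label,
    resolution = def$resolution
  ), class = "domain_instance")
}

#' @export
print.domain_instance <- function(x, ...) {
  cat(sprintf("domain_instance %s:%d [%s] %d residues, %d segment(s)\n",
              x$entry_id, x$domain_number, x$fold_label, x$length,
              nrow(x$definition$segments)))
  invisible(x)
}

#' Classify a domain as continuous or discontinuous
#'
#' A domain is continuous if and only if it is delineated by exactly one
#' sequence segment.
#'
#' @param domain a `domain_instance`.
#' @return `"continuous"` or `"discontinuous"`.
#' @export
classify_continuity <- function(domain) {
  stopifnot(inherits(domain, "domain_instance"))
  if (nrow(domain$definition$segments) == 1L) "continuous" else "discontinuous"
}

#' Inter-domain linker length between two continuous domains
#'
#' Counts the residue positions strictly between the first domain's last
#' residue and the second domain's first residue by author numbering, so
#' annotated missing residues are counted. Returns `NA` (undefined) when
#' another classified domain of the chain lies between the two.
#'
#' @param chain a `chain_structure` with domains attached.
#' @param domA,domB continuous `domain_instance` objects of that chain.
#' @return Integer linker length, or `NA_integer_` when undefined.
#' @export
linker_length <- function(chain, domA, domB) {
  stopifnot(inherits(chain, "chain_structure"))
  if (length(intersect(domA$ord, domB$ord)) > 0L)
    stop("domains overlap: ", domA$domain_number, " and ", domB$domain_number)
  if (domA$ord[1L] > domB$ord[1L]) { tmp <- domA; domA <- domB; domB <- tmp }
  if (.has_intervening_domain(chain, domA, domB)) return(NA_integer_)
  a_end <- chain$residues$resno[max(domA$ord)]
  b_start <- chain$residues$resno[min(domB$ord)]
  max(0L, as.integer(b_start - a_end - 1L))
}

.has_intervening_domain <- function(chain, domA, domB) {
  lo <- max(domA$ord); hi <- min(domB$ord)
  for (d in chain$domains) {
    if (d$domain_number %in% c(domA$domain_number, domB$domain_number) &&
        d$entry_id == domA$entry_id) next
    if (any(d$ord > lo & d$ord < hi)) return(TRUE)
  }
  FALSE
}

#' Are two continuous domains consecutive?
#'
#' Two continuous domains are consecutive when no classified domain lies
#' between them and, if the intervening linker contains missing residues,
#' the linker (counted by residue numbering) is at most
#' `max_linker_when_missing` residues. A fully resolved linker is accepted
#' at any length unless `params$linker_rule_resolved` is set.
#'
#' @param chain a `chain_structure` with domains attached.
#' @param domA,domB continuous `domain_instance` objects.
#' @param params a [ddi_params()] object (uses `max_missing_linker` and
#'   `linker_rule_resolved`).
#' @return Logical.
#' @export
is_consecutive_pair <- function(chain, domA, domB, params = ddi_params()) {
  stopifnot(classify_continuity(domA) == "continuous",
            classify_continuity(domB) == "continuous")
  n <- linker_length(chain, domA, domB)
  if (is.na(n)) return(FALSE)
  if (domA$ord[1L] > domB$ord[1L]) { tmp <- domA; domA <- domB; domB <- tmp }
  a_end <- chain$residues$resno[max(domA$ord)]
  b_start <- chain$residues$resno[min(domB$ord)]
  resolved <- sum(chain$residues$resno > a_end & chain$residues$resno < b_start)
  has_missing <- resolved < n
  if (has_missing || params$linker_rule_resolved)
    n <= params$max_missing_linker
  else TRUE
}

#' Major segment of a discontinuous domain
#'
#' A discontinuous domain is represented by its longest segment provided
#' that segment (a) has at least `major_segment_min_length` resolved
#' residues, (b) covers at least `major_segment_min_coverage` of the total
#' domain length and (c) contributes at least
#' `major_segment_min_interface` residues to the domain-domain interface.
#'
#' @param domain a discontinuous `domain_instance`.
#' @param interface the `domain_interface` of the full domain pair; the side
#'   belonging to `domain` is located automatically.
#' @param params a [ddi_params()] object.
#' @return A one-row data frame (`start`, `end`) for the accepted major
#'   segment, or `NULL` when the domain is rejected.
#' @export
select_major_segment <- function(domain, interface, params = ddi_params()) {
  stopifnot(classify_continuity(domain) == "discontinuous",
            inherits(interface, "domain_interface"))
  segs <- domain$definition$segments
  counts <- vapply(seq_len(nrow(segs)), function(i)
    sum(domain$residues$resno >= segs$start[i] &
          domain$residues$resno <= segs$end[i]), 1L)
  k <- which.max(counts)
  seg <- segs[k, , drop = FALSE]
  len <- counts[k]
  if (len < params$major_segment_min_length) return(NULL)
  if (len / domain$length < params$major_segment_min_coverage) return(NULL)
  side <- interface_side_for(interface, domain)
  if (is.null(side)) return(NULL)
  n_int <- sum(side$resno >= seg$start & side$resno <= seg$end)
  if (n_int < params$major_segment_min_interface) return(NULL)
  rownames(seg) <- NULL
  seg
}
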