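# Interface extraction: inter-domain heavy-atom contacts, interfacial
# residue sets, the interacting-pair criterion and interface planarity.

#' Heavy-atom contacts between two domains
#'
#' A residue pair (one residue from each domain) is in contact when the
#' minimum distance between any heavy atom of one and any heavy atom of the
#' other is at most `cutoff` (inclusive boundary). Hydrogens never
#' contribute. Candidate residue pairs are pruned by residue centroid
#' distance plus per-residue radii before exact atom-atom evaluation; the
#' result is identical to the all-pairs double loop.
#'
#' @param domA,domB `domain_instance` objects sharing no residues.
#' @param cutoff contact distance cutoff in Angstrom (default 4.5).
#' @return Data frame with one row per contacting residue pair: `ord_a`,
#'   `ord_b` (chain residue ordinals), `min_dist`.
#' @export
heavy_atom_contacts <- function(domA, domB, cutoff = 4.5) {
  stopifnot(inherits(domA, "domain_instance"), inherits(domB, "domain_instance"))
  if (domA$length == 0L || domB$length == 0L) stop("empty domain")
  if (length(intersect(domA$ord, domB$ord)) > 0L)
    stop("domains share residues")
  .residue_contacts(domA$atoms, domB$atoms, cutoff)
}

# Residue-level contacts between two atom tables (cols: ord, is_heavy, x,y,z)
.residue_contacts <- function(atA, atB, cutoff) {
  atA <- atA[atA$is_heavy, , drop = FALSE]
  atB <- atB[atB$is_heavy, , drop = FALSE]
  empty <- data.frame(ord_a = integer(), ord_b = integer(),
                      min_dist = numeric())
  if (nrow(atA) == 0L || nrow(atB) == 0L) return(empty)
  cen <- function(at) {
    xs <- rowsum(cbind(at$x, at$y, at$z), at$ord)
    n <- as.vector(rowsum(rep(1, nrow(at)), at$ord))
    ords <- as.integer(rownames(xs))
    c3 <- xs / n
    r <- vapply(seq_along(ords), function(i) {
      sel <- at$ord == ords[i]
      sqrt(max(rowSums((cbind(at$x[sel], at$y[sel], at$z[sel]) -
                          matrix(c3[i, ], sum(sel), 3, byrow = TRUE))^2)))
    }, 1)
    list(ord = ords, xyz = c3, r = r)
  }
  ca <- cen(atA); cb <- cen(atB)
  # prune residue pairs whose bounding spheres cannot come within cutoff
  d2 <- outer(rowSums(ca$xyz^2), rowSums(cb$xyz^2), "+") -
    2 * (ca$xyz %*% t(cb$xyz))
  lim <- outer(ca$r, cb$r, "+") + cutoff
  cand <- which(d2 <= lim^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  out <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    oa <- ca$ord[cand[k, 1L]]; ob <- cb$ord[cand[k, 2L]]
    xa <- as.matrix(atA[atA$ord == oa, c("x", "y", "z")])
    xb <- as.matrix(atB[atB$ord == ob, c("x", "y", "z")])
    dd <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * (xa %*% t(xb))
    md <- sqrt(max(0, min(dd)))
    if (md <= cutoff)
      out[[k]] <- data.frame(ord_a = oa, ord_b = ob, min_dist = md)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$ord_a, out$ord_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the domain-domain interface of a pair of domains
#'
#' The interface consists of every residue of either domain participating
#' in at least one heavy-atom contact with the other domain, the
#' inter-domain contact map, and the total interfacial residue count
#' `L = |side_a| + |side_b|`. A pair of domains with no contacts yields an
#' empty interface (flagged, not an error).
#'
#' @inheritParams heavy_atom_contacts
#' @param pair_id optional identifier for the interface.
#' @return Object of class `domain_interface` with elements `side_a`,
#'   `side_b` (data frames: `ord`, `resno`, `aa`, `x`, `y`, `z`, `has_ca`,
#'   `n_contacts`), `contacts` (`ia`, `ib` row indices into the sides,
#'   `ord_a`, `ord_b`, `min_dist`), `L`, `n_contacts_total` and the two
#'   domain identities.
#' @export
build_interface <- function(domA, domB, cutoff = 4.5, pair_id = NULL) {
  cts <- heavy_atom_contacts(domA, domB, cutoff)
  if (is.null(pair_id))
    pair_id <- sprintf("%s:%d-%d", domA$entry_id, domA$domain_number,
                       domB$domain_number)
  side <- function(dom, ords) {
    sub <- dom$residues[match(ords, dom$residues$ord), , drop = FALSE]
    data.frame(ord = sub$ord, resno = sub$resno, aa = sub$aa,
               x = sub$ca_x, y = sub$ca_y, z = sub$ca_z,
               has_ca = sub$has_ca,
               n_contacts = rep(0L, nrow(sub)), stringsAsFactors = FALSE)
  }
  sa <- side(domA, sort(unique(cts$ord_a)))
  sb <- side(domB, sort(unique(cts$ord_b)))
  if (nrow(cts) > 0L) {
    cts$ia <- match(cts$ord_a, sa$ord)
    cts$ib <- match(cts$ord_b, sb$ord)
    sa$n_contacts <- as.integer(tabulate(cts$ia, nbins = nrow(sa)))
    sb$n_contacts <- as.integer(tabulate(cts$ib, nbins = nrow(sb)))
  } else {
    cts$ia <- integer(); cts$ib <- integer()
  }
  structure(list(pair_id = pair_id,
                 entry_a = domA$entry_id, number_a = domA$domain_number,
                 entry_b = domB$entry_id, number_b = domB$domain_number,
                 side_a = sa, side_b = sb,
                 contacts = cts[, c("ia", "ib", "ord_a", "ord_b", "min_dist")],
                 L = nrow(sa) + nrow(sb),
                 n_contacts_total = nrow(cts),
                 cutoff = cutoff),
            class = "domain_interface")
}

#' @export
print.domain_interface <- function(x, ...) {
  cat(sprintf("domain_interface %s: L = %d (%d + %d), %d contacts\n",
              x$pair_id, x$L, nrow(x$side_a), nrow(x$side_b),
              x$n_contacts_total))
  invisible(x)
}

# locate the interface side that belongs to a given domain, or NULL
interface_side_for <- function(interface, domain) {
  if (interface$entry_a == domain$entry_id &&
      interface$number_a == domain$domain_number) return(interface$side_a)
  if (interface$entry_b == domain$entry_id &&
      interface$number_b == domain$domain_number) return(interface$side_b)
  NULL
}

#' Interacting-pair criterion
#'
#' Two domains interact when at least `min_residues` residues (both sides
#' together) are involved in interfacial heavy-atom contacts.
#'
#' @param interface a `domain_interface`.
#' @param min_residues minimum interfacial residue count (default 20).
#' @return Logical.
#' @export
is_interacting_pair <- function(interface, min_residues = 20L) {
  stopifnot(inherits(interface, "domain_interface"))
  interface$L >= min_residues
}

#' Interface planarity
#'
#' Root-mean-square deviation of the interfacial C-alpha atoms from their
#' least-squares plane (the plane through the centroid whose normal is the
#' smallest principal axis of the C-alpha cloud). Flat interfaces score
#' near zero.
#'
#' @param interface a `domain_interface` with at least three C-alpha
#'   bearing interfacial residues.
#' @return RMS plane deviation in Angstrom.
#' @export
interface_planarity <- function(interface) {
  stopifnot(inherits(interface, "domain_interface"))
  xyz <- rbind(as.matrix(interface$side_a[interface$side_a$has_ca,
                                          c("x", "y", "z")]),
               as.matrix(interface$side_b[interface$side_b$has_ca,
                                          c("x", "y", "z")]))
  if (nrow(xyz) < 3L) stop("planarity needs at least 3 interfacial C-alpha")
  xc <- sweep(xyz, 2L, colMeans(xyz))
  sv <- svd(xc)
  normal <- sv$v[, 3L]
  sqrt(mean((xc %*% normal)^2))
}

#' Write interface tables to TSV
#'
#' Dumps the residue sides and the contact map of one interface in a plain
#' text, round-trippable form for downstream alignment tools.
#'
#' @param interface a `domain_interface`.
#' @param file path of the TSV to write.
#' @return Invisibly, the file path.
#' @export
write_interface_tsv <- function(interface, file) {
  sa <- cbind(side = "A", interface$side_a)
  sb <- cbind(side = "B", interface$side_b)
  res <- rbind(sa, sb)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# pair_id\t%s\tL\t%d", interface$pair_id, interface$L),
             con)
  writeLines("# residues", con)
  write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# contacts", con)
  write.table(interface$contacts, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
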