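# Shared fixtures and independent oracles for the test suite. Expensive
# generated objects are built once per test run and cached.

.fix_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- force(expr)
  .fix_env[[name]]
}

# -- hand-built PDB text ----------------------------------------------------

# minimal PDB ATOM record formatter for fixture text
pdb_atom_line <- function(serial, elety, resname, chain, resno, x, y, z,
                          element = substr(elety, 1, 1), occ = 1, b = 0) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, elety, resname, chain, resno, x, y, z, occ, b, element)
}

# a toy chain: one CA (and optionally more atoms) per residue at spaced
# positions along x, with the given author numbering
pdb_chain_text <- function(resno, chain = "A", extra_atoms = NULL,
                           remark465 = integer()) {
  lines <- character()
  for (num in remark465)
    lines <- c(lines, sprintf("REMARK 465   GLY %s %5d", chain, num))
  serial <- 0L
  for (i in seq_along(resno)) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", chain, resno[i],
                                    i * 3.8, 0, 0))
  }
  if (!is.null(extra_atoms)) {
    for (r in seq_len(nrow(extra_atoms))) {
      serial <- serial + 1L
      ea <- extra_atoms[r, ]
      lines <- c(lines, pdb_atom_line(serial, ea$elety, "GLY", chain,
                                      ea$resno, ea$x, ea$y, ea$z,
                                      element = ea$element))
    }
  }
  c(lines, "END")
}

# -- hand-built domain/interface objects ------------------------------------

# fabricate a domain_instance with explicit atoms (data frame with columns
# elety, element, x, y, z and one row group per residue index `res`)
toy_domain <- function(entry_id, number, resno, atoms = NULL,
                       fold_label = "t.1.1", aa = NULL, segments = NULL) {
  n <- length(resno)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(atoms)) {
    atoms <- data.frame(res = seq_len(n), elety = "CA", element = "C",
                        x = seq_len(n) * 3.8, y = 0, z = 0)
  }
  if (is.null(segments)) segments <- data.frame(start = min(resno),
                                               end = max(resno))
  ca_rows <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- as.matrix(ca_rows[, c("x", "y", "z")])
  def <- domain_definition(entry_id, number, segments, fold_label)
  # chain-level ordinals follow the author numbering so fabricated domains
  # of one entry never share ordinals
  residues <- data.frame(ord = resno, resno = resno, ins = "", aa = aa,
                         has_ca = seq_len(n) %in% ca_rows$res,
                         ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
                         stringsAsFactors = FALSE)
  residues$ca_x[ca_rows$res] <- ca_rows$x
  residues$ca_y[ca_rows$res] <- ca_rows$y
  residues$ca_z[ca_rows$res] <- ca_rows$z
  structure(list(
    definition = def, entry_id = entry_id, domain_number = as.integer(number),
    ord = resno, sequence = paste(aa, collapse = ""),
    cluster_sequence = paste(aa, collapse = ""),
    length = n, residues = residues,
    ca = ca[order(ca_rows$res), , drop = FALSE],
    ca_ord = resno[ca_rows$res[order(ca_rows$res)]],
    atoms = data.frame(ord = resno[atoms$res], elety = atoms$elety,
                       element = atoms$element, is_heavy =
                         toupper(atoms$element) != "H",
                       x = atoms$x, y = atoms$y, z = atoms$z,
                       stringsAsFactors = FALSE),
    fold_label = fold_label, resolution = 2.0
  ), class = "domain_instance")
}

# fabricate a domain_interface directly from side C-alpha coordinates and a
# contact list (rows: index into side_a, index into side_b)
toy_interface <- function(xa, xb, contacts, id = "toy") {
  side <- function(x, off) data.frame(
    ord = off + seq_len(nrow(x)), resno = off + seq_len(nrow(x)), aa = "A",
    x = x[, 1], y = x[, 2], z = x[, 3], has_ca = TRUE, n_contacts = 0L)
  sa <- side(xa, 0L); sb <- side(xb, 1000L)
  ct <- data.frame(ia = contacts[, 1], ib = contacts[, 2],
                   ord_a = sa$ord[contacts[, 1]],
                   ord_b = sb$ord[contacts[, 2]], min_dist = 4.0)
  sa$n_contacts <- as.integer(tabulate(ct$ia, nrow(sa)))
  sb$n_contacts <- as.integer(tabulate(ct$ib, nrow(sb)))
  structure(list(pair_id = id, entry_a = id, number_a = 1L,
                 entry_b = id, number_b = 2L, side_a = sa, side_b = sb,
                 contacts = ct, L = nrow(sa) + nrow(sb),
                 n_contacts_total = nrow(ct), cutoff = 4.5),
            class = "domain_interface")
}

# a random rigid transform applied to an interface
transform_interface <- function(ifc, R, tvec) {
  tr <- function(s) {
    x <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
    s$x <- x[, 1] + tvec[1]; s$y <- x[, 2] + tvec[2]; s$z <- x[, 3] + tvec[3]
    s
  }
  ifc$side_a <- tr(ifc$side_a); ifc$side_b <- tr(ifc$side_b)
  ifc
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# -- cached generated fixtures ----------------------------------------------

fix_pair <- function() cached("pair", make_domain_pair("FIX1", seed = 3))
fix_pair2 <- function() cached("pair2", make_domain_pair(
  "FIX2", style_a = "mixed", style_b = "helix-bundle", seed = 4,
  fold_a = "4.10.1", fold_b = "5.20.1"))
fix_helix <- function() cached("helix",
  make_idealized_domain("helix-bundle", 60, seed = 7))
fix_sandwich <- function() cached("sandwich",
  make_idealized_domain("beta-sandwich", 80, seed = 8))

# -- independent oracles ----------------------------------------------------

# planarity by direct numerical minimisation over plane parameters
planarity_oracle <- function(xyz) {
  rms_for <- function(p) {
    n <- c(cos(p[1]) * cos(p[2]), cos(p[1]) * sin(p[2]), sin(p[1]))
    d <- xyz %*% n - p[3]
    sqrt(mean(d^2))
  }
  best <- Inf
  for (s1 in seq(-1.4, 1.4, length.out = 6))
    for (s2 in seq(0, pi, length.out = 6)) {
      o <- stats::optim(c(s1, s2, mean(xyz %*% c(cos(s1) * cos(s2),
                                                 cos(s1) * sin(s2),
                                                 sin(s1)))),
                        rms_for, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      best <- min(best, o$value)
    }
  best
}

# all-pairs double-loop contact oracle over two atom tables
contacts_oracle <- function(atA, atB, cutoff) {
  atA <- atA[atA$is_heavy, ]; atB <- atB[atB$is_heavy, ]
  out <- list()
  for (oa in unique(atA$ord)) for (ob in unique(atB$ord)) {
    xa <- as.matrix(atA[atA$ord == oa, c("x", "y", "z")])
    xb <- as.matrix(atB[atB$ord == ob, c("x", "y", "z")])
    md <- Inf
    for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb)))
      md <- min(md, sqrt(sum((xa[i, ] - xb[j, ])^2)))
    if (md <= cutoff)
      out[[length(out) + 1L]] <- data.frame(ord_a = oa, ord_b = ob,
                                            min_dist = md)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) data.frame(ord_a = integer(), ord_b = integer(),
                              min_dist = numeric())
  else df[order(df$ord_a, df$ord_b), ]
}

# reachability within k steps by boolean matrix powers
reach_oracle <- function(adj, k) {
  n <- nrow(adj)
  reach <- adj > 0
  acc <- reach
  p <- reach
  if (k >= 2) for (i in 2:k) {
    p <- (p %*% (adj > 0)) > 0
    acc <- acc | p
  }
  diag(acc) <- FALSE
  acc
}

# strongly connected component sizes by brute-force mutual reachability
scc_oracle <- function(adj) {
  n <- nrow(adj)
  r <- reach_oracle(adj, n)
  diag(r) <- TRUE
  mutual <- r & t(r)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[mutual[i, ] & mutual[, i]] <- cid
  }
  tabulate(comp)
}

# exhaustive interface-alignment oracle: enumerate both domain pairings and
# all per-side injective assignments; score each full matching with the
# IS-score formula under the Kabsch superposition of its own pairs
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

injections_oracle <- function(n, k) {
  # ordered selections of k out of n
  if (k == n) return(perms_oracle(n))
  out <- list()
  subsets <- combn(n, k)
  for (s in seq_len(ncol(subsets))) for (p in perms_oracle(k))
    out[[length(out) + 1L]] <- subsets[, s][p]
  out
}

align_oracle <- function(query, template, d0_floor = 0.5) {
  LQ <- query$L
  d0 <- d0_scale(LQ, "non-sequential", d0_floor)
  s0 <- s0_norm(LQ)
  qa <- as.matrix(query$side_a[, c("x", "y", "z")])
  qb <- as.matrix(query$side_b[, c("x", "y", "z")])
  qc <- query$contacts
  bq_a <- query$side_a$n_contacts; bq_b <- query$side_b$n_contacts
  best <- -Inf
  for (pairing in 1:2) {
    ta <- if (pairing == 1) template$side_a else template$side_b
    tb <- if (pairing == 1) template$side_b else template$side_a
    xta <- as.matrix(ta[, c("x", "y", "z")])
    xtb <- as.matrix(tb[, c("x", "y", "z")])
    tc <- template$contacts
    tkey <- if (pairing == 1) paste(tc$ia, tc$ib) else paste(tc$ib, tc$ia)
    side_maps <- function(nq, nt) {
      if (nq <= nt) lapply(injections_oracle(nt, nq),
                           function(j) cbind(seq_len(nq), j))
      else lapply(injections_oracle(nq, nt),
                  function(j) cbind(j, seq_len(nt)))
    }
    mA <- side_maps(nrow(qa), nrow(xta))
    mB <- side_maps(nrow(qb), nrow(xtb))
    for (ma in mA) for (mb in mB) {
      np <- nrow(ma) + nrow(mb)
      if (np < 3) next
      X <- rbind(xta[ma[, 2], , drop = FALSE], xtb[mb[, 2], , drop = FALSE])
      Y <- rbind(qa[ma[, 1], , drop = FALSE], qb[mb[, 1], , drop = FALSE])
      k <- tryCatch(kabsch_superpose(Y, X), error = function(e) NULL)
      if (is.null(k)) next
      Xt <- X %*% t(k$rotation) + matrix(k$translation, np, 3, byrow = TRUE)
      di2 <- rowSums((Xt - Y)^2)
      mapA <- rep(NA_integer_, nrow(qa)); mapA[ma[, 1]] <- ma[, 2]
      mapB <- rep(NA_integer_, nrow(qb)); mapB[mb[, 1]] <- mb[, 2]
      pres <- !is.na(mapA[qc$ia]) & !is.na(mapB[qc$ib]) &
        paste(mapA[qc$ia], mapB[qc$ib]) %in% tkey
      cA <- tabulate(qc$ia[pres], nrow(qa))
      cB <- tabulate(qc$ib[pres], nrow(qb))
      fi <- c((cA[ma[, 1]] / ta$n_contacts[ma[, 2]] +
                 cA[ma[, 1]] / bq_a[ma[, 1]]) / 2,
              (cB[mb[, 1]] / tb$n_contacts[mb[, 2]] +
                 cB[mb[, 1]] / bq_b[mb[, 1]]) / 2)
      S <- sum(fi / (1 + di2 / d0^2)) / LQ
      best <- max(best, S)
    }
  }
  (best + s0) / (1 + s0)
}

# gapless-threading TM oracle: best offset alignment, Kabsch, one score
tm_gapless_oracle <- function(A, B, d0_floor = 0.5) {
  n <- nrow(A); m <- nrow(B)
  lmin <- min(15, n, m)
  best <- 0
  for (Lnorm in c(n, m)) {
    d0 <- d0_scale(Lnorm, "sequential", d0_floor)
    for (off in (-(m - lmin)):(n - lmin)) {
      i <- seq_len(n); j <- i - off
      keep <- j >= 1 & j <= m
      if (sum(keep) < 3) next
      X <- B[j[keep], , drop = FALSE]; Y <- A[keep, , drop = FALSE]
      k <- tryCatch(kabsch_superpose(Y, X), error = function(e) NULL)
      if (is.null(k)) next
      Xt <- X %*% t(k$rotation) +
        matrix(k$translation, nrow(X), 3, byrow = TRUE)
      tm <- sum(1 / (1 + rowSums((Xt - Y)^2) / d0^2)) / Lnorm
      best <- max(best, tm)
    }
  }
  best
}

# brute-force non-redundant selection oracle following the cluster-pair
# description directly (independent implementation)
nonredundant_oracle <- function(clusters, records) {
  cl_of <- function(e, d) {
    for (cl in clusters)
      if (any(cl$members$entry_id == e & cl$members$domain_number == d))
        return(cl$cluster_id)
    stop("unclustered")
  }
  info <- lapply(records, function(r) list(
    e = r$entry_id, na = r$domain_a$domain_number,
    nb = r$domain_b$domain_number, res = r$resolution,
    len = r$total_length))
  sel <- integer()
  N <- length(clusters)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i >= j) next
    for (dir in c("fwd", "rev")) {
      hits <- which(vapply(info, function(x) {
        ca <- cl_of(x$e, x$na); cb <- cl_of(x$e, x$nb)
        x$na != x$nb &&
          ((dir == "fwd" && ca == i && cb == j) ||
             (dir == "rev" && ca == j && cb == i))
      }, TRUE))
      if (length(hits) == 0L) next
      hi <- info[hits]
      o <- order(vapply(hi, function(x) x$res, 1),
                 -vapply(hi, function(x) x$len, 1),
                 vapply(hi, function(x) x$e, ""))
      sel <- c(sel, hits[o[1L]])
    }
  }
  sort(unique(sel))
}

# lightweight domain_pair_record for dataset bookkeeping tests: fabricated
# interface, explicit resolution/length/folds/sequences
toy_record <- function(entry, na = 1L, nb = 2L, res = 2.0, len = 100L,
                       seq_a = strrep("A", 30), seq_b = strrep("C", 30),
                       fold_a = "1.10.8", fold_b = "2.60.9",
                       dom_a = NULL, dom_b = NULL) {
  if (is.null(dom_a)) {
    dom_a <- toy_domain(entry, na, seq_len(nchar(seq_a)),
                        aa = strsplit(seq_a, "")[[1]], fold_label = fold_a)
  }
  if (is.null(dom_b)) {
    dom_b <- toy_domain(entry, nb, 500L + seq_len(nchar(seq_b)),
                        aa = strsplit(seq_b, "")[[1]], fold_label = fold_b)
  }
  dom_a$resolution <- res; dom_b$resolution <- res
  ifc <- toy_interface(matrix(rnorm(30), 10), matrix(rnorm(30), 10) + 6,
                       cbind(1:10, 1:10), paste0(entry, ":", na, "-", nb))
  ifc$entry_a <- entry; ifc$number_a <- as.integer(na)
  ifc$entry_b <- entry; ifc$number_b <- as.integer(nb)
  structure(list(record_id = ifc$pair_id, entry_id = entry,
                 domain_a = dom_a, domain_b = dom_b, pair_class = "CC-2",
                 interface = ifc, resolution = res,
                 total_length = as.integer(len)),
            class = "domain_pair_record")
}

# random clustered toy instance for non-redundant selection oracle tests
random_nr_instance <- function(n_clusters, n_records, seed) {
  set.seed(seed)
  clusters <- lapply(seq_len(n_clusters), function(i)
    list(cluster_id = i,
         members = data.frame(entry_id = character(),
                              domain_number = integer()),
         representative = NULL))
  records <- list()
  for (r in seq_len(n_records)) {
    e <- sprintf("P%02d", r)
    ci <- sample(n_clusters, 2L)
    rec <- toy_record(e, 1L, 2L, res = round(runif(1, 1.5, 2.5), 2),
                      len = sample(80:300, 1L))
    records[[r]] <- rec
    clusters[[ci[1]]]$members <- rbind(
      clusters[[ci[1]]]$members,
      data.frame(entry_id = e, domain_number = 1L))
    clusters[[ci[2]]]$members <- rbind(
      clusters[[ci[2]]]$members,
      data.frame(entry_id = e, domain_number = 2L))
  }
  clusters <- Filter(function(cl) nrow(cl$members) > 0L, clusters)
  for (k in seq_along(clusters)) {
    clusters[[k]]$cluster_id <- k
    clusters[[k]]$representative <- clusters[[k]]$members[1L, ]
  }
  list(clusters = clusters, records = records)
}
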