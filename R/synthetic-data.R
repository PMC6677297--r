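# Synthetic multidomain structure generator: idealized secondary-structure
# domains, rigid placement of domain pairs with controllable interface
# size, planted interface similarity across unrelated domain contexts,
# inter-domain linkers with missing residues, discontinuous domains and
# sequence families. Everything is deterministic under a fixed seed.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# evaluate expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.unit <- function(v) v / sqrt(sum(v^2))

.random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# interior points of a circular arc from p0 to p1 with uniform chord length
# `spacing`; the arc bulges along direction `bow`
.arc_points <- function(p0, p1, n_pts, spacing = 3.8, bow = c(0, 0, 1)) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (n_pts <= 0L) return(matrix(numeric(), 0L, 3L))
  D <- sqrt(sum((p1 - p0)^2))
  m <- n_pts + 1L
  if (D >= spacing * m - 1e-9) {
    # too far for an arc at this spacing: evenly spaced straight line
    tt <- seq_len(n_pts) / m
    return(outer(tt, p1 - p0) + matrix(p0, n_pts, 3, byrow = TRUE))
  }
  u <- .unit(p1 - p0)
  w <- bow - sum(bow * u) * u
  if (sqrt(sum(w^2)) < 1e-6) {
    w <- c(1, 0, 0) - u[1] * u
    if (sqrt(sum(w^2)) < 1e-6) w <- c(0, 1, 0) - u[2] * u
  }
  w <- .unit(w)
  f <- function(phi) sin(phi / 2) / sin(phi / (2 * m)) - D / spacing
  phi <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-6))$root
  r <- D / (2 * sin(phi / 2))
  centre <- (p0 + p1) / 2 - w * (r * cos(phi / 2))
  # p0 sits at angle pi/2 + phi/2 and p1 at pi/2 - phi/2 in the (u, w)
  # frame of the circle; sweep the arc between them
  ang <- pi / 2 + phi / 2 - phi * seq_len(n_pts) / m
  t(vapply(ang, function(a) centre + r * (cos(a) * u + sin(a) * w),
           numeric(3)))
}

# idealized C-alpha trace for one domain; returns list(ca, elements)
.ideal_ca <- function(style, n_res, jitter = 0.15) {
  helix <- function(len, x0, up) {
    j <- seq_len(len) - 1
    z <- 1.5 * j
    if (!up) z <- max(z) - z
    cbind(x0 + 2.3 * cos(j * 100 * pi / 180),
          2.3 * sin(j * 100 * pi / 180), z)
  }
  strand <- function(len, x0, y0, up) {
    j <- seq_len(len) - 1
    z <- 3.3 * j
    if (!up) z <- max(z) - z
    cbind(rep(x0, len), y0 + 0.943 * ((j %% 2) * 2 - 1), z)
  }
  build <- function(makers, loop_len = 3L) {
    ca <- NULL
    elements <- data.frame(type = character(), start = integer(),
                           end = integer())
    for (i in seq_along(makers)) {
      seg <- makers[[i]]$xyz
      if (!is.null(ca)) {
        # loops bulge beyond the z-extreme they connect at, away from the
        # element bodies
        prev <- makers[[i - 1L]]$xyz
        at_top <- ca[nrow(ca), 3L] >= mean(prev[, 3L])
        bow <- c(0, 0.3, if (at_top) 1 else -1)
        lp <- .arc_points(ca[nrow(ca), ], seg[1L, ], loop_len, bow = bow)
        ca <- rbind(ca, lp)
      }
      elements <- rbind(elements, data.frame(
        type = makers[[i]]$type, start = nrow(ca %||% matrix(0, 0, 3)) + 1L,
        end = nrow(ca %||% matrix(0, 0, 3)) + nrow(seg)))
      ca <- rbind(ca, seg)
    }
    list(ca = ca, elements = elements)
  }
  loop_len <- 3L
  if (style == "helix-bundle") {
    loop_len <- 4L
    n_h <- max(2L, round(n_res / 21))
    body <- n_res - (n_h - 1L) * loop_len
    lens <- rep(body %/% n_h, n_h)
    lens[seq_len(body %% n_h)] <- lens[seq_len(body %% n_h)] + 1L
    makers <- lapply(seq_len(n_h), function(i) list(
      xyz = helix(lens[i], (i - 1) * 10.5, i %% 2 == 1L),
      type = "helix", bow = c(0, 1, if (i %% 2 == 1L) 1 else -1)))
  } else if (style == "beta-sandwich") {
    n_s <- if (n_res >= 70) 8L else 6L
    loop_len <- 2L
    body <- n_res - (n_s - 1L) * loop_len
    lens <- rep(body %/% n_s, n_s)
    lens[seq_len(body %% n_s)] <- lens[seq_len(body %% n_s)] + 1L
    half <- n_s %/% 2L
    makers <- lapply(seq_len(n_s), function(i) {
      sheet <- if (i <= half) 0 else 1
      col <- if (sheet == 0) i else n_s + 1L - i  # return path on sheet 2
      list(xyz = strand(lens[i], (col - 1) * 4.8 + sheet * 2.4,
                        sheet * 9.5, i %% 2 == 1L),
           type = "strand", bow = c(0, if (sheet == 0) -1 else 1, 0))
    })
  } else if (style == "mixed") {
    n_h <- 2L
    n_s <- 3L
    body <- n_res - (n_h + n_s - 1L) * loop_len
    hl <- round(body * 0.55 / n_h)
    sl <- (body - hl * n_h) %/% n_s
    extra <- body - hl * n_h - sl * n_s
    makers <- list(
      list(xyz = helix(hl, 0, TRUE), type = "helix", bow = c(0, 1, 1)),
      list(xyz = strand(sl + extra, 10, 4, FALSE), type = "strand",
           bow = c(0, -1, 0)),
      list(xyz = strand(sl, 14.8, 4, TRUE), type = "strand",
           bow = c(0, -1, 0)),
      list(xyz = strand(sl, 19.6, 4, FALSE), type = "strand",
           bow = c(0, -1, 0)),
      list(xyz = helix(hl, 26, TRUE), type = "helix", bow = c(0, 1, 1)))
  } else stop("unknown style: ", style)
  out <- build(makers, loop_len)
  if (jitter > 0)
    out$ca <- out$ca + matrix(rnorm(length(out$ca), sd = jitter),
                              nrow(out$ca))
  out$ca <- sweep(out$ca, 2L, colMeans(out$ca))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pseudo-backbone heavy atoms (N, CA, C, O, CB) around a C-alpha trace
.backbone_atoms <- function(ca) {
  n <- nrow(ca)
  rows <- list()
  add <- function(ord, elety, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      ord = ord, elety = elety, element = substr(elety, 1, 1),
      is_heavy = TRUE, x = p[1], y = p[2], z = p[3])
  for (j in seq_len(n)) {
    p <- ca[j, ]
    add(j, "CA", p)
    u_prev <- if (j > 1L) .unit(ca[j - 1L, ] - p) else NULL
    u_next <- if (j < n) .unit(ca[j + 1L, ] - p) else NULL
    if (!is.null(u_prev)) add(j, "N", p + 1.0 * u_prev)
    if (!is.null(u_next)) add(j, "C", p + 1.0 * u_next)
    bis <- if (!is.null(u_prev) && !is.null(u_next)) -(u_prev + u_next)
           else if (!is.null(u_next)) -u_next else -u_prev
    if (sqrt(sum(bis^2)) > 1e-6) add(j, "CB", p + 1.5 * .unit(bis))
  }
  do.call(rbind, rows)
}

# remove pseudo-CB atoms involved in non-local clashes (the C-alpha trace
# itself is kept clash-free by construction; CB decorations occasionally
# collide in tightly packed cores)
.prune_cb <- function(atoms, threshold = 2.5, protect_ord = integer()) {
  repeat {
    at <- atoms[atoms$is_heavy, , drop = FALSE]
    x <- as.matrix(at[, c("x", "y", "z")])
    d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * (x %*% t(x))
    d2[abs(outer(at$ord, at$ord, "-")) <= 1L] <- Inf
    diag(d2) <- Inf
    bad <- which(d2 < threshold^2, arr.ind = TRUE)
    if (nrow(bad) == 0L) return(atoms)
    inv <- unique(as.vector(bad))
    # drop unprotected decorations (e.g. linker pseudo-atoms) first, then
    # clashing CBs; C-alphas are never dropped
    unprot <- inv[!(at$ord[inv] %in% protect_ord) & at$elety[inv] != "CA"]
    drop <- if (length(unprot) > 0L) unprot
            else inv[at$elety[inv] == "CB" & !(at$ord[inv] %in% protect_ord)]
    if (length(drop) == 0L) return(atoms)
    key <- paste(at$ord[drop], at$elety[drop])
    atoms <- atoms[!(paste(atoms$ord, atoms$elety) %in% key), , drop = FALSE]
  }
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
.rot_align <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-9) {
    if (cth > 0) return(diag(3))
    p <- .unit(if (abs(a[1]) < 0.9) c(1, 0, 0) - a[1] * a
               else c(0, 1, 0) - a[2] * a)
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

.rot_about <- function(axis, angle) {
  a <- .unit(axis)
  vx <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3,
               byrow = TRUE)
  diag(3) * cos(angle) + sin(angle) * vx + (1 - cos(angle)) * outer(a, a)
}

.smallest_axis <- function(ca) svd(sweep(ca, 2L, colMeans(ca)))$v[, 3L]

# linker path from p0 to p1 bowing away from the complex centroid, with
# spacing stretched when the endpoints are far apart
.linker_arc <- function(p0, p1, n_pts, centroid) {
  if (n_pts <= 0L) return(matrix(numeric(), 0L, 3L))
  D <- sqrt(sum((p1 - p0)^2))
  spacing <- max(3.8, 1.25 * D / (n_pts + 1L))
  bow <- (p0 + p1) / 2 - centroid
  if (sqrt(sum(bow^2)) < 1e-6) bow <- c(0, 0, 1)
  .arc_points(p0, p1, n_pts, spacing = spacing, bow = .unit(bow))
}

# Pseudo side-chain atom pairs bridging near-contact residue pairs across
# an interface, used to grow the interface to a target size that rigid
# placement of idealized bodies cannot reach on its own. Each accepted
# bridge adds one atom to each residue, 3.9 A apart on the line joining
# their C-alphas, clash-checked against everything already present.
.bridge_pairs <- function(atA, atB, cutoff, target_L) {
  ct <- .residue_contacts(atA, atB, cutoff)
  SA <- unique(ct$ord_a); SB <- unique(ct$ord_b)
  caA <- atA[atA$elety == "CA", ]
  caB <- atB[atB$elety == "CA", ]
  xa <- as.matrix(caA[, c("x", "y", "z")])
  xb <- as.matrix(caB[, c("x", "y", "z")])
  D <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * (xa %*% t(xb)))
  cand <- which(D > cutoff + 1.5 & D < 13, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(NULL)
  new_a <- !(caA$ord[cand[, 1L]] %in% SA)
  new_b <- !(caB$ord[cand[, 2L]] %in% SB)
  gain <- new_a + new_b
  o <- order(-gain, D[cand])
  cand <- cand[o, , drop = FALSE]
  ha <- atA[atA$is_heavy, , drop = FALSE]
  hb <- atB[atB$is_heavy, , drop = FALSE]
  hx <- as.matrix(rbind(ha[, c("x", "y", "z")], hb[, c("x", "y", "z")]))
  # owner key so a bridge atom may sit close to its own residue
  howner <- c(paste0("A", ha$ord), paste0("B", hb$ord))
  atoms <- list()
  L <- length(SA) + length(SB)
  for (k in seq_len(nrow(cand))) {
    if (L >= 0.9 * target_L) break
    i <- cand[k, 1L]; j <- cand[k, 2L]
    oa <- caA$ord[i]; ob <- caB$ord[j]
    if (oa %in% SA && ob %in% SB) next
    pa <- xa[i, ]; pb <- xb[j, ]
    m <- (pa + pb) / 2
    # one atom per residue, 3.9 A apart on the joining line
    q1 <- m + 1.95 * .unit(pa - m)
    q2 <- m + 1.95 * .unit(pb - m)
    # clash check against all heavy atoms except the parent residue's own
    ok <- TRUE
    for (side in 1:2) {
      q <- if (side == 1L) q1 else q2
      own <- if (side == 1L) paste0("A", oa) else paste0("B", ob)
      dq <- rowSums(sweep(hx, 2L, q)^2)
      dq[howner == own] <- Inf
      if (sqrt(min(dq)) < 2.6) { ok <- FALSE; break }
    }
    if (!ok) next
    hx <- rbind(hx, q1, q2)
    howner <- c(howner, paste0("A", oa), paste0("B", ob))
    atoms[[length(atoms) + 1L]] <- data.frame(
      side = c(1L, 2L), res = c(oa, ob),
      x = c(q1[1], q2[1]), y = c(q1[2], q2[2]), z = c(q1[3], q2[3]))
    if (!(oa %in% SA)) { SA <- c(SA, oa); L <- L + 1L }
    if (!(ob %in% SB)) { SB <- c(SB, ob); L <- L + 1L }
  }
  if (L < 0.9 * target_L) return(NULL)
  list(atoms = do.call(rbind, atoms), L = L)
}

# minimum heavy-atom distance between two atom tables
.min_heavy_dist <- function(atA, atB) {
  xa <- as.matrix(atA[atA$is_heavy, c("x", "y", "z")])
  xb <- as.matrix(atB[atB$is_heavy, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * (xa %*% t(xb))
  sqrt(max(0, min(d2)))
}

# heavy-atom self-clash check, ignoring chain neighbours (|delta ord| <= 1)
.self_clash <- function(atoms, threshold = 2.5) {
  at <- atoms[atoms$is_heavy, , drop = FALSE]
  x <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * (x %*% t(x))
  near <- abs(outer(at$ord, at$ord, "-")) <= 1L
  d2[near] <- Inf
  min(d2) < threshold^2
}

# assemble a chain_structure from a C-alpha trace, sequence and numbering
.assemble_chain <- function(entry_id, ca, seq, resno, chain_id = "A",
                            extra_atoms = NULL, resolution = NA_real_,
                            protect_ord = integer()) {
  n <- nrow(ca)
  stopifnot(length(resno) == n, nchar(seq) == n)
  atoms <- .prune_cb(.backbone_atoms(ca), protect_ord = protect_ord)
  if (!is.null(extra_atoms) && nrow(extra_atoms) > 0L)
    atoms <- rbind(atoms, data.frame(
      ord = extra_atoms$ord, elety = extra_atoms$elety,
      element = substr(extra_atoms$elety, 1, 1), is_heavy = TRUE,
      x = extra_atoms$x, y = extra_atoms$y, z = extra_atoms$z))
  atoms <- atoms[order(atoms$ord), , drop = FALSE]
  rownames(atoms) <- NULL
  residues <- data.frame(
    ord = seq_len(n), resno = as.integer(resno), ins = "",
    aa = strsplit(seq, "")[[1]], has_ca = TRUE,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    stringsAsFactors = FALSE)
  structure(list(entry_id = entry_id, chain_id = chain_id,
                 residues = residues, atoms = atoms,
                 missing_ranges = .numbering_gaps(residues$resno),
                 domains = list(), resolution = resolution),
            class = "chain_structure")
}

#' Generate an idealized single domain
#'
#' Builds a self-avoiding C-alpha trace from ideal secondary-structure
#' geometry (helix rise 1.5 Angstrom/residue at 100 degrees/residue twist;
#' strand rise 3.3 Angstrom with backbone zigzag; uniformly spaced loop
#' arcs), decorates it with pseudo-backbone heavy atoms (N, CA, C, CB) and
#' a random sequence, and returns it as a `domain_instance`. The element
#' layout is attached as the `elements` field.
#'
#' @param style `"helix-bundle"`, `"beta-sandwich"` or `"mixed"`.
#' @param n_res residue count, >= 30.
#' @param seed RNG seed (sequence and coordinate jitter).
#' @param fold_label classification label given to the domain.
#' @param jitter coordinate jitter standard deviation in Angstrom.
#' @return A `domain_instance` with an `elements` data frame.
#' @export
make_idealized_domain <- function(style, n_res, seed,
                                  fold_label = paste0("syn.", style),
                                  jitter = 0.15) {
  stopifnot(n_res >= 30L)
  .with_seed(seed, {
    for (try in 1:5) {
      tr <- .ideal_ca(style, n_res, jitter)
      seq <- paste(sample(AA20, n_res, replace = TRUE), collapse = "")
      chain <- .assemble_chain(paste0("dom_", style), tr$ca, seq,
                               seq_len(n_res))
      if (!.self_clash(chain$atoms)) {
        chain <- apply_domain_definitions(chain, domain_definition(
          chain$entry_id, 1L, data.frame(start = 1L, end = n_res),
          fold_label))
        d <- chain$domains[[1L]]
        d$elements <- tr$elements
        return(d)
      }
    }
    stop("could not build a clash-free ", style, " domain of ", n_res,
         " residues")
  })
}

# transform helper for atom tables
.transform_atoms <- function(at, R, t) {
  x <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- x[, 1] + t[1]; at$y <- x[, 2] + t[2]; at$z <- x[, 3] + t[3]
  at
}

#' Generate a two-domain chain with a controlled interface
#'
#' Builds two idealized domains, places the second against the first by
#' random rigid placement with a slide-until-contact line search until the
#' interface size L (interfacial residues, both sides) lies within 10% of
#' `target_L`, and assembles the chain with an inter-domain linker.
#' Optionally part of the linker is left unresolved (a numbering gap, also
#' emitted as REMARK 465 on PDB export), and optionally the first domain is
#' made discontinuous by inserting the second domain into its sequence.
#'
#' @param entry_id entry identifier.
#' @param style_a,style_b domain styles (see [make_idealized_domain()]).
#' @param n_a,n_b domain residue counts.
#' @param target_L target interfacial residue count.
#' @param linker_length linker span in residues (by numbering).
#' @param missing_gap how many central linker positions are unresolved
#'   (0 <= missing_gap <= linker_length).
#' @param discontinuous `NULL` or `list(longest_fraction = f)`: make domain
#'   A discontinuous by inserting domain B after a fraction `f` of A.
#' @param seed RNG seed.
#' @param fold_a,fold_b fold labels.
#' @param resolution pseudo-resolution in Angstrom (default drawn from
#'   U(1.5, 2.4)).
#' @param params a [ddi_params()] object (contact cutoff).
#' @param sequence_a,sequence_b optional fixed domain sequences.
#' @return List with `chain` (a `chain_structure` with both domains
#'   applied), `interface` (the built `domain_interface`), and `truth`
#'   (placement metadata: achieved L, linker/missing annotation, segment
#'   layout).
#' @export
make_domain_pair <- function(entry_id, style_a = "helix-bundle",
                             style_b = "beta-sandwich", n_a = 60L,
                             n_b = 60L, target_L = 24L, linker_length = 4L,
                             missing_gap = 0L, discontinuous = NULL,
                             seed = 1L, fold_a = "1.10.1", fold_b = "2.60.1",
                             resolution = NULL, params = ddi_params(),
                             sequence_a = NULL, sequence_b = NULL) {
  stopifnot(missing_gap >= 0L, missing_gap <= linker_length)
  .with_seed(seed, {
    trA <- .ideal_ca(style_a, n_a)
    trB <- .ideal_ca(style_b, n_b)
    atA <- .prune_cb(.backbone_atoms(trA$ca))
    seqA <- sequence_a %||% paste(sample(AA20, n_a, replace = TRUE),
                                  collapse = "")
    seqB <- sequence_b %||% paste(sample(AA20, n_b, replace = TRUE),
                                  collapse = "")
    if (is.null(resolution)) resolution <- round(runif(1, 1.5, 2.4), 2)

    placed <- NULL
    uA <- .smallest_axis(trA$ca)
    axB <- .smallest_axis(trB$ca)
    for (try in 1:80) {
      # face-to-face placement: approach along the flattest direction of A
      # (with random tilt), presenting B's flattest face, random spin
      u <- .unit(sample(c(1, -1), 1L) * uA + rnorm(3, sd = 0.2))
      R <- .rot_about(u, runif(1, 0, 2 * pi)) %*%
        .rot_align(sample(c(1, -1), 1L) * axB, -u)
      caB0 <- trB$ca %*% t(R)
      atB0 <- .prune_cb(.backbone_atoms(caB0))
      rA <- max(sqrt(rowSums(trA$ca^2)))
      rB <- max(sqrt(rowSums(caB0^2)))
      shift <- function(d) {
        at <- atB0
        at$x <- at$x + d * u[1]; at$y <- at$y + d * u[2]
        at$z <- at$z + d * u[3]
        at
      }
      # slide inward to the closest non-clashing separation
      lo <- 0; hi <- rA + rB + 5
      if (.min_heavy_dist(atA, shift(hi)) < 2.6) next
      while (hi - lo > 0.1) {
        mid <- (lo + hi) / 2
        if (.min_heavy_dist(atA, shift(mid)) < 2.6) lo <- mid else hi <- mid
      }
      d_touch <- hi
      L_at <- function(d) {
        ct <- .residue_contacts(atA, shift(d), params$contact_cutoff)
        length(unique(ct$ord_a)) + length(unique(ct$ord_b))
      }
      L_touch <- L_at(d_touch)
      if (L_touch >= 0.9 * target_L) {
        d <- d_touch
        repeat {
          L <- L_at(d)
          if (L <= 1.1 * target_L) break
          d <- d + 0.25
          if (d > d_touch + 15) break
        }
        L <- L_at(d)
        if (L >= 0.9 * target_L && L <= 1.1 * target_L) {
          placed <- list(d = d, R = R, u = u, L = L, bridges = NULL)
          break
        }
      } else if (L_touch >= max(10L, round(0.3 * target_L))) {
        # grow the interface with bridging pseudo side-chain atoms
        br <- .bridge_pairs(atA, shift(d_touch), params$contact_cutoff,
                            target_L)
        if (!is.null(br)) {
          placed <- list(d = d_touch, R = R, u = u, L = br$L,
                         bridges = br$atoms)
          break
        }
      }
    }
    if (is.null(placed))
      stop("placement search failed for target_L = ", target_L)
    caB <- caB0 + matrix(placed$d * u, n_b, 3, byrow = TRUE)

    # chain assembly
    n_link_res <- linker_length - missing_gap
    if (is.null(discontinuous)) {
      cen_all <- colMeans(rbind(trA$ca, caB))
      link_ca <- .linker_arc(trA$ca[n_a, ], caB[1L, ], linker_length,
                             cen_all)
      link_keep <- if (linker_length > 0L) {
        keep <- rep(TRUE, linker_length)
        if (missing_gap > 0L) {
          lead <- ceiling(n_link_res / 2)
          keep <- c(rep(TRUE, lead), rep(FALSE, missing_gap),
                    rep(TRUE, n_link_res - lead))
        }
        keep
      } else logical()
      link_seq <- paste(sample(AA20, n_link_res, replace = TRUE),
                        collapse = "")
      ca_all <- rbind(trA$ca, link_ca[link_keep, , drop = FALSE], caB)
      resno <- c(seq_len(n_a),
                 (n_a + seq_len(linker_length))[link_keep],
                 n_a + linker_length + seq_len(n_b))
      seq_all <- paste0(seqA, link_seq, seqB)
      seg_a <- data.frame(start = 1L, end = n_a)
      seg_b <- data.frame(start = n_a + linker_length + 1L,
                          end = n_a + linker_length + n_b)
      num_a <- 1L; num_b <- 2L
    } else {
      # domain B inserted into domain A: A becomes 2 segments
      f <- discontinuous$longest_fraction %||% 0.6
      k1 <- max(1L, round(n_a * f))
      l1 <- max(1L, linker_length)
      cen_all <- colMeans(rbind(trA$ca, caB))
      link1 <- .linker_arc(trA$ca[k1, ], caB[1L, ], l1, cen_all)
      link2 <- .linker_arc(caB[n_b, ], trA$ca[k1 + 1L, ], l1, cen_all)
      ca_all <- rbind(trA$ca[seq_len(k1), , drop = FALSE], link1, caB,
                      link2, trA$ca[(k1 + 1L):n_a, , drop = FALSE])
      n_tot <- nrow(ca_all)
      resno <- seq_len(n_tot)
      seqA1 <- substr(seqA, 1L, k1); seqA2 <- substr(seqA, k1 + 1L, n_a)
      seq_all <- paste0(seqA1,
                        paste(sample(AA20, l1, replace = TRUE), collapse = ""),
                        seqB,
                        paste(sample(AA20, l1, replace = TRUE), collapse = ""),
                        seqA2)
      b_start <- k1 + l1 + 1L
      seg_a <- data.frame(start = c(1L, b_start + n_b + l1),
                          end = c(k1, n_tot))
      seg_b <- data.frame(start = b_start, end = b_start + n_b - 1L)
      num_a <- 1L; num_b <- 2L
    }

    dom_resno <- c(seg_a$start[1]:seg_a$end[1], seg_b$start[1]:seg_b$end[1],
                   if (nrow(seg_a) > 1L) seg_a$start[2]:seg_a$end[2])
    # chain position of a domain-local residue index
    if (is.null(discontinuous)) {
      pos_a <- function(o) o
      pos_b <- function(o) match(n_a + linker_length + o, resno)
    } else {
      k1d <- max(1L, round(n_a * (discontinuous$longest_fraction %||% 0.6)))
      l1d <- max(1L, linker_length)
      pos_a <- function(o) ifelse(o <= k1d, o, k1d + 2L * l1d + n_b +
                                    (o - k1d))
      pos_b <- function(o) k1d + l1d + o
    }
    extra <- NULL
    if (!is.null(placed$bridges)) {
      br <- placed$bridges
      ords <- ifelse(br$side == 1L, pos_a(br$res), pos_b(br$res))
      cnt <- integer(length(resno))
      elety <- character(nrow(br))
      for (r in seq_len(nrow(br))) {
        cnt[ords[r]] <- cnt[ords[r]] + 1L
        elety[r] <- sprintf("CG%d", cnt[ords[r]])
      }
      extra <- data.frame(ord = ords, elety = elety,
                          x = br$x, y = br$y, z = br$z)
    }
    chain <- .assemble_chain(entry_id, ca_all, seq_all, resno,
                             extra_atoms = extra,
                             resolution = resolution,
                             protect_ord = match(intersect(dom_resno, resno),
                                                 resno))
    chain <- apply_domain_definitions(chain, list(
      domain_definition(entry_id, num_a, seg_a, fold_a, resolution),
      domain_definition(entry_id, num_b, seg_b, fold_b, resolution)))
    da <- chain$domains[[which(vapply(chain$domains, function(d)
      d$domain_number, 1L) == num_a)]]
    db <- chain$domains[[which(vapply(chain$domains, function(d)
      d$domain_number, 1L) == num_b)]]
    ifc <- build_interface(da, db, params$contact_cutoff)
    list(chain = chain, interface = ifc,
         truth = list(L = ifc$L, target_L = target_L,
                      linker_length = linker_length,
                      missing_gap = missing_gap,
                      discontinuous = !is.null(discontinuous),
                      placement = placed[c("d", "L")]))
  })
}

#' Plant a geometrically similar interface in unrelated host domains
#'
#' Copies the interfacial C-alpha geometry of a source interface (both
#' sides) under a random rigid transform with iid Gaussian coordinate noise
#' and grafts it between two freshly generated host domains of the given
#' styles. The planted residues carry pseudo side-chain atoms that realize
#' the source's inter-domain contact map, so both the geometry and the
#' contact pattern of the source interface are reproduced up to the noise.
#' When source domains are supplied, the hosts are verified structurally
#' unrelated to them (TM-score below `params$tm_threshold`).
#'
#' @param source a `domain_interface` to replicate.
#' @param host_styles length-2 character vector of host domain styles.
#' @param noise_sigma coordinate noise standard deviation in Angstrom.
#' @param seed RNG seed.
#' @param host_n residue counts of the two host bulks.
#' @param entry_id entry identifier of the generated chain.
#' @param fold_labels length-2 fold labels of the host domains.
#' @param source_domains optional list of the two source
#'   `domain_instance`s, enabling the structural-unrelatedness check.
#' @param params a [ddi_params()] object.
#' @return List with `chain` (two-domain `chain_structure`), `interface`
#'   (the rebuilt interface) and `truth` (`correspondence`: source side
#'   residue ordinals mapped to planted chain ordinals; noise level).
#' @export
plant_similar_interface <- function(source, host_styles = c("helix-bundle",
                                                            "beta-sandwich"),
                                    noise_sigma = 0.5, seed = 1L,
                                    host_n = c(70L, 80L),
                                    entry_id = "planted",
                                    fold_labels = c("9.10.1", "9.20.1"),
                                    source_domains = NULL,
                                    params = ddi_params()) {
  stopifnot(inherits(source, "domain_interface"), source$L >= 1L)
  sa <- source$side_a[source$side_a$has_ca, , drop = FALSE]
  sb <- source$side_b[source$side_b$has_ca, , drop = FALSE]
  ka <- nrow(sa); kb <- nrow(sb)
  .with_seed(seed, {
    for (try in 1:20) {
      R <- .random_rotation()
      P <- rbind(as.matrix(sa[, c("x", "y", "z")]),
                 as.matrix(sb[, c("x", "y", "z")]))
      P <- sweep(P, 2L, colMeans(P)) %*% t(R)
      if (noise_sigma > 0)
        P <- P + matrix(rnorm(length(P), sd = noise_sigma), nrow(P))
      Pa <- P[seq_len(ka), , drop = FALSE]
      Pb <- P[ka + seq_len(kb), , drop = FALSE]

      # host bulk sizes are re-drawn each attempt so a failed structural
      # unrelatedness check can be escaped
      trH <- lapply(1:2, function(i)
        .ideal_ca(host_styles[i],
                  host_n[i] + sample(c(-10L, -5L, 0L, 5L, 10L, 15L), 1L)))
      # place each host bulk behind its interface side
      place_bulk <- function(tr, Pown, Pother) {
        v <- .unit(colMeans(Pown) - colMeans(Pother) + rnorm(3, sd = 0.3))
        r_bulk <- max(sqrt(rowSums(tr$ca^2)))
        for (gap in seq(3, 30, by = 1.5)) {
          ca <- tr$ca + matrix(colMeans(Pown) + v * (r_bulk + gap),
                               nrow(tr$ca), 3, byrow = TRUE)
          at <- .backbone_atoms(ca)
          other <- data.frame(ord = seq_len(nrow(Pother)), elety = "CA",
                              element = "C", is_heavy = TRUE,
                              x = Pother[, 1], y = Pother[, 2],
                              z = Pother[, 3])
          own <- data.frame(ord = seq_len(nrow(Pown)), elety = "CA",
                            element = "C", is_heavy = TRUE,
                            x = Pown[, 1], y = Pown[, 2], z = Pown[, 3])
          if (.min_heavy_dist(at, other) > 5 &&
              .min_heavy_dist(at, own) > 2.6) return(ca)
        }
        NULL
      }
      caA <- place_bulk(trH[[1L]], Pa, Pb)
      caB <- place_bulk(trH[[2L]], Pb, Pa)
      if (is.null(caA) || is.null(caB)) next
      if (.min_heavy_dist(.backbone_atoms(caA), .backbone_atoms(caB)) < 5)
        next

      nA <- nrow(caA); nB <- nrow(caB)
      ca_all <- rbind(caA, Pa, Pb, caB)
      n_tot <- nrow(ca_all)
      seq_all <- paste(c(sample(AA20, nA, replace = TRUE), sa$aa, sb$aa,
                         sample(AA20, nB, replace = TRUE)), collapse = "")
      # pseudo side-chain atoms realizing the source contact map
      extra <- list()
      cnt <- integer(n_tot)
      for (r in seq_len(nrow(source$contacts))) {
        ia <- source$contacts$ia[r]; ib <- source$contacts$ib[r]
        ja <- match(source$contacts$ord_a[r], sa$ord)
        jb <- match(source$contacts$ord_b[r], sb$ord)
        if (is.na(ja) || is.na(jb)) next
        pa <- Pa[ja, ]; pb <- Pb[jb, ]
        dd <- sqrt(sum((pa - pb)^2))
        if (dd <= params$contact_cutoff - 0.1) next  # C-alphas already touch
        m <- (pa + pb) / 2
        for (side in 1:2) {
          oa <- if (side == 1L) nA + ja else nA + ka + jb
          p <- if (side == 1L) m + 1.95 * .unit(pa - m)
               else m + 1.95 * .unit(pb - m)
          cnt[oa] <- cnt[oa] + 1L
          extra[[length(extra) + 1L]] <- data.frame(
            ord = oa, elety = sprintf("C%02d", cnt[oa]),
            x = p[1], y = p[2], z = p[3])
        }
      }
      chain <- .assemble_chain(entry_id, ca_all, seq_all, seq_len(n_tot),
                               extra_atoms = do.call(rbind, extra),
                               resolution = round(runif(1, 1.5, 2.4), 2),
                               protect_ord = seq_len(n_tot))
      chain <- apply_domain_definitions(chain, list(
        domain_definition(entry_id, 1L, data.frame(start = 1L,
                                                   end = nA + ka),
                          fold_labels[1L]),
        domain_definition(entry_id, 2L, data.frame(start = nA + ka + 1L,
                                                   end = n_tot),
                          fold_labels[2L])))
      if (!is.null(source_domains)) {
        unrelated <- TRUE
        for (h in chain$domains) for (s in source_domains)
          if (tm_score_domains(h, s, params) >= params$tm_threshold)
            unrelated <- FALSE
        if (!unrelated) next
      }
      ifc <- build_interface(chain$domains[[1L]], chain$domains[[2L]],
                             params$contact_cutoff)
      corr <- data.frame(
        source_ord = c(sa$ord, sb$ord),
        source_side = c(rep("A", ka), rep("B", kb)),
        planted_ord = c(nA + seq_len(ka), nA + ka + seq_len(kb)))
      return(list(chain = chain, interface = ifc,
                  truth = list(correspondence = corr,
                               noise_sigma = noise_sigma)))
    }
    stop("could not graft planted interface without clashes")
  })
}

#' Generate a sequence family at a target identity
#'
#' Members derive from a random ancestor by point substitutions calibrated
#' so each member's identity to the ancestor equals the target (up to
#' rounding of the substitution count).
#'
#' @param ancestor_length sequence length.
#' @param n_members number of derived members (ancestor not included).
#' @param target_identity target identity to the ancestor in (0, 1].
#' @param seed RNG seed.
#' @return Character vector: the ancestor followed by the members.
#' @export
make_sequence_family <- function(ancestor_length, n_members,
                                 target_identity, seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 1)
  .with_seed(seed, {
    anc <- sample(AA20, ancestor_length, replace = TRUE)
    n_mut <- round((1 - target_identity) * ancestor_length)
    members <- vapply(seq_len(n_members), function(i) {
      s <- anc
      pos <- sample(ancestor_length, n_mut)
      s[pos] <- vapply(s[pos], function(a) sample(setdiff(AA20, a), 1L), "")
      paste(s, collapse = "")
    }, "")
    c(paste(anc, collapse = ""), members)
  })
}

#' Write a generated chain as a PDB file
#'
#' Emits REMARK 465 records for annotated missing residues followed by the
#' coordinate records (via bio3d).
#'
#' @param chain a `chain_structure`.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
write_entry_pdb <- function(chain, file) {
  at <- chain$atoms
  res <- chain$residues
  resno <- res$resno[at$ord]
  aa3 <- vapply(res$aa[at$ord], function(a) {
    v <- suppressWarnings(bio3d::aa123(a))
    if (is.na(v)) "UNK" else v
  }, "")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  bio3d::write.pdb(file = tf,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = resno, resid = aa3,
                   chain = rep(chain$chain_id, nrow(at)),
                   elety = at$elety, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  lines <- readLines(tf)
  rem <- character()
  if (nrow(chain$missing_ranges) > 0L) {
    for (i in seq_len(nrow(chain$missing_ranges)))
      for (num in chain$missing_ranges$start[i]:chain$missing_ranges$end[i])
        rem <- c(rem, sprintf("REMARK 465   GLY %s %5d", chain$chain_id, num))
  }
  writeLines(c(rem, lines), file)
  invisible(file)
}

#' Specification of a synthetic benchmark suite
#'
#' Defaults define the study conditions exercised throughout the package:
#' 31 decoy two-domain entries with varied styles, 10 planted-similarity
#' entries (noise 0/0.25/0.5 Angstrom cycling), 3 three-domain entries, 3
#' discontinuous-domain entries, 3 missing-linker entries (gaps 10/13/14),
#' two 6-member sequence families at 45% identity, interface target L = 24,
#' and pseudo-resolutions mostly within the 2.5 Angstrom filter with a few
#' entries beyond it to exercise rejection.
#'
#' @param n_decoys,n_planted,n_multi,n_discontinuous,n_missing entry counts.
#' @param plant_sigmas noise levels cycled over planted entries.
#' @param target_L interface size target.
#' @param family_identity,family_size,n_families sequence family settings.
#' @param n_over_resolution entries assigned resolution beyond the filter.
#' @param seed RNG seed.
#' @return List of class `suite_spec`.
#' @export
suite_spec <- function(n_decoys = 31L, n_planted = 10L, n_multi = 3L,
                       n_discontinuous = 3L, n_missing = 3L,
                       plant_sigmas = c(0, 0.25, 0.5), target_L = 24L,
                       family_identity = 0.45, family_size = 6L,
                       n_families = 2L, n_over_resolution = 2L, seed = 1L) {
  structure(as.list(environment()), class = "suite_spec")
}

.decoy_styles <- function(i) {
  styles <- c("helix-bundle", "beta-sandwich", "mixed")
  c(styles[(i - 1L) %% 3L + 1L], styles[i %% 3L + 1L])
}

#' Generate a full benchmark corpus on disk
#'
#' Writes PDB files, a domain-boundary TSV, per-domain FASTA sequences and
#' a truth JSON sufficient to run the whole pipeline end to end: decoy
#' two-domain entries, planted-similarity entries with graded noise,
#' multi-domain entries, discontinuous-domain entries and missing-linker
#' entries. Deterministic (byte-identical corpus) under a fixed seed.
#'
#' @param spec a [suite_spec()].
#' @param dir output directory (created if needed).
#' @param params a [ddi_params()] object.
#' @return Invisibly, a manifest list: per-entry metadata, file paths and
#'   the planted truth.
#' @export
make_benchmark_suite <- function(spec = suite_spec(), dir,
                                 params = ddi_params()) {
  stopifnot(inherits(spec, "suite_spec"))
  dir.create(file.path(dir, "pdb"), recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  truth <- list()
  seed0 <- spec$seed

  fam_seqs <- lapply(seq_len(spec$n_families), function(i)
    make_sequence_family(60L, spec$family_size, spec$family_identity,
                         seed0 * 1000L + i))

  decoys <- list()
  for (i in seq_len(spec$n_decoys)) {
    id <- sprintf("DEC%03d", i)
    st <- .decoy_styles(i)
    fam <- if (i <= spec$n_families * spec$family_size)
      fam_seqs[[(i - 1L) %/% spec$family_size + 1L]][(i - 1L) %%
                                                       spec$family_size + 1L]
    else NULL
    res_override <- if (i > spec$n_decoys - spec$n_over_resolution)
      round(2.6 + 0.1 * (i %% 3), 2) else NULL
    dp <- make_domain_pair(
      id, st[1L], st[2L],
      n_a = if (is.null(fam)) 55L + (i %% 3L) * 10L else nchar(fam),
      n_b = 55L + ((i + 1L) %% 3L) * 10L, target_L = spec$target_L,
      linker_length = 3L + (i %% 4L), seed = seed0 * 100L + i,
      fold_a = sprintf("1.%d.10", i), fold_b = sprintf("2.%d.20", i),
      resolution = res_override, params = params, sequence_a = fam)
    decoys[[i]] <- dp
    entries[[id]] <- dp
  }

  planted_truth <- list()
  for (i in seq_len(spec$n_planted)) {
    id <- sprintf("PLT%03d", i)
    src <- decoys[[i]]
    sigma <- spec$plant_sigmas[(i - 1L) %% length(spec$plant_sigmas) + 1L]
    host_style <- setdiff(c("helix-bundle", "beta-sandwich", "mixed"),
                          .decoy_styles(i))
    pl <- plant_similar_interface(
      src$interface, host_styles = rep(host_style[1L], 2L),
      noise_sigma = sigma, seed = seed0 * 100L + 500L + i,
      entry_id = id,
      fold_labels = c(sprintf("7.%d.1", i), sprintf("8.%d.1", i)),
      source_domains = src$chain$domains, params = params)
    entries[[id]] <- pl
    planted_truth[[id]] <- list(source = sprintf("DEC%03d", i),
                                noise_sigma = sigma,
                                correspondence = pl$truth$correspondence)
  }

  for (i in seq_len(spec$n_multi)) {
    id <- sprintf("MUL%03d", i)
    # three-domain chain: a two-domain pair extended by a third domain
    dp <- make_domain_pair(id, "helix-bundle", "mixed", n_a = 55L,
                           n_b = 55L, target_L = spec$target_L,
                           linker_length = 4L, seed = seed0 * 100L + 700L + i,
                           fold_a = sprintf("3.%d.1", i),
                           fold_b = sprintf("3.%d.2", i), params = params)
    dp3 <- .extend_with_third_domain(dp, seed0 * 100L + 750L + i,
                                     sprintf("3.%d.3", i), spec$target_L,
                                     params)
    entries[[id]] <- dp3
  }

  for (i in seq_len(spec$n_discontinuous)) {
    id <- sprintf("DIS%03d", i)
    dp <- make_domain_pair(id, "beta-sandwich", "helix-bundle",
                           n_a = 170L, n_b = 80L, target_L = 50L,
                           linker_length = 3L,
                           discontinuous = list(longest_fraction = 0.7),
                           seed = seed0 * 100L + 800L + i,
                           fold_a = sprintf("4.%d.1", i),
                           fold_b = sprintf("4.%d.2", i), params = params)
    entries[[id]] <- dp
  }

  gaps <- c(10L, 13L, 14L)
  for (i in seq_len(spec$n_missing)) {
    id <- sprintf("MIS%03d", i)
    g <- gaps[(i - 1L) %% length(gaps) + 1L]
    dp <- make_domain_pair(id, "mixed", "helix-bundle", n_a = 55L,
                           n_b = 55L, target_L = spec$target_L,
                           linker_length = g + 2L, missing_gap = g,
                           seed = seed0 * 100L + 900L + i,
                           fold_a = sprintf("5.%d.1", i),
                           fold_b = sprintf("5.%d.2", i), params = params)
    entries[[id]] <- dp
    truth[[id]] <- list(missing_gap = g, linker_length = g + 2L)
  }

  # write corpus
  dom_rows <- list(); fasta <- character()
  for (id in names(entries)) {
    e <- entries[[id]]
    write_entry_pdb(e$chain, file.path(dir, "pdb", paste0(id, ".pdb")))
    for (d in e$chain$domains) {
      segs <- paste(sprintf("%d-%d", d$definition$segments$start,
                            d$definition$segments$end), collapse = ",")
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        entry_id = id, chain = e$chain$chain_id,
        domain_number = d$domain_number, segments = segs,
        fold_label = d$fold_label,
        resolution = e$chain$resolution, stringsAsFactors = FALSE)
      fasta <- c(fasta, sprintf(">%s_%d", id, d$domain_number), d$sequence)
    }
  }
  dom_tab <- do.call(rbind, dom_rows)
  write.table(dom_tab, file.path(dir, "domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(fasta, file.path(dir, "sequences.fasta"))
  jsonlite::write_json(
    list(seed = seed0,
         planted = lapply(planted_truth, function(p)
           list(source = p$source, noise_sigma = p$noise_sigma)),
         missing = truth,
         n_entries = length(entries)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(entries = entries, planted = planted_truth,
                 domains = dom_tab, dir = dir))
}

# append a third domain after an existing two-domain chain
.extend_with_third_domain <- function(dp, seed, fold_c, target_L, params) {
  .with_seed(seed, {
    chain <- dp$chain
    db <- chain$domains[[2L]]
    trC <- .ideal_ca("beta-sandwich", 55L)
    atB <- db$atoms
    at_all <- chain$atoms
    caB_mat <- as.matrix(db$residues[, c("ca_x", "ca_y", "ca_z")])
    uB <- .smallest_axis(caB_mat)
    axC <- .smallest_axis(trC$ca)
    for (try in 1:60) {
      # approach along B's flattest direction, presenting C's flattest face
      u <- .unit(sample(c(1, -1), 1L) * uB + rnorm(3, sd = 0.25))
      R <- .rot_about(u, runif(1, 0, 2 * pi)) %*%
        .rot_align(sample(c(1, -1), 1L) * axC, -u)
      caC0 <- trC$ca %*% t(R)
      cb <- colMeans(caB_mat)
      place <- function(d) {
        ca <- caC0 + matrix(cb + d * u, nrow(caC0), 3, byrow = TRUE)
        ca
      }
      lo <- 0; hi <- 80
      atC <- function(d) .backbone_atoms(place(d))
      if (.min_heavy_dist(at_all, atC(hi)) < 2.6) next
      while (hi - lo > 0.2) {
        mid <- (lo + hi) / 2
        if (.min_heavy_dist(at_all, atC(mid)) < 2.6) lo <- mid else hi <- mid
      }
      d <- hi
      ct <- .residue_contacts(atB, atC(d), params$contact_cutoff)
      L <- length(unique(ct$ord_a)) + length(unique(ct$ord_b))
      if (L < 0.7 * target_L) next
      caC <- place(d)
      n_old <- nrow(chain$residues)
      link <- .arc_points(as.matrix(chain$residues[n_old,
                                                   c("ca_x", "ca_y", "ca_z")]),
                          caC[1L, ], 3L)
      ca_all <- rbind(as.matrix(chain$residues[, c("ca_x", "ca_y", "ca_z")]),
                      link, caC)
      seq_all <- paste0(paste(chain$residues$aa, collapse = ""),
                        paste(sample(AA20, 3L + nrow(caC), replace = TRUE),
                              collapse = ""))
      new_chain <- .assemble_chain(chain$entry_id, ca_all, seq_all,
                                   seq_len(nrow(ca_all)),
                                   resolution = chain$resolution,
                                   protect_ord = c(seq_len(n_old),
                                                   n_old + 3L +
                                                     seq_len(nrow(caC))))
      defs <- lapply(chain$domains, function(dm) dm$definition)
      defs[[3L]] <- domain_definition(chain$entry_id, 3L,
                                      data.frame(start = n_old + 4L,
                                                 end = nrow(ca_all)),
                                      fold_c, chain$resolution)
      new_chain <- apply_domain_definitions(new_chain, defs)
      return(list(chain = new_chain, interface = dp$interface,
                  truth = dp$truth))
    }
    stop("could not place a third domain")
  })
}
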