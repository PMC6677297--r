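# Non-sequential structural alignment of two domain-domain interfaces and
# its scoring: S, IS-score, RMSD, f_res, f_con, with empirical significance
# calibrated on random interface pairs.

#' Distance normalization scale d0
#'
#' `d0` sets the distance scale of the alignment score kernel
#' `1/(1 + d^2/d0^2)`. For sequential (whole-domain) alignment
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`; for non-sequential interface alignment
#' `d0 = 0.7 (L - 15)^(1/3) - 0.1`. Both are floored at `floor` (the
#' formulas are non-positive for L <= 15).
#'
#' @param L length (interface residue count or domain length) used for
#'   normalization.
#' @param mode `"non-sequential"` (interface alignment, default) or
#'   `"sequential"` (whole-domain TM-score).
#' @param floor lower bound in Angstrom (default 0.5).
#' @return d0 in Angstrom.
#' @export
d0_scale <- function(L, mode = c("non-sequential", "sequential"),
                     floor = 0.5) {
  mode <- match.arg(mode)
  stopifnot(all(L >= 1), floor > 0)
  v <- if (mode == "sequential") 1.24 * sign(L - 15) * abs(L - 15)^(1 / 3) - 1.8
       else 0.7 * sign(L - 15) * abs(L - 15)^(1 / 3) - 0.1
  pmax(v, floor)
}

#' Score normalization constant s0
#'
#' `s0 = 0.18 - 0.35 / L^0.3`, the length-dependent constant used to map the
#' raw alignment score S onto the IS-score scale
#' `IS = (S + s0)/(1 + s0)`. Positive only for L >= 10; smaller interfaces
#' are outside the score's calibrated regime and raise an error.
#'
#' @param L query interface length (total interfacial residues).
#' @return s0 (dimensionless).
#' @export
s0_norm <- function(L) {
  v <- 0.18 - 0.35 / L^0.3
  if (any(v <= 0))
    stop("s0 is non-positive for L = ", paste(L[v <= 0], collapse = ", "),
         "; interfaces this small are not scoreable")
  v
}

#' Per-position contact overlap f_i
#'
#' `f_i = (c_i/a_i + c_i/b_i)/2` where `a_i` and `b_i` are the interfacial
#' contact counts of the template and query residues at aligned position i
#' and `c_i` is the number of overlapping contacts at that position.
#'
#' @param c_i overlapping contact count.
#' @param a_i template residue contact count (>= 1).
#' @param b_i query residue contact count (>= 1).
#' @return f_i in `[0, 1]`.
#' @export
contact_overlap <- function(c_i, a_i, b_i) {
  if (any(a_i < 1) || any(b_i < 1)) stop("contact counts must be >= 1")
  stopifnot(all(c_i >= 0), all(c_i <= pmin(a_i, b_i)))
  (c_i / a_i + c_i / b_i) / 2
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation mapping the rows
#' of `coords_b` onto the rows of `coords_a` (paired order).
#'
#' @param coords_a,coords_b N x 3 matrices of paired points, N >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   such that `coords_b %*% t(rotation) + translation` approximates
#'   `coords_a`, and the minimized `rmsd`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) < 3L || nrow(coords_a) != nrow(coords_b))
    stop("need at least 3 paired points")
  if (any(apply(coords_b, 2, stats::var) + apply(coords_a, 2, stats::var) == 0) ||
      qr(sweep(coords_a, 2, colMeans(coords_a)))$rank < 2L)
    stop("degenerate (collinear or coincident) point set")
  r <- .kabsch_cpp(coords_b, coords_a)
  list(rotation = r$rotation, translation = as.numeric(r$translation),
       rmsd = r$rmsd)
}

# stacked C-alpha representation of an interface: coordinates, side labels
# (1 = side_a, 2 = side_b) and side-local row indices
.ifc_coords <- function(ifc) {
  a <- ifc$side_a[ifc$side_a$has_ca, , drop = FALSE]
  b <- ifc$side_b[ifc$side_b$has_ca, , drop = FALSE]
  list(X = rbind(as.matrix(a[, c("x", "y", "z")]),
                 as.matrix(b[, c("x", "y", "z")])),
       side = c(rep(1L, nrow(a)), rep(2L, nrow(b))),
       row = c(match(a$ord, ifc$side_a$ord), match(b$ord, ifc$side_b$ord)),
       nA = nrow(a), nB = nrow(b))
}

# Score a full correspondence between stacked query indices qs and stacked
# template indices ts under superposition (R, t) applied to the template.
.score_from_matching <- function(query, template, cq, ct, qs, ts, pairing,
                                 R, tvec, params) {
  LQ <- query$L
  d0 <- d0_scale(LQ, "non-sequential", params$d0_floor)
  s0 <- s0_norm(LQ)
  n <- length(qs)
  if (n == 0L) {
    scores <- list(S = 0, IS_score = s0 / (1 + s0), s0 = s0, d0 = d0,
                   rmsd = NA_real_, f_res = 0, f_con = 0, n_aligned = 0L,
                   p_value = NA_real_, empty = TRUE)
    return(list(scores = scores, pairs = NULL))
  }
  Tt <- ct$X[ts, , drop = FALSE] %*% t(R) +
    matrix(tvec, n, 3, byrow = TRUE)
  di <- sqrt(rowSums((cq$X[qs, , drop = FALSE] - Tt)^2))

  # map query side rows -> template side rows under this correspondence
  mapA <- rep(NA_integer_, nrow(query$side_a))  # query side_a row -> t row
  mapB <- rep(NA_integer_, nrow(query$side_b))
  q_side <- cq$side[qs]; q_row <- cq$row[qs]
  t_side <- ct$side[ts]; t_row <- ct$row[ts]
  mapA[q_row[q_side == 1L]] <- t_row[q_side == 1L]
  mapB[q_row[q_side == 2L]] <- t_row[q_side == 2L]

  tc <- template$contacts
  tkey <- paste(tc$ia, tc$ib)
  qc <- query$contacts
  # template residue pair implied by each query contact
  if (pairing == 1L) {
    ka <- mapA[qc$ia]; kb <- mapB[qc$ib]
    preserved <- !is.na(ka) & !is.na(kb) & paste(ka, kb) %in% tkey
  } else {
    ka <- mapA[qc$ia]  # lands on template side_b
    kb <- mapB[qc$ib]  # lands on template side_a
    preserved <- !is.na(ka) & !is.na(kb) & paste(kb, ka) %in% tkey
  }

  # per-position counts: c_i over query contacts incident to each aligned
  # query residue; a_i template counts; b_i query counts
  ci <- integer(n)
  bi <- integer(n); ai <- integer(n)
  for (k in seq_len(n)) {
    if (q_side[k] == 1L) {
      inc <- qc$ia == q_row[k]
      bi[k] <- query$side_a$n_contacts[q_row[k]]
    } else {
      inc <- qc$ib == q_row[k]
      bi[k] <- query$side_b$n_contacts[q_row[k]]
    }
    ci[k] <- sum(preserved & inc)
    ai[k] <- if (t_side[k] == 1L) template$side_a$n_contacts[t_row[k]]
             else template$side_b$n_contacts[t_row[k]]
  }
  fi <- contact_overlap(ci, ai, bi)
  kern <- 1 / (1 + (di / d0)^2)
  S <- sum(fi * kern) / LQ
  IS <- (S + s0) / (1 + s0)
  f_con <- if (nrow(qc) > 0L) sum(preserved) / nrow(qc) else 0
  pairs <- data.frame(q_side = q_side, q_row = q_row, t_side = t_side,
                      t_row = t_row, d = di, c = ci, a = ai, b = bi, f = fi)
  scores <- list(S = S, IS_score = IS, s0 = s0, d0 = d0,
                 rmsd = sqrt(mean(di^2)), f_res = n / LQ, f_con = f_con,
                 n_aligned = n, p_value = NA_real_, empty = FALSE)
  list(scores = scores, pairs = pairs)
}

#' Score an interface alignment
#'
#' Computes all score fields for a given residue correspondence under its
#' superposition: the raw score `S = (1/L_Q) sum f_i / (1 + d_i^2/d0^2)`,
#' the normalized `IS-score = (S + s0)/(1 + s0)`, the C-alpha RMSD over
#' aligned pairs, the residue coverage `f_res = N_a/L_Q` and the contact
#' coverage `f_con` (fraction of query contacts preserved in the template).
#'
#' @param alignment an `interface_alignment` as returned by
#'   [align_interfaces()].
#' @param params a [ddi_params()] object.
#' @return List of class `alignment_scores`.
#' @export
score_alignment <- function(alignment, params = ddi_params()) {
  stopifnot(inherits(alignment, "interface_alignment"))
  cq <- .ifc_coords(alignment$query)
  ct <- .ifc_coords(alignment$template)
  r <- .score_from_matching(alignment$query, alignment$template, cq, ct,
                            alignment$qs, alignment$ts, alignment$pairing,
                            alignment$rotation, alignment$translation,
                            params)
  structure(r$scores, class = "alignment_scores")
}

.pca_rotations <- function(X, Y) {
  # rotations aligning the principal frames of template Y onto query X,
  # over the four proper sign combinations
  vx <- svd(sweep(X, 2, colMeans(X)))$v
  vy <- svd(sweep(Y, 2, colMeans(Y)))$v
  if (det(vx) < 0) vx[, 3] <- -vx[, 3]
  if (det(vy) < 0) vy[, 3] <- -vy[, 3]
  out <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    sg <- diag(c(s1, s2, s1 * s2))
    out[[length(out) + 1L]] <- vx %*% sg %*% t(vy)
  }
  out
}

# all ordered injections of 1..k into 1..n (k <= n), as a list
.injections <- function(n, k) {
  if (k == 0L) return(list(integer()))
  out <- list()
  rec <- function(chosen, left) {
    if (length(chosen) == k) { out[[length(out) + 1L]] <<- chosen; return() }
    for (v in left) rec(c(chosen, v), setdiff(left, v))
  }
  rec(integer(), seq_len(n))
  out
}

.count_injections <- function(n, k) {
  if (k > n) k <- n
  prod(seq(n, by = -1, length.out = k))
}

#' Non-sequential alignment of two interfaces
#'
#' Searches for the residue correspondence between a query and a template
#' interface that maximizes the IS-score. A valid correspondence maps each
#' query domain side onto exactly one template side (both pairings are
#' tried), is one-to-one, and is scored under the Kabsch least-squares
#' superposition of its own pairs. The search runs iterative refinement
#' (superpose, rebuild the distance-kernel cost, re-assign per side by
#' rectangular Hungarian assignment, re-superpose) from principal-axes
#' seeds, contiguous interface-fragment seeds and an identity seed; on
#' instances small enough to enumerate, an exact search over all per-side
#' injective assignments is additionally performed and the overall best is
#' returned. Deterministic for fixed inputs and parameters.
#'
#' @param query,template `domain_interface` objects with C-alpha
#'   coordinates.
#' @param params a [ddi_params()] object.
#' @return List with elements `alignment` (class `interface_alignment`:
#'   stacked index correspondence, rotation, translation, pairing, pairs
#'   table) and `scores` (class `alignment_scores`).
#' @export
align_interfaces <- function(query, template, params = ddi_params()) {
  stopifnot(inherits(query, "domain_interface"),
            inherits(template, "domain_interface"))
  cq <- .ifc_coords(query); ct <- .ifc_coords(template)
  if (nrow(cq$X) < 3L || nrow(ct$X) < 3L)
    stop("interfaces need at least 3 C-alpha coordinates to align")
  d0 <- d0_scale(query$L, "non-sequential", params$d0_floor)

  best <- NULL
  consider <- function(qs, ts, pairing, R, tvec) {
    if (length(qs) < 3L) return()
    sc <- .score_from_matching(query, template, cq, ct, qs, ts, pairing,
                               R, tvec, params)
    if (is.null(best) || sc$scores$IS_score > best$scores$IS_score + 1e-12)
      best <<- list(scores = sc$scores, pairs = sc$pairs, qs = qs, ts = ts,
                    pairing = pairing, rotation = R, translation = tvec)
  }

  refine_and_consider <- function(pairing, R0, t0) {
    r <- .refine_seed_cpp(cq$X, ct$X, cq$side, ct$side, pairing,
                          R0, matrix(t0, 1), d0, 2 * d0,
                          params$max_iterations, params$convergence_tol)
    qs <- r$qi; ts <- r$ti
    if (length(qs) < 3L) return()
    # final superposition: Kabsch on the converged matching
    k <- .kabsch_cpp(ct$X[ts, , drop = FALSE], cq$X[qs, , drop = FALSE])
    consider(qs, ts, pairing, k$rotation, as.numeric(k$translation))
  }

  for (pairing in 1:2) {
    ta_lab <- if (pairing == 1L) 1L else 2L
    nAq <- cq$nA; nBq <- cq$nB
    nAt <- sum(ct$side == ta_lab); nBt <- sum(ct$side == (3L - ta_lab))
    if (min(nAq, nAt) + min(nBq, nBt) < 3L) next

    # principal-axes seeds
    cx <- colMeans(cq$X); cy <- colMeans(ct$X)
    for (R in .pca_rotations(cq$X, ct$X))
      refine_and_consider(pairing, R, cx - as.numeric(R %*% cy))

    # identity seed when side sizes match
    if (nAq == nAt && nBq == nBt) {
      qs <- seq_len(nrow(cq$X))
      ts <- c(which(ct$side == ta_lab), which(ct$side == (3L - ta_lab)))
      k <- tryCatch(.kabsch_cpp(ct$X[ts, , drop = FALSE], cq$X[qs, , drop = FALSE]),
                    error = function(e) NULL)
      if (!is.null(k))
        refine_and_consider(pairing, k$rotation, as.numeric(k$translation))
    }

    # contiguous fragment seeds
    fl <- params$fragment_length
    frag_starts <- function(n) if (n < fl) integer() else
      unique(round(seq(1L, n - fl + 1L, length.out = min(4L, n - fl + 1L))))
    seeds <- list()
    for (s in 1:2) {
      iq <- which(cq$side == s)
      it <- which(ct$side == (if (pairing == 1L) s else 3L - s))
      for (a in frag_starts(length(iq))) for (b in frag_starts(length(it)))
        seeds[[length(seeds) + 1L]] <- list(q = iq[a:(a + fl - 1L)],
                                            t = it[b:(b + fl - 1L)])
    }
    if (length(seeds) > params$max_seeds)
      seeds <- seeds[unique(round(seq(1L, length(seeds),
                                      length.out = params$max_seeds)))]
    for (sd in seeds) {
      k <- tryCatch(.kabsch_cpp(ct$X[sd$t, , drop = FALSE],
                                cq$X[sd$q, , drop = FALSE]),
                    error = function(e) NULL)
      if (!is.null(k))
        refine_and_consider(pairing, k$rotation, as.numeric(k$translation))
    }

    # exact enumeration when feasible (all per-side injective assignments,
    # each scored under the Kabsch superposition of its own pairs)
    n_enum <- .count_injections(max(nAq, nAt), min(nAq, nAt)) *
      .count_injections(max(nBq, nBt), min(nBq, nBt))
    if (is.finite(n_enum) && n_enum <= params$exact_limit && n_enum >= 1) {
      iqA <- which(cq$side == 1L); iqB <- which(cq$side == 2L)
      itA <- which(ct$side == ta_lab); itB <- which(ct$side == (3L - ta_lab))
      # query contacts between C-alpha-bearing rows, as positions in qa/qb
      qposA <- match(seq_len(nrow(query$side_a)), cq$row[iqA])
      qposB <- match(seq_len(nrow(query$side_b)), cq$row[iqB])
      qc <- query$contacts
      qc_pos <- cbind(qposA[qc$ia], qposB[qc$ib]) - 1L
      qc_pos <- qc_pos[stats::complete.cases(qc_pos), , drop = FALSE]
      # template contact matrix in (ta, tb) position space
      tposA <- ct$row[itA]  # side rows of the ta coordinates
      tposB <- ct$row[itB]
      tc <- template$contacts
      tcon <- matrix(0L, length(itA), length(itB))
      for (r in seq_len(nrow(tc))) {
        if (ta_lab == 1L) {
          i <- match(tc$ia[r], tposA); j <- match(tc$ib[r], tposB)
        } else {
          i <- match(tc$ib[r], tposA); j <- match(tc$ia[r], tposB)
        }
        if (!is.na(i) && !is.na(j)) tcon[i, j] <- 1L
      }
      a_a <- if (ta_lab == 1L) template$side_a$n_contacts[tposA]
             else template$side_b$n_contacts[tposA]
      a_b <- if (ta_lab == 1L) template$side_b$n_contacts[tposB]
             else template$side_a$n_contacts[tposB]
      ex <- .exact_enum_cpp(
        cq$X[iqA, , drop = FALSE], cq$X[iqB, , drop = FALSE],
        ct$X[itA, , drop = FALSE], ct$X[itB, , drop = FALSE],
        matrix(as.integer(qc_pos), ncol = 2L), tcon,
        pmax(a_a, 1), pmax(a_b, 1),
        pmax(query$side_a$n_contacts[cq$row[iqA]], 1),
        pmax(query$side_b$n_contacts[cq$row[iqB]], 1),
        d0, query$L)
      if (length(ex$qa) + length(ex$qb) >= 3L) {
        qs <- c(iqA[ex$qa + 1L], iqB[ex$qb + 1L])
        ts <- c(itA[ex$ta + 1L], itB[ex$tb + 1L])
        k <- tryCatch(.kabsch_cpp(ct$X[ts, , drop = FALSE],
                                  cq$X[qs, , drop = FALSE]),
                      error = function(e) NULL)
        if (!is.null(k))
          consider(qs, ts, pairing, k$rotation, as.numeric(k$translation))
      }
    }
  }

  if (is.null(best)) stop("no alignment found (degenerate interfaces)")
  alignment <- structure(list(
    query = query, template = template,
    qs = best$qs, ts = best$ts, pairing = best$pairing,
    rotation = best$rotation, translation = best$translation,
    pairs = best$pairs, n_aligned = length(best$qs)
  ), class = "interface_alignment")
  list(alignment = alignment,
       scores = structure(best$scores, class = "alignment_scores"))
}

#' @export
print.alignment_scores <- function(x, ...) {
  cat(sprintf(
    "alignment_scores: IS = %.4f  S = %.4f  rmsd = %.2f  N_a = %d  f_res = %.3f  f_con = %.3f\n",
    x$IS_score, x$S, x$rmsd, x$n_aligned, x$f_res, x$f_con))
  invisible(x)
}

#' Calibrate IS-score significance on a null sample
#'
#' Fits an extreme-value (Gumbel) distribution by the method of moments to
#' best-match IS-scores obtained from random (structurally unrelated)
#' interface pairs, giving a smooth, monotone-decreasing p-value for any
#' observed score and the score threshold at the chosen significance level.
#'
#' @param null_scores numeric vector of null best-match IS-scores.
#' @param alpha significance level (default 0.05).
#' @param min_n minimum sample size accepted (default 50).
#' @return Object of class `ddi_significance` with elements `mu`, `beta`,
#'   `n`, `alpha` and `threshold` (score with p-value alpha).
#' @export
calibrate_significance <- function(null_scores, alpha = 0.05, min_n = 50L) {
  null_scores <- null_scores[is.finite(null_scores)]
  if (length(null_scores) < min_n)
    stop("need at least ", min_n, " null scores, got ", length(null_scores))
  beta <- stats::sd(null_scores) * sqrt(6) / pi
  mu <- mean(null_scores) - 0.5772156649 * beta
  structure(list(mu = mu, beta = beta, n = length(null_scores),
                 alpha = alpha,
                 threshold = mu - beta * log(-log(1 - alpha))),
            class = "ddi_significance")
}

#' p-value of an IS-score under a calibrated null
#'
#' Upper-tail probability of the fitted Gumbel null; monotone decreasing in
#' the score.
#'
#' @param model a `ddi_significance` object from [calibrate_significance()].
#' @param score IS-score value(s).
#' @return p-value(s) in `(0, 1)`.
#' @export
significance_pvalue <- function(model, score) {
  stopifnot(inherits(model, "ddi_significance"))
  1 - exp(-exp(-(score - model$mu) / model$beta))
}

#' @export
print.ddi_significance <- function(x, ...) {
  cat(sprintf(
    "ddi_significance: Gumbel(mu = %.4f, beta = %.4f), n = %d, IS threshold at p = %.2g: %.4f\n",
    x$mu, x$beta, x$n, x$alpha, x$threshold))
  invisible(x)
}
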