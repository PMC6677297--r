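test_that("d0 follows the printed formulas with a floor", {
  expect_equal(d0_scale(20, "non-sequential"), 0.7 * 5^(1 / 3) - 0.1,
               tolerance = 1e-12)
  expect_equal(d0_scale(20, "non-sequential"), 1.097, tolerance = 1e-3)
  expect_equal(d0_scale(135, "sequential"), 1.24 * 120^(1 / 3) - 1.8,
               tolerance = 1e-12)
  expect_equal(d0_scale(135, "sequential"), 4.316, tolerance = 1e-3)
  # floor engages at and below L = 15
  expect_equal(d0_scale(15, "non-sequential"), 0.5)
  expect_equal(d0_scale(3, "sequential", floor = 0.5), 0.5)
})

test_that("s0 follows its formula, is monotone, and guards small L", {
  expect_equal(s0_norm(20), 0.18 - 0.35 / 20^0.3, tolerance = 1e-12)
  expect_equal(s0_norm(20), 0.0375, tolerance = 2e-3)
  expect_equal(s0_norm(1000), 0.1359, tolerance = 1e-3)
  L <- c(10, 20, 50, 200, 1000, 1e6)
  expect_true(all(diff(s0_norm(L)) > 0))
  expect_lt(s0_norm(1e9), 0.18)
  expect_error(s0_norm(5), "non-positive")
})

test_that("contact overlap f_i is the symmetrized contact ratio", {
  expect_equal(contact_overlap(0, 3, 4), 0)
  expect_equal(contact_overlap(5, 5, 5), 1)
  expect_equal(contact_overlap(2, 4, 2), 0.75)
  expect_error(contact_overlap(1, 0, 2), ">= 1")
  expect_error(contact_overlap(3, 2, 2))  # c_i > min(a_i, b_i)
})

test_that("Kabsch superposition recovers exact and noisy transforms", {
  set.seed(3)
  X <- matrix(rnorm(30), ncol = 3)
  id <- kabsch_superpose(X, X)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)

  R <- random_rotation(); tv <- c(3, -2, 7)
  Y <- X %*% t(R) + matrix(tv, nrow(X), 3, byrow = TRUE)
  k <- kabsch_superpose(X, Y)   # maps Y back onto X
  expect_equal(k$rmsd, 0, tolerance = 1e-8)
  expect_equal(k$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)

  # 4-point toy vs brute-force minimisation over rotation space
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3,
              byrow = TRUE) * 3
  B <- A + matrix(rnorm(12, sd = 0.4), ncol = 3)
  k2 <- kabsch_superpose(A, B)
  rot_from <- function(ang) {
    Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                               0, 0, 1), 3, byrow = TRUE)
    Ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                               -sin(a), 0, cos(a)), 3, byrow = TRUE)
    Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3])
  }
  obj <- function(ang) {
    Rr <- rot_from(ang)
    Bt <- sweep(B, 2, colMeans(B)) %*% t(Rr)
    sqrt(mean(rowSums((Bt - sweep(A, 2, colMeans(A)))^2)))
  }
  best <- Inf
  for (s in 1:20) {
    o <- optim(runif(3, -pi, pi), obj,
               control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(k2$rmsd, best, tolerance = 1e-5)

  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  colin <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(colin, colin), "degenerate")
})

test_that("score_alignment reproduces hand-computed S and IS-score", {
  # 12-residue toy interface aligned to a shifted copy under the identity
  # superposition: d_i known exactly, contact pattern fully preserved
  xa <- cbind(seq_len(6) * 6, 0, 0)
  xb <- cbind(seq_len(6) * 6, 4, 0)
  q <- toy_interface(xa, xb, cbind(1:6, 1:6))
  shift <- 1.5
  dz <- cbind(0, 0, rep(shift, 6))
  tpl <- toy_interface(xa + dz, xb + dz, cbind(1:6, 1:6), "t")
  al <- structure(list(query = q, template = tpl,
                       qs = 1:12, ts = 1:12, pairing = 1L,
                       rotation = diag(3), translation = c(0, 0, 0),
                       n_aligned = 12L),
                  class = "interface_alignment")
  sc <- score_alignment(al)
  d0 <- d0_scale(12, "non-sequential")
  s0 <- s0_norm(12)
  S_hand <- sum(rep(1, 12) / (1 + shift^2 / d0^2)) / 12
  expect_equal(sc$S, S_hand, tolerance = 1e-12)
  expect_equal(sc$IS_score, (S_hand + s0) / (1 + s0), tolerance = 1e-12)
  expect_equal(sc$rmsd, shift, tolerance = 1e-12)
  expect_equal(sc$f_res, 1)
  expect_equal(sc$f_con, 1)

  # all contact overlap destroyed: f_i = 0 -> S = 0, IS = s0/(1+s0)
  tpl2 <- tpl
  tpl2$contacts <- tpl2$contacts[c(2:6, 1), ]
  tpl2$contacts$ib <- c(3, 4, 5, 6, 1, 2)  # contacts that never match query
  al2 <- al; al2$template <- tpl2
  sc2 <- score_alignment(al2)
  expect_equal(sc2$S, 0)
  expect_equal(sc2$IS_score, s0 / (1 + s0), tolerance = 1e-12)
})
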