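test_that("heavy-atom contact cutoff is inclusive at 4.5 A and ignores hydrogens", {
  mk <- function(dist, elety = "CB", element = "C") {
    da <- toy_domain("e", 1L, 1L, atoms = data.frame(
      res = 1L, elety = c("CA", "CB"), element = "C",
      x = c(0, 0), y = 0, z = 0))
    db <- toy_domain("e", 2L, 2L, atoms = data.frame(
      res = 1L, elety = c("CA", elety), element = c("C", element),
      x = c(dist + 10, dist), y = 0, z = 0))
    heavy_atom_contacts(da, db, 4.5)
  }
  expect_equal(nrow(mk(4.4)), 1L)
  expect_equal(nrow(mk(4.5)), 1L)   # inclusive boundary
  expect_equal(nrow(mk(4.6)), 0L)
  # hydrogens at 1 A do not create a contact when heavy atoms are far
  expect_equal(nrow(mk(1.0, elety = "H", element = "H")), 0L)
})

test_that("pruned neighbour search equals the all-pairs double loop", {
  dp <- fix_pair()
  da <- dp$chain$domains[[1]]; db <- dp$chain$domains[[2]]
  fast <- heavy_atom_contacts(da, db, 4.5)
  slow <- contacts_oracle(da$atoms, db$atoms, 4.5)
  expect_equal(fast$ord_a, slow$ord_a)
  expect_equal(fast$ord_b, slow$ord_b)
  expect_equal(fast$min_dist, slow$min_dist, tolerance = 1e-10)
})

test_that("build_interface collects interfacial residues and contact counts", {
  # 12 distinct contacting residue pairs -> L = 24
  xa <- cbind(seq_len(12) * 8, 0, 0)
  atoms <- function(x, y) data.frame(res = seq_len(nrow(x)), elety = "CA",
                                     element = "C", x = x[, 1], y = y,
                                     z = 0)
  da <- toy_domain("e", 1L, 1:12, atoms = atoms(xa, 0))
  db <- toy_domain("e", 2L, 101:112, atoms = atoms(xa, 4.0))
  ifc <- build_interface(da, db)
  expect_equal(ifc$L, 24L)
  expect_equal(ifc$n_contacts_total, 12L)
  expect_true(is_interacting_pair(ifc, 20L))
  # every interfacial residue appears in at least one contact
  expect_true(all(ifc$side_a$n_contacts >= 1L))
  expect_true(all(ifc$side_b$n_contacts >= 1L))

  # far-apart domains: empty interface, flagged not an error
  db_far <- toy_domain("e", 2L, 101:112, atoms = atoms(xa, 100))
  empty <- build_interface(da, db_far)
  expect_equal(empty$L, 0L)
  expect_false(is_interacting_pair(empty))

  # one residue contacting 3 partners has contact count 3
  da1 <- toy_domain("e", 1L, 1L, atoms = data.frame(
    res = 1L, elety = "CA", element = "C", x = 0, y = 0, z = 0))
  db3 <- toy_domain("e", 2L, 101:103, atoms = data.frame(
    res = 1:3, elety = "CA", element = "C", x = c(-3, 0, 3), y = 3, z = 0))
  ifc3 <- build_interface(da1, db3)
  expect_equal(ifc3$side_a$n_contacts, 3L)
})

test_that("interface is symmetric and invariant under rigid transforms", {
  dp <- fix_pair()
  da <- dp$chain$domains[[1]]; db <- dp$chain$domains[[2]]
  ab <- build_interface(da, db)
  ba <- build_interface(db, da)
  expect_equal(ab$L, ba$L)
  expect_setequal(paste(ab$contacts$ord_a, ab$contacts$ord_b),
                  paste(ba$contacts$ord_b, ba$contacts$ord_a))

  # rigid transform of the whole complex
  set.seed(11)
  R <- random_rotation(); tv <- rnorm(3, sd = 20)
  rot <- function(d) {
    x <- as.matrix(d$atoms[, c("x", "y", "z")]) %*% t(R)
    d$atoms$x <- x[, 1] + tv[1]; d$atoms$y <- x[, 2] + tv[2]
    d$atoms$z <- x[, 3] + tv[3]
    d
  }
  ab2 <- build_interface(rot(da), rot(db))
  expect_equal(ab2$L, ab$L)
  expect_equal(ab2$contacts$ord_a, ab$contacts$ord_a)
  expect_equal(ab2$contacts$min_dist, ab$contacts$min_dist,
               tolerance = 1e-8)
})

test_that("enlarging the cutoff never removes a contact", {
  dp <- fix_pair()
  da <- dp$chain$domains[[1]]; db <- dp$chain$domains[[2]]
  prev <- NULL
  for (cut in c(3.5, 4.0, 4.5, 5.0, 6.0)) {
    cur <- heavy_atom_contacts(da, db, cut)
    key <- paste(cur$ord_a, cur$ord_b)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("interface planarity matches closed forms and a numeric oracle", {
  # coplanar points -> 0
  set.seed(2)
  flat <- cbind(runif(12, -5, 5), runif(12, -5, 5), 0)
  ifc <- toy_interface(flat[1:6, ], flat[7:12, ],
                       cbind(1:6, 1:6))
  expect_equal(interface_planarity(ifc), 0, tolerance = 1e-10)

  # points at +-1 A about the plane z = 0, with the deviation pattern
  # orthogonal to 1, x and y so the least-squares plane stays at z = 0
  zpat <- rep(c(1, -1, -1, 1), 4)
  pm <- cbind(rep(1:8, 2), rep(c(0, 8), each = 8), zpat)
  ifc2 <- toy_interface(pm[1:8, ], pm[9:16, ], cbind(1:8, 1:8))
  expect_equal(interface_planarity(ifc2), 1, tolerance = 1e-8)

  # random cloud equals brute-force minimisation over plane parameters
  cloud <- matrix(rnorm(36, sd = 3), ncol = 3)
  ifc3 <- toy_interface(cloud[1:6, ], cloud[7:12, ], cbind(1:6, 1:6))
  expect_equal(interface_planarity(ifc3),
               planarity_oracle(cloud), tolerance = 1e-4)

  tiny <- toy_interface(matrix(0, 1, 3), matrix(1, 1, 3),
                        cbind(1L, 1L))
  expect_error(interface_planarity(tiny), "at least 3")
})
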