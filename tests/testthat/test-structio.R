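test_that("read_model parses minimal Ca-only PDB files", {
  xyz <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  f <- write_pdb_fixture(pdb_lines(xyz))
  s <- read_model(f)
  expect_s3_class(s, "ca_structure")
  expect_equal(length(s), 3L)
  expect_equal(unname(s$ca_coords), xyz, tolerance = 1e-6)
  expect_equal(s$residue_index, 1:3)
})

test_that("read_model keeps the first alternate location only", {
  xyz <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  lines <- pdb_lines(xyz)
  alt_b <- sub("CA ALA", "CA BALA", sub("  1.00", "  0.50",
               pdb_lines(xyz[2, , drop = FALSE] + 50, resno = 2)))
  alt_a <- sub("CA ALA", "CA AALA", pdb_lines(xyz[2, , drop = FALSE],
                                              resno = 2))
  f <- write_pdb_fixture(c(lines[1], alt_a, alt_b, lines[3]))
  s <- read_model(f)
  expect_equal(length(s), 3L)
  expect_equal(unname(s$ca_coords[2, ]), xyz[2, ], tolerance = 1e-6)
})

test_that("read_model drops residues without Ca and errors on empty input", {
  xyz <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  lines <- pdb_lines(xyz)
  lines[2] <- sub("CA ", "CB ", lines[2])   # residue 2 has no Ca
  f <- write_pdb_fixture(lines)
  expect_warning(s <- read_model(f), "without a Ca")
  expect_equal(s$residue_index, c(1L, 3L))

  empty <- tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_model(empty))
})

test_that("structures survive a PDB write/read round trip", {
  s <- make_native(25, seed = 7)
  f <- tempfile(fileext = ".pdb")
  write_model(s, f)
  s2 <- read_model(f)
  expect_equal(s2$ca_coords, s$ca_coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(s2$residue_index, s$residue_index)
  expect_equal(s2$sequence, s$sequence)
})

test_that("distance_map is exact on a 2-residue pair and matches brute force", {
  s <- ca_structure(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE))
  m <- distance_map(s)
  expect_equal(unname(m), matrix(c(0, 3.8, 3.8, 0), 2, 2))

  s5 <- make_native(15, seed = 3)
  m5 <- distance_map(s5)
  brute <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15)
    brute[i, j] <- sqrt(sum((s5$ca_coords[i, ] - s5$ca_coords[j, ])^2))
  expect_equal(unname(m5), brute, tolerance = 1e-12)
})

test_that("distance maps are symmetric with zero diagonal on random structures", {
  for (seed in 1:5) {
    s <- make_native(10 + 7 * seed, seed = seed)
    m <- distance_map(s, scheme = sample(c("ca", "cb"), 1))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(is.finite(m)) && all(m >= 0))
  }
})

test_that("contacts_from_map matches exhaustive enumeration and class bounds", {
  expect_error(contacts_from_map(matrix(0, 3, 3), separation_class = "weird"),
               "unknown separation class")

  far <- matrix(50, 10, 10); diag(far) <- 0
  expect_equal(nrow(contacts_from_map(far, 8, "any")), 0L)

  # long range needs separation >= 24: impossible on a 10-residue map
  s <- make_native(10, seed = 1)
  expect_equal(nrow(contacts_from_map(distance_map(s), 8, "long")), 0L)

  set.seed(42)
  for (rep in 1:4) {
    L <- sample(30:80, 1)
    m <- matrix(0, L, L)
    m[upper.tri(m)] <- runif(L * (L - 1) / 2, 0, 20)
    m <- m + t(m)
    cls <- sample(c("short", "medium", "long", "any"), 1)
    b <- switch(cls, short = c(6, 11), medium = c(12, 23),
                long = c(24, 1e9), any = c(1, 1e9))
    got <- contacts_from_map(m, 8, cls)
    want <- oracle_contacts(m, 8, b[1], b[2])
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) expect_equal(cbind(got$i, got$j), unname(want))
  }
})

test_that("contact sets round trip through RR-style text", {
  s <- make_native(40, seed = 5)
  cs <- contacts_from_map(distance_map(s, "cb"), 8, "medium")
  f <- tempfile(fileext = ".rr")
  write_rr(cs, f)
  back <- read_rr(f, "medium")
  expect_equal(back$i, cs$i)
  expect_equal(back$j, cs$j)
})

test_that("geometry_check flags breaks, clashes, and clean ideal traces", {
  # adjacent Ca at 5.0 A: broken chain (cutoff 4.5 A)
  s <- ca_structure(matrix(c(0, 0, 0, 5, 0, 0, 8.8, 0, 0), 3, 3, byrow = TRUE))
  g <- geometry_check(s)
  expect_false(g$clean)
  expect_equal(nrow(g$breaks), 1L)
  expect_equal(unname(g$breaks[1, ]), c(1L, 2L))

  # non-adjacent Ca at 1.5 A: severe clash (cutoff 1.9 A)
  s2 <- ca_structure(matrix(c(0, 0, 0, 3.8, 0, 0, 0.75, 1.3, 0), 3, 3,
                            byrow = TRUE))
  expect_lt(sqrt(sum((s2$ca_coords[3, ] - s2$ca_coords[1, ])^2)), 1.9)
  g2 <- geometry_check(s2)
  expect_false(g2$clean)
  expect_gte(nrow(g2$clashes), 1L)

  # ideal 3.8 A-spaced extended trace is clean
  ext <- ca_structure(cbind(3.8 * (0:9), 0, 0))
  expect_true(geometry_check(ext)$clean)
})

test_that("perturbing one residue of a clean native creates a violation", {
  for (seed in 1:5) {
    s <- make_native(40, seed = seed)
    expect_true(geometry_check(s)$clean)
    bad <- s
    bad$ca_coords[20, ] <- bad$ca_coords[22, ] + c(0.3, 0, 0) # deep clash
    g <- geometry_check(bad)
    expect_false(g$clean)
  }
})

test_that("distance maps round trip through whitespace text", {
  s <- make_native(12, seed = 2)
  m <- distance_map(s)
  dimnames(m) <- NULL
  f <- tempfile(fileext = ".txt")
  write_distance_map(m, f)
  expect_equal(read_distance_map(f), m, tolerance = 1e-5)
})
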