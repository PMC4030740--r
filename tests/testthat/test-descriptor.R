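test_that("autocorrelate partitions every unordered pair by product sign", {
  one <- newMolecule("one", cbind(0, 0, 0), 0.4)
  ac1 <- autocorrelate(one)
  expect_identical(nrow(positivePairs(ac1)), 0L)
  expect_identical(nrow(negativePairs(ac1)), 0L)

  two <- newMolecule("two", rbind(c(0, 0, 0), c(0, 0, 3)), c(1, 2))
  ac2 <- autocorrelate(two)
  expect_equal(unname(positivePairs(ac2)[1, ]), c(3, 2))
  expect_identical(nrow(negativePairs(ac2)), 0L)

  set.seed(11)
  for (rep in 1:20) {
    m <- randomTestMolecule(sample(3:10, 1))
    ac <- autocorrelate(m)
    got <- rbind(positivePairs(ac), negativePairs(ac))
    expect_identical(nrow(got), (nAtoms(m) * (nAtoms(m) - 1L)) %/% 2L)
    ref <- oraclePairs(m)
    # same multiset of (distance, value) pairs
    ordG <- order(got[, 1], got[, 2])
    ordR <- order(ref$distance, ref$value)
    expect_equal(got[ordG, 1], ref$distance[ordR])
    expect_equal(got[ordG, 2], ref$value[ordR])
    expect_true(all(positivePairs(ac)[, 2] >= 0))
    expect_true(all(negativePairs(ac)[, 2] < 0))
  }
})

test_that("zero products go to the positive part and d = 0 pairs drop", {
  m <- newMolecule("zeroq", rbind(c(0, 0, 0), c(1, 0, 0)), c(0, -0.5))
  ac <- autocorrelate(m)
  expect_identical(nrow(positivePairs(ac)), 1L)
  expect_equal(unname(positivePairs(ac)[1, 2]), 0)

  co <- newMolecule("coincident", rbind(c(1, 1, 1), c(1, 1, 1)), c(1, 1))
  expect_warning(ac2 <- autocorrelate(co), "coincident")
  expect_identical(nrow(positivePairs(ac2)), 0L)
})

test_that("linBin splits mass linearly between flanking grid points", {
  # on-grid distance: full mass on its own grid point
  expect_equal(linBin(1.0, 2.0, dx = 0.5), c(0, 0, 2, 0))
  # midpoint: symmetric split
  expect_equal(linBin(0.75, 2.0, dx = 0.5), c(0, 1, 1))
  # empty input, bad dx
  expect_identical(linBin(numeric(0), numeric(0), 0.005), numeric(0))
  expect_error(linBin(1, 1, dx = 0), "positive")
  expect_error(linBin(1, 1, dx = -0.1), "positive")
})

test_that("linBin conserves mass and matches per-pair accumulation", {
  set.seed(5)
  for (rep in 1:5) {
    d <- runif(100, 0.1, 12)
    v <- rnorm(100)
    got <- linBin(d, v, 0.005)
    expect_lt(abs(sum(got) - sum(v)) / max(abs(sum(v)), 1e-12), 1e-9)
    ref <- oracleLinbin(d, v, 0.005)
    expect_identical(length(got), length(ref))
    expect_lt(max(abs(got - ref)), 1e-12 * max(1, max(abs(ref))))
  }
})

test_that("encode matches the brute-force re-derivation on small molecules", {
  set.seed(23)
  for (rep in 1:40) {
    m <- randomTestMolecule(sample(1:8, 1))
    d <- encodeMolecule(m, dx = 0.005)
    ref <- oracleEncode(m, 0.005)
    expect_identical(length(lbacPlus(d)), length(ref$plus))
    expect_identical(length(lbacMinus(d)), length(ref$minus))
    scale <- max(1e-12, abs(ref$plus), abs(ref$minus))
    expect_lte(max(abs(lbacPlus(d) - ref$plus), 0) / scale, 1e-9)
    expect_lte(max(abs(lbacMinus(d) - ref$minus), 0) / scale, 1e-9)
  }
})

test_that("encoding is deterministic and degenerate inputs behave", {
  m <- randomTestMolecule(12)
  expect_descriptor_equal(encodeMolecule(m, 0.005), encodeMolecule(m, 0.005))

  single <- newMolecule("single", cbind(1, 2, 3), -0.2)
  d1 <- encodeMolecule(single, 0.005)
  expect_identical(lbacPlus(d1), numeric(0))
  expect_identical(lbacMinus(d1), numeric(0))

  allzero <- newMolecule("allzero", rbind(c(0, 0, 0), c(2, 0, 0)), c(0, 0))
  d0 <- encodeMolecule(allzero, 0.005)
  expect_true(all(lbacPlus(d0) == 0))
  expect_identical(lbacMinus(d0), numeric(0))
})

test_that("dx outside the recommended range warns but works", {
  m <- randomTestMolecule(5)
  expect_warning(encodeMolecule(m, 0.5), "recommended range")
  expect_warning(encodeMolecule(m, 0.0005), "recommended range")
  expect_error(encodeMolecule(m, 0), "positive")
})

test_that("descriptor is invariant under translation, rotation, permutation", {
  set.seed(31)
  for (rep in 1:15) {
    m <- randomTestMolecule(sample(3:25, 1))
    ref <- encodeMolecule(m, 0.005)
    tr <- rigidTransform(m, translation = runif(3, -50, 50))
    expect_descriptor_equal(encodeMolecule(tr, 0.005), ref, tol = 1e-12)
    rot <- rigidTransform(m, rotation = randomRotation())
    expect_descriptor_equal(encodeMolecule(rot, 0.005), ref, tol = 1e-9)
    perm <- sample(nAtoms(m))
    shuf <- newMolecule(molName(m), atomCoords(m)[perm, , drop = FALSE],
                        atomCharges(m)[perm])
    expect_descriptor_equal(encodeMolecule(shuf, 0.005), ref, tol = 1e-12)
  }
})

test_that("mirror images and charge-flipped copies encode identically", {
  set.seed(37)
  for (rep in 1:10) {
    m <- randomTestMolecule(sample(3:20, 1))
    ref <- encodeMolecule(m, 0.005)
    expect_descriptor_equal(encodeMolecule(mirrorMolecule(m), 0.005), ref)
    expect_descriptor_equal(encodeMolecule(flipCharges(m), 0.005), ref)
  }
})

test_that("scaling all charges by c scales every bin by c^2", {
  set.seed(41)
  m <- randomTestMolecule(15)
  ref <- encodeMolecule(m, 0.005)
  c0 <- 2.5
  scaled <- newMolecule(molName(m), atomCoords(m), c0 * atomCharges(m))
  ds <- encodeMolecule(scaled, 0.005)
  expect_equal(lbacPlus(ds), c0^2 * lbacPlus(ref), tolerance = 1e-9)
  expect_equal(lbacMinus(ds), c0^2 * lbacMinus(ref), tolerance = 1e-9)
})

test_that("binned mass equals the sum of all charge products", {
  set.seed(43)
  for (rep in 1:20) {
    m <- randomTestMolecule(sample(2:30, 1))
    d <- encodeMolecule(m, 0.005)
    p <- oraclePairs(m)
    total <- sum(p$value)
    got <- sum(lbacPlus(d)) + sum(lbacMinus(d))
    expect_lt(abs(got - total) / max(abs(total), 1e-12), 1e-9)
  }
})

test_that("the autocorrelogram dump is two labelled numeric columns", {
  m <- randomTestMolecule(6)
  d <- encodeMolecule(m, 0.005)
  f <- withr::local_tempfile()
  writeAutocorrelogram(d, f)
  lines <- readLines(f)
  expect_identical(sum(startsWith(lines, "#")), 2L)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  expect_identical(length(body),
                   length(lbacPlus(d)) + length(lbacMinus(d)))
})
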