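test_that("rank-1 data concentrate all variance in the first mode", {
  eof <- computeEOF(fixtureMovie("rank1"))
  nz <- normalizedEigenvalues(eof)
  expect_equal(nz[1], 100, tolerance = 1e-8)
  # a permissive loading threshold keeps even the faintest pixels of the
  # common pattern classified
  cls <- classifyPixels(eof, nComponents = 1, threshold = 0.4)
  expect_true(all(cls@labels == 1))
})

test_that("orthogonal equal-power subspaces split 50/50", {
  eof <- computeEOF(fixtureMovie("sincos-50-50"))
  nz <- normalizedEigenvalues(eof)
  expect_equal(nz[1], 50, tolerance = 1e-6)
  expect_equal(nz[2], 50, tolerance = 1e-6)
  # classification recovers the two pixel groups exactly (up to swap)
  cls <- classifyPixels(eof)
  lab <- cls@labels
  expect_true(all(lab[1:20] == lab[1]) && all(lab[21:40] == lab[21]))
  expect_true(lab[1] != lab[21])
})

test_that("normalized eigenvalues always sum to 100 percent", {
  A <- matrix(withr::with_seed(7, rnorm(70 * 30)), 70, 30)
  expect_equal(sum(normalizedEigenvalues(computeEOF(A))), 100,
               tolerance = 1e-6)
  expect_equal(sum(normalizedEigenvalues(computeEOF(fixtureMovie("white-noise")))),
               100, tolerance = 1e-6)
})

test_that("EOF equals the SVD oracle across matrix shapes", {
  for (dims in list(c(30, 10), c(50, 50), c(40, 120))) {
    A <- matrix(withr::with_seed(sum(dims), rnorm(prod(dims))),
                dims[1], dims[2])
    eof <- computeEOF(A, center = TRUE)
    Ac <- sweep(A, 2, colMeans(A))
    sv <- svd(Ac)
    k <- length(eigenvalues(eof))
    expect_equal(eigenvalues(eof)[seq_len(min(k, length(sv$d)))],
                 (sv$d^2)[seq_len(min(k, length(sv$d)))], tolerance = 1e-8)
    # loadings match up to sign
    for (i in 1:3)
      expect_equal(abs(eofVectors(eof)[, i]), abs(sv$v[, i]),
                   tolerance = 1e-6)
    # energy conservation: total variance is the squared Frobenius norm
    expect_equal(sum(eigenvalues(eof)), sum(Ac^2), tolerance = 1e-8)
    # reconstruction from all retained modes
    recon <- eofModes(eof) %*% t(eofVectors(eof))
    expect_equal(recon, Ac, tolerance = 1e-8)
    # orthonormal loadings
    G <- crossprod(eofVectors(eof))
    expect_equal(G, diag(nrow(G)), tolerance = 1e-8)
  }
})

test_that("degenerate input is rejected, movies are accepted", {
  expect_error(computeEOF(matrix(0, 50, 4)), "zero")
  eof <- computeEOF(fixtureMovie("two-cluster-periods"))
  expect_s4_class(eof, "EOFResult")
  expect_output(show(eof), "modes")
})

test_that("noise pixels stay unclassified under a strict threshold", {
  eof <- computeEOF(fixtureMovie("white-noise"))
  cls <- classifyPixels(eof, threshold = 2)
  expect_gt(mean(is.na(cls@labels)), 0.5)
})

test_that("classified modes recover the imposed split periods", {
  mov <- fixtureMovie("two-cluster-periods")
  eof <- computeEOF(mov)
  cls <- classifyPixels(eof, movie = mov)
  m1 <- median(cls@periods$component1)
  m2 <- median(cls@periods$component2)
  # the stronger 21-h cluster leads; medians differ by the imposed 11 h
  expect_equal(sort(c(m1, m2)), c(21, 32), tolerance = 0.01)
  expect_equal(abs(m1 - m2), 11, tolerance = 0.2)
})
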