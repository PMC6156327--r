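test_that("constructor enforces parameter invariants", {
  expect_s3_class(emt_model(1.1, 8), "emt_model")
  expect_error(emt_model(-0.1, 8), "must be >= 0")
  expect_error(emt_model(1.1, -2), "must be >= 0")
  expect_error(emt_model(1, 1, k1 = 0), "must be > 0")
  expect_error(emt_model(1, 1, theta = 0), "theta")
  expect_error(emt_model(1, 1, n1 = 1.5), "positive integer")
  expect_error(emt_model(1, 1, n2 = 0), "positive integer")
  expect_error(emt_model(NA, 1), "finite")
  # defaults are the published circuit constants
  p <- coef(emt_model(0, 0))
  expect_identical(p[c("n1", "n2", "n3")], c(n1 = 2, n2 = 6, n3 = 3))
  expect_identical(p[c("c", "k1", "k2", "theta")],
                   c(c = 1, k1 = 1, k2 = 1, theta = 0.5))
})

test_that("drift has the closed-form values at the Hill anchor points", {
  for (b in c(0, 3, 8)) {
    m <- emt_model(a = 1.7, b = b)
    # at the origin: activation off, both repressions at full strength
    expect_equal(as.numeric(drift(m, c(0, 0))), c(1.0, b))
    # at (theta, theta): every Hill term at half saturation
    expect_equal(as.numeric(drift(m, c(0.5, 0.5))),
                 c(1.7 / 2, b / 2 - 0.5))
  }
  expect_error(drift(emt_model(1, 1), c(-1, 0)), ">= 0")
  expect_error(drift(emt_model(1, 1), c(1, NaN)), "finite")
})

test_that("drift is bounded and inward on the invariant box", {
  set.seed(11)
  for (rep in 1:20) {
    m <- emt_model(a = runif(1, 0, 2.5), b = runif(1, 0, 45))
    x <- cbind(runif(50, 0, 4), runif(50, 0, 50))
    f <- drift(m, x)
    expect_true(all(is.finite(f)))
    # production terms bounded: F1 <= a + c - k1 x1, F2 <= b - k2 x2
    expect_true(all(f[, 1] <= m$a + m$c - m$k1 * x[, 1] + 1e-12))
    expect_true(all(f[, 2] <= m$b - m$k2 * x[, 2] + 1e-12))
    # beyond the box the flow points back in
    expect_lt(drift(m, c((m$a + m$c) / m$k1 + 0.1, 1))[, 1], 0)
    expect_lt(drift(m, c(1, m$b / m$k2 + 0.1))[, 2], 0)
  }
})

test_that("analytic Jacobian matches central differences and sign structure", {
  m <- emt_model(a = 0.9, b = 8)
  # half-saturation point: dF1/dx1 = a n1/(4 theta) - k1 = a - 1 at defaults
  J <- jacobian(m, c(0.5, 0.5))
  expect_equal(J[1, 1], 0.9 - 1)
  expect_equal(J[2, 2], -m$k2)
  set.seed(21)
  h <- 1e-6
  for (rep in 1:100) {
    m <- emt_model(a = runif(1, 0, 2.5), b = runif(1, 0, 45))
    x <- c(runif(1, 0.01, 3), runif(1, 0.01, 10))
    J <- jacobian(m, x)
    num <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      num[, j] <- (drift(m, x + e) - drift(m, x - e)) / (2 * h)
    }
    expect_close(J, num, 1e-5)
    expect_lte(J[1, 2], 0)  # miR-200 represses ZEB
    expect_lte(J[2, 1], 0)  # ZEB represses miR-200
    expect_equal(J[2, 2], -m$k2)
  }
})

test_that("scalar reduction: roots, sign structure, and lift to 2-D", {
  # a = b = 0 forces x2 = 0 and kills autoactivation: root exactly at c/k1
  m0 <- emt_model(a = 0, b = 0)
  expect_equal(steady_residual(m0, 1), 0)
  # the tristable point has five sign changes on a dense grid
  m <- emt_model(a = 1.1, b = 8)
  xs <- seq(0, 1.5 * (m$a + m$c), length.out = 1e5)
  g <- steady_residual(m, xs)
  expect_identical(sum(diff(sign(g)) != 0), 5L)
  # beyond the production bound g is negative for any parameters
  set.seed(31)
  for (rep in 1:20) {
    mr <- emt_model(a = runif(1, 0, 3), b = runif(1, 0, 45))
    expect_lt(steady_residual(mr, (mr$a + mr$c) / mr$k1 + 1), 0)
  }
  # roots of g, lifted by the miR nullcline, are zeros of the full field
  fp <- fixed_points(m)
  expect_close(drift(m, cbind(fp$x1, fp$x2)), 0, 1e-9)
  expect_equal(fp$x2, mirna_nullcline(m, fp$x1))
})

test_that("model configuration round-trips through the flat key-value file", {
  m <- emt_model(a = 1.1, b = 8, c = 0.7, k1 = 1.2, k2 = 0.9, n1 = 3,
                 theta = 0.41)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_identical(coef(m), coef(m2))
  # keys are exactly the canonical parameter names
  keys <- trimws(vapply(strsplit(readLines(path), "="), `[`, "", 1))
  expect_identical(keys, c("a", "b", "c", "k1", "k2", "n1", "n2", "n3",
                           "theta"))
})
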