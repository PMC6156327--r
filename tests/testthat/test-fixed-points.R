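test_that("the printed tristable point has three stable states E/HYBRID/M", {
  fp <- fixed_points(emt_model(a = 1.1, b = 8))
  expect_identical(nrow(fp), 5L)
  st <- fp[fp$stability == "stable", ]
  expect_identical(nrow(st), 3L)
  expect_identical(sort(st$phenotype), c("E", "HYBRID", "M"))
  # locations frozen from the dense-bracketing oracle (grid 1e5 + polish)
  st <- st[order(st$x1), ]
  expect_lt(st$x1[1], 1e-6)               # E: ZEB fully repressed
  expect_equal(st$x2[1], 8.0, tolerance = 1e-4)
  expect_equal(st$x1[2], 0.7809, tolerance = 1e-3)
  expect_equal(st$x2[2], 1.6634, tolerance = 1e-3)
  expect_equal(st$x1[3], 2.0374, tolerance = 1e-3)
  expect_equal(st$x2[3], 0.1165, tolerance = 1e-3)
  # the two interior unstable points are saddles
  expect_identical(fp$stability[!fp$stability == "stable"],
                   c("saddle", "saddle"))
  expect_lt(max(abs(fp$residual)), 1e-9)
})

test_that("with no signal the only state is the mesenchymal one at (1, 0)", {
  fp <- fixed_points(emt_model(a = 0, b = 0))
  expect_identical(nrow(fp), 1L)
  expect_equal(fp$x1, 1)
  expect_equal(fp$x2, 0)
  expect_identical(fp$stability, "stable")
  expect_identical(fp$phenotype, "M")
  # one eigenvalue is exactly -k2 (the miR equation is linear in x2)
  expect_equal(sort(c(fp$re1, fp$re2))[2], -1)
})

test_that("phenotype rule: E below theta in ZEB, M below theta in miR", {
  m <- emt_model(1.1, 8)
  expect_identical(label_phenotype(m, 1e-7, 8), "E")
  expect_identical(label_phenotype(m, 0.78, 1.66), "HYBRID")
  expect_identical(label_phenotype(m, 2.04, 0.12), "M")
  expect_identical(label_phenotype(m, 1, 0), "M")
})

test_that("stability labels agree with long-time integration of the flow", {
  skip_if_not_installed("deSolve")
  m <- emt_model(a = 1.1, b = 8)
  fp <- fixed_points(m)
  for (i in seq_len(nrow(fp))) {
    lab <- classify_stability(m, c(fp$x1[i], fp$x2[i]))
    end <- ode_endpoint(m, c(fp$x1[i] + 0.03, fp$x2[i] + 0.03), 200)
    ret <- sqrt(sum((end - c(fp$x1[i], fp$x2[i]))^2)) < 1e-5
    if (lab == "stable") expect_true(ret) else expect_false(ret)
  }
})

test_that("scalar-reduction roots match the 2-D sign-grid oracle", {
  set.seed(41)
  for (rep in 1:20) {
    m <- emt_model(a = runif(1, 0, 2.5), b = runif(1, 0.5, 45))
    fp <- fixed_points(m)
    orc <- oracle_fixed_points_2d(m, n = 400)
    sp <- c(1.5 * (m$a + m$c) / 400, 1.5 * m$b / 400)
    # merge near-degenerate pairs below oracle resolution before comparing
    dedup <- function(x1, x2) {
      o <- order(x1)
      x1 <- x1[o]; x2 <- x2[o]
      keep <- c(TRUE, diff(x1) > 2 * sp[1])
      cbind(x1[keep], x2[keep])
    }
    a1 <- dedup(fp$x1, fp$x2)
    a2 <- dedup(orc[, 1], orc[, 2])
    expect_identical(nrow(a1), nrow(a2))
    expect_close(a1[, 1], a2[, 1], 2 * sp[1])
    expect_close(a1[, 2], a2[, 2], 2 * sp[2])
  }
})

test_that("nullclines: explicit miR graph, x1-axis at b = 0, crossings", {
  m <- emt_model(1.1, 8)
  nc <- nullclines(m, n = 400)
  expect_equal(nc$mirna$x2, mirna_nullcline(m, nc$mirna$x1))
  expect_equal(mirna_nullcline(emt_model(1, 0), c(0, 0.5, 2)), c(0, 0, 0))
  # every fixed point sits within grid distance of a ZEB-nullcline point
  fp <- fixed_points(m)
  zeb <- do.call(rbind, nc$zeb)
  h <- max(diff(nc$xlim), diff(nc$ylim)) / 400
  for (i in seq_len(nrow(fp))) {
    d <- sqrt((zeb$x1 - fp$x1[i])^2 + (zeb$x2 - fp$x2[i])^2)
    expect_lt(min(d), 3 * h)
  }
})

test_that("marginal eigenvalues are refused unless opted into", {
  # with the miR leg off (b = c = 0) the ZEB equation x' = a h(x) - x has an
  # exact saddle-node at a = 1 (double root at x1 = theta = 0.5, J11 = 0)
  m <- emt_model(a = 1, b = 0, c = 0)
  expect_equal(as.numeric(drift(m, c(0.5, 0))), c(0, 0))
  expect_identical(classify_stability(m, c(0.5, 0), marginal = "label"),
                   "marginal")
  expect_error(classify_stability(m, c(0.5, 0)), "near-bifurcation")
  # away from the bifurcation the labels are definite
  m2 <- emt_model(a = 1.1, b = 8)
  expect_identical(classify_stability(m2, c(2.037351, 0.116528)), "stable")
})
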