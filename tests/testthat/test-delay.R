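test_that("zero delay degenerates to the undelayed stepper exactly", {
  m <- emt_model(1.1, 8)
  t0 <- simulate(m, x0 = c(0.3, 2), t_end = 2, D = 0, tau = 0)
  t1 <- simulate(m, x0 = c(0.3, 2), t_end = 2, D = 0)
  expect_identical(t0$x1, t1$x1)
  # with noise, same seed: identical stream
  s0 <- simulate(m, seed = 4, x0 = c(0.3, 2), t_end = 2, D = 0.02, tau = 0)
  s1 <- simulate(m, seed = 4, x0 = c(0.3, 2), t_end = 2, D = 0.02)
  expect_identical(s0$x1, s1$x1)
})

test_that("ring buffer matches a full-history reference integration", {
  m <- emt_model(1.1, 8)
  for (tau in c(0.05, 0.5, 2)) {
    tr <- simulate(m, x0 = c(1.8, 0.4), t_end = 5, dt = 0.005, D = 0,
                   tau = tau)
    ref <- reference_stepper(m, c(1.8, 0.4), 0.005, 1000,
                             tau_steps = round(tau / 0.005))
    expect_identical(cbind(tr$x1, tr$x2), unname(ref))
  }
  # and under noise with a shared RNG stream (equal up to floating-point
  # association of the three-term update)
  tr <- simulate(m, seed = 17, x0 = c(1.8, 0.4), t_end = 5, dt = 0.005,
                 D = 0.01, tau = 0.5)
  set.seed(17)
  ref <- reference_stepper(m, c(1.8, 0.4), 0.005, 1000, D = 0.01,
                           tau_steps = 100)
  expect_equal(cbind(tr$x1, tr$x2), unname(ref), tolerance = 1e-12)
})

test_that("without noise the outcome depends on the start, not the delay", {
  # bistable point, mesenchymal start: M for every delay
  sc <- tau_scan(emt_model(0.1, 1), D = 0, start = "M",
                 tau_values = c(0, 1, 5, 20), t_end = 100)
  expect_identical(unique(sc$reps$final), "M")
  # tristable point, epithelial start: E for every delay
  sc <- tau_scan(emt_model(1.1, 8), D = 0, start = "E",
                 tau_values = c(0, 1, 5, 20), t_end = 100)
  expect_identical(unique(sc$reps$final), "E")
  # deterministic replicates are identical
  sc <- tau_scan(emt_model(1.1, 8), D = 0, start = "M", tau_values = c(0, 5),
                 n_reps = 3, t_end = 100)
  byrep <- split(sc$reps$late_mean_x1, sc$reps$tau)
  for (v in byrep) expect_identical(length(unique(v)), 1L)
})

test_that("trajectory classification: labels, dwell sequence, oscillation", {
  m <- emt_model(1.1, 8)
  att <- fixed_points(m)
  M <- att[att$stability == "stable" & att$phenotype == "M", ]
  # constant trajectory at an attractor
  tr <- simulate(m, x0 = c(M$x1, M$x2), t_end = 100, D = 0, thin = 10)
  oc <- classify_trajectory(tr)
  expect_identical(oc$final, "M")
  expect_identical(oc$visited, "M")
  expect_false(oc$oscillating)
  # deterministic relaxation into the epithelial attractor is labelled E
  tr <- simulate(m, x0 = c(0.3, 7), t_end = 150, D = 0, thin = 10)
  expect_identical(classify_trajectory(tr)$final, "E")
  # synthetic sine of amplitude 2 * osc_tol flips the oscillation flag
  tr2 <- tr
  tr2$x1 <- 1 + 0.2 * sin(tr2$t)
  expect_true(classify_trajectory(tr2, m, osc_tol = 0.1)$oscillating)
  # a window longer than the trajectory is refused
  expect_error(classify_trajectory(tr[1:3, ], m), "window")
})

test_that("deterministic final labels are unchanged by halving dt", {
  m <- emt_model(1.1, 8)
  for (start in c("E", "M")) for (tau in c(0, 5)) {
    att <- emtdyn:::stable_attractors(m)
    a <- c(tau_scan(m, 0, start, tau, n_reps = 1, t_end = 100,
                    dt = 0.005)$summary$majority,
           tau_scan(m, 0, start, tau, n_reps = 1, t_end = 100,
                    dt = 0.0025)$summary$majority)
    expect_identical(a[1], a[2])
  }
})

test_that("delay scan bookkeeping: ordering, counts, determinism", {
  m <- emt_model(1.1, 8)
  sc <- tau_scan(m, D = 0.02, start = "HYBRID", tau_values = c(0, 2, 5),
                 n_reps = 4, seed = 9, t_end = 60)
  expect_identical(sc$summary$tau, c(0, 2, 5))
  expect_identical(nrow(sc$reps), 12L)
  expect_true(all(table(sc$reps$tau) == 4))
  sc2 <- tau_scan(m, D = 0.02, start = "HYBRID", tau_values = c(0, 2, 5),
                  n_reps = 4, seed = 9, t_end = 60)
  expect_identical(sc$reps$late_mean_x1, sc2$reps$late_mean_x1)
  expect_error(tau_scan(emt_model(0, 0), 0.01, "E", c(0, 1)), "no stable")
})
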