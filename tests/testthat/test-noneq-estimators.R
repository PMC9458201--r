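test_that("CFT-ML solves the self-consistency equation", {
  # crossing point of identical degenerate distributions
  ws <- work_set(rep(1.7, 5), rep(-1.7, 5))
  expect_equal(cft_ml_estimate(ws)$value, 1.7, tolerance = 1e-9)
  # two-sample symbolic solution (W_F - W_R)/2 at equal counts
  expect_equal(cft_ml_estimate(work_set(3.0, -1.0))$value, 2.0,
               tolerance = 1e-9)
  # recovery of the generating dG
  ws <- gen_crooks_work(-1.40, 1.0, 2000, 2000, seed = 17)
  est <- cft_ml_estimate(ws)$value
  se <- bootstrap_uncertainty(ws, n_boot = 200, seed = 18)
  expect_lt(abs(est - (-1.40)), 3 * se)
})

test_that("CFT-ML root matches an independent grid-scan oracle", {
  set.seed(31)
  for (i in 1:50) {
    nf <- sample(1:20, 1); nr <- sample(1:20, 1)
    ws <- work_set(rnorm(nf, sd = 2) + runif(1, -3, 3),
                   rnorm(nr, sd = 2) + runif(1, -3, 3))
    expect_equal(cft_ml_estimate(ws)$value, cft_gridscan(ws),
                 tolerance = 1e-6)
  }
})

test_that("CFT-ML is antisymmetric and shift-equivariant", {
  set.seed(5)
  for (i in 1:10) {
    ws <- work_set(rnorm(30, 2, 1.5), rnorm(25, -1, 1.5))
    dg <- cft_ml_estimate(ws)$value
    swapped <- work_set(ws$reverse_works, ws$forward_works,
                        temperature = ws$temperature)
    expect_lt(abs(dg + cft_ml_estimate(swapped)$value), 1e-9)
    cshift <- runif(1, -5, 5)
    shifted <- work_set(ws$forward_works + cshift, ws$reverse_works - cshift)
    expect_equal(cft_ml_estimate(shifted)$value, dg + cshift,
                 tolerance = 1e-9)
  }
})

test_that("CFT-ML recovers ground truth with calibrated bootstrap errors", {
  study <- crooks_recovery_study(dg_true = -1.40, sigma_w = 1.0, n = 2000,
                                 n_seeds = 20, n_boot = 100)
  expect_lt(abs(mean(study$est) - study$dg_true), 0.05)
  covered <- abs(study$est - study$dg_true) <= 2 * study$se
  expect_gte(mean(covered), 0.80)
})

test_that("Jarzynski estimator obeys its closed forms", {
  expect_equal(jarzynski_estimate(rep(2.5, 8))$value, 2.5, tolerance = 1e-12)
  expect_equal(jarzynski_estimate(0.7)$value, 0.7)
  # Gaussian cumulant identity: dG -> mu - beta sigma^2/2
  set.seed(11)
  beta <- 1 / (KB_KCAL * 298)
  w <- rnorm(2e5, mean = 1.0, sd = 0.5)
  expect_equal(jarzynski_estimate(w)$value, 1.0 - beta * 0.5^2 / 2,
               tolerance = 0.02)
  # reverse direction flips the sign convention
  expect_equal(jarzynski_estimate(rep(-2.5, 4), direction = "reverse")$value,
               2.5)
  expect_error(jarzynski_estimate(numeric(0)), "at least one")
})

test_that("bootstrap uncertainty is seeded, zero for constants, shrinks with n", {
  ws <- work_set(rep(1, 10), rep(-1, 10))
  expect_equal(bootstrap_uncertainty(ws, n_boot = 50, seed = 1), 0)
  ws2 <- gen_crooks_work(-1, 1, 200, 200, seed = 3)
  expect_identical(bootstrap_uncertainty(ws2, n_boot = 100, seed = 4),
                   bootstrap_uncertainty(ws2, n_boot = 100, seed = 4))
  expect_error(bootstrap_uncertainty(ws2, n_boot = 1), "n_boot")
  # sqrt(n) trend: doubling n reduces the median bootstrap SE over seeds
  ses <- sapply(1:10, function(s) {
    small <- gen_crooks_work(-1, 1, 100, 100, seed = s)
    big <- gen_crooks_work(-1, 1, 200, 200, seed = 100 + s)
    c(small = bootstrap_uncertainty(small, n_boot = 60, seed = s),
      big = bootstrap_uncertainty(big, n_boot = 60, seed = s))
  })
  expect_lt(median(ses["big", ]), median(ses["small", ]))
})

test_that("work overlap matches limits and the Gaussian closed form", {
  ws <- gen_crooks_work(-2, 1, 500, 500, seed = 8)
  same <- work_set(ws$forward_works, -ws$forward_works)
  expect_equal(work_overlap(same), 1.0, tolerance = 1e-12)
  apart <- work_set(rnorm(200), -(rnorm(200) + 1e4))
  expect_lt(work_overlap(apart), 1e-6)
  # equal-variance normals separated by dmu = beta sigma^2:
  # BC = exp(-dmu^2/(8 sigma^2))
  beta <- 1 / (KB_KCAL * 298)
  sw <- sqrt(2 / beta)                            # beta sigma^2 = 2
  big <- gen_crooks_work(0, sw, 4e4, 4e4, seed = 12)
  bc_true <- exp(-(beta * sw^2)^2 / (8 * sw^2))
  expect_equal(work_overlap(big), bc_true, tolerance = 0.03)
})

test_that("dH/dlambda traces integrate to work values by trapezoid", {
  lam <- seq(0, 1, length.out = 11)
  # dH/dl = 2*lam integrates to 1; dH/dl = 3*lam^2 trapezoid gives 1.005
  df <- rbind(
    data.frame(transition = 1, direction = "forward", lambda = lam,
               dhdl = 2 * lam),
    data.frame(transition = 2, direction = "forward", lambda = lam,
               dhdl = 3 * lam^2),
    data.frame(transition = 3, direction = "reverse", lambda = lam,
               dhdl = -2 * lam))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  ws <- read_work_tsv(tmp)
  expect_equal(sort(ws$forward_works), c(1, sum(diff(lam) *
    (head(3 * lam^2, -1) + tail(3 * lam^2, -1)) / 2)), tolerance = 1e-12)
  expect_equal(ws$reverse_works, -1, tolerance = 1e-12)
})

test_that("estimate_work_set bundles value, error and overlap", {
  ws <- gen_crooks_work(-1.4, 1, 400, 400, seed = 21)
  est <- estimate_work_set(ws, n_boot = 100, seed = 2)
  expect_s3_class(est, "free_energy_estimate")
  expect_gt(est$uncertainty, 0)
  expect_true(est$overlap > 0 && est$overlap <= 1)
  expect_equal(est$n_bootstrap, 100L)
})

test_that("degenerate non-overlapping inputs fail with a diagnostic", {
  expect_error(work_set(numeric(0), 1), "non-empty")
  expect_error(work_set(c(1, Inf), -1), "finite")
})
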