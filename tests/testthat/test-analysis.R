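# Trajectory post-processing: speed estimation, MSD and its through-origin
# fits, and the chemotactic index.

test_that("speed estimate recovers a noiseless linear drift exactly", {
  tt <- 0:500
  ens <- lapply(1:5, function(k) fake_traj(3 + 0.002 * tt))
  sp <- estimate_speed(ens)
  expect_equal(sp$slope, 0.002, tolerance = 1e-12)
  expect_equal(sp$stderr, 0)
  expect_equal(sp$mean_mr_per_tau, 2, tolerance = 1e-9)
  expect_equal(sp$n_replicates, 5L)
})

test_that("speed estimate of an unbiased random walk is consistent with zero", {
  set.seed(21)
  ens <- lapply(1:100, function(k) fake_traj(cumsum(c(0, rnorm(800, 0, 0.1)))))
  sp <- estimate_speed(ens)
  expect_lt(abs(sp$slope), 3 * sp$stderr)
})

test_that("speed estimate is translation-invariant and reflects with the axis", {
  set.seed(22)
  com <- cumsum(c(0, rnorm(300, 0.01, 0.2)))
  ens <- lapply(1:4, function(k) fake_traj(com + k))
  shifted <- lapply(1:4, function(k) fake_traj(com + k + 100))
  flipped <- lapply(1:4, function(k) fake_traj(-(com + k)))
  expect_equal(estimate_speed(ens)$slope, estimate_speed(shifted)$slope)
  expect_equal(estimate_speed(flipped)$slope, -estimate_speed(ens)$slope)
})

test_that("speed estimation validates its inputs", {
  expect_error(estimate_speed(list(fake_traj(1:10))), "2 replicates")
  expect_error(estimate_speed(list(fake_traj(1:10), fake_traj(1:9))),
               "unequal")
  ens <- lapply(1:3, function(k) fake_traj(seq(0, 1, length.out = 11)))
  expect_error(estimate_speed(ens, burn_in = 10), "burn_in")
})

test_that("MSD closed forms: stationary, ballistic, diffusive", {
  ens0 <- lapply(1:3, function(k) fake_traj(rep(2, 101)))
  expect_true(all(compute_msd(ens0)$msd == 0))
  v <- 0.004
  ensb <- lapply(1:3, function(k) fake_traj(v * (0:100)))
  mb <- compute_msd(ensb)
  expect_equal(mb$msd, v^2 * (0:100)^2, tolerance = 1e-12)
  # unbiased random walk with step variance q: MSD(t) ~ q t
  set.seed(33)
  q <- 0.04
  ensd <- lapply(1:10000, function(k)
    fake_traj(cumsum(c(0, rnorm(100, 0, sqrt(q))))))
  md <- compute_msd(ensd)
  expect_equal(md$msd[101], q * 100, tolerance = 0.05)
  fit <- fit_msd(md, 1)
  expect_equal(unname(fit$coefficients["a"]), q, tolerance = 0.03)
})

test_that("through-origin fits recover exact polynomials with R^2 = 1", {
  line <- lapply(1:2, function(k) fake_traj(sqrt(3 * (0:50))))
  f1 <- suppressWarnings(fit_msd(compute_msd(line), 1))  # exact fit
  expect_equal(unname(f1$coefficients["a"]), 3, tolerance = 1e-10)
  expect_equal(f1$r_squared, 1)
  par <- lapply(1:2, function(k) fake_traj(0:50))
  f2 <- suppressWarnings(fit_msd(compute_msd(par), 2))
  expect_equal(unname(f2$coefficients["a"]), 0, tolerance = 1e-8)
  expect_equal(unname(f2$coefficients["b"]), 1, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1)
  short <- lapply(1:2, function(k) fake_traj(c(0, 1)))
  expect_error(fit_msd(compute_msd(short), 2), "distinct")
})

test_that("directed ensembles are quadratic, undirected ones linear", {
  ens_g <- run_ensemble(ref_config(T = 15, n_steps = 1500), 60,
                        base_seed = 500)
  ens_0 <- run_ensemble(ref_config(grad = 1, T = 15, n_steps = 1500), 60,
                        base_seed = 700)
  mg2 <- fit_msd(compute_msd(ens_g), 2)
  mg1 <- fit_msd(compute_msd(ens_g), 1)
  # ballistic signature: positive quadratic term, and the quadratic model
  # beats the linear one
  expect_gt(unname(mg2$coefficients["b"]), 0)
  expect_gt(mg2$r_squared, mg1$r_squared)
  # no gradient: quadratic coefficient within noise of zero, assessed by
  # bootstrap over replicates (lag points are strongly correlated, so the
  # regression standard error is not a valid noise scale)
  m02 <- fit_msd(compute_msd(ens_0), 2)
  set.seed(44)
  boot_b <- replicate(200, {
    idx <- sample(ncol(ens_0$com), replace = TRUE)
    sub <- structure(list(com = ens_0$com[, idx]), class = "cohesim_ensemble")
    unname(fit_msd(compute_msd(sub), 2)$coefficients["b"])
  })
  expect_lt(abs(unname(m02$coefficients["b"])), 3 * sd(boot_b))
})

test_that("chemotactic index spans [-1, 1] with the expected landmarks", {
  expect_equal(chemotactic_index(c(0, 1, 2, 3)), 1)
  expect_equal(chemotactic_index(c(0, 2, 0)), 0)
  expect_equal(chemotactic_index(c(3, 2, 1)), -1)
  expect_equal(chemotactic_index(c(0, 2, 1)), 1 / 3)
  expect_warning(ci <- chemotactic_index(rep(1, 5)), "zero path")
  expect_true(is.na(ci))
})
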