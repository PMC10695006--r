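test_that("prior samples are standard normal and reproducible", {
  z <- sample_prior(2e4, 8, rng_seed = 3)
  expect_identical(dim(z), c(2e4L, 8L))
  se <- 1 / sqrt(2e4)
  expect_true(all(abs(colMeans(z)) < 4 * se))
  expect_true(all(abs(apply(z, 2, var) - 1) < 0.05))
  expect_identical(z, sample_prior(2e4, 8, rng_seed = 3))
  expect_error(sample_prior(0, 8), "n >= 1")
})

test_that("lerp paths are straight with equal spacing", {
  z0 <- c(1, 2, 3); z1 <- c(-1, 0, 5)
  p <- lerp(z0, z1, 5)
  expect_equal(p$points[1, ], z0)
  expect_equal(p$points[5, ], z1)
  d <- sqrt(rowSums(diff(p$points)^2))
  expect_equal(d, rep(sqrt(sum((z1 - z0)^2)) / 4, 4))
  expect_equal(lerp(z0, -z0, 3)$points[2, ], c(0, 0, 0))
})

test_that("slerp follows the trigonometric closed form", {
  z0 <- c(1, 0, 0, 0); z1 <- c(0, 1, 0, 0)
  p <- slerp(z0, z1, 3)
  expect_equal(p$points[1, ], z0, tolerance = 1e-12)
  expect_equal(p$points[3, ], z1, tolerance = 1e-12)
  # orthogonal unit endpoints: midpoint is (z0 + z1) * sqrt(2)/2
  expect_lt(max(abs(p$points[2, ] - (z0 + z1) * sqrt(2) / 2)), 1e-10)
  expect_equal(sqrt(sum(p$points[2, ]^2)), 1, tolerance = 1e-10)

  # constant norm along the path when endpoint norms agree
  set.seed(4)
  a <- rnorm(6); a <- a / sqrt(sum(a^2)) * 3
  b <- rnorm(6); b <- b / sqrt(sum(b^2)) * 3
  ps <- slerp(a, b, 9)
  expect_equal(sqrt(rowSums(ps$points^2)), rep(3, 9), tolerance = 1e-10)

  # parallel endpoints: slerp degenerates to lerp
  pl <- slerp(a, 2 * a, 5)
  expect_equal(pl$points, lerp(a, 2 * a, 5)$points, tolerance = 1e-12)
  expect_error(slerp(c(0, 0), c(1, 0), 3), "nonzero")
})

test_that("acquisition matches its closed form and is linear in omega", {
  # predictor returning collapse probability; target 0 => persistence
  pred_zero <- function(z) rep(0, nrow(z))    # always persistent
  expect_equal(acquisition(rep(0, 4), pred_zero,
                           acq_config(target = 0, omega = 1)), 0,
               tolerance = 1e-5)
  pred_half <- function(z) rep(0.5, nrow(z))
  expect_equal(acquisition(rep(0, 4), pred_half,
                           acq_config(target = 0, omega = 0)), log(2))
  z <- c(1, 1, 0, 0)  # ||z||^2 = 2
  expect_equal(acquisition(z, pred_half, acq_config(omega = 1)),
               log(2) + 1)
  # linearity: value(omega) = value(0) + omega * ||z||^2 / 2
  set.seed(8)
  zz <- matrix(rnorm(12), 3)
  pr <- function(z) plogis(z[, 1])
  for (om in c(0.1, 0.7, 2)) {
    expect_equal(acquisition(zz, pr, acq_config(omega = om)),
                 acquisition(zz, pr, acq_config(omega = 0)) +
                   om * rowSums(zz^2) / 2)
  }
  # clamping keeps the value finite at p = 0
  pred_one <- function(z) rep(1, nrow(z))     # never persistent
  expect_true(is.finite(acquisition(rep(0, 4), pred_one, acq_config())))
})

test_that("Bayesian optimisation recovers a known optimum in the box", {
  d <- 3L
  zstar <- c(0.5, -0.8, 0.2)
  fn <- function(z) rowSums(sweep(z, 2, zstar)^2)
  bounds <- rbind(rep(-2, d), rep(2, d))
  for (seed in 1:3) {
    bo <- bayes_optimize(fn, bounds, n_iterations = 50, rng_seed = seed)
    expect_lt(sqrt(sum((bo$best_x - zstar)^2)), 0.1)
    expect_true(all(bo$X >= matrix(bounds[1, ], nrow(bo$X), d,
                                   byrow = TRUE) - 1e-9))
    expect_true(all(bo$X <= matrix(bounds[2, ], nrow(bo$X), d,
                                   byrow = TRUE) + 1e-9))
    expect_equal(bo$values, sort(bo$values))
  }
  expect_error(bayes_optimize(fn, rbind(c(0, 0, 0), c(0, 1, 1))),
               "degenerate bounds")
})

test_that("a dominant regulariser pulls the optimum to the origin", {
  pred_half <- function(z) rep(0.5, nrow(z))
  fn <- function(z) acquisition(z, pred_half, acq_config(omega = 100))
  bo <- bayes_optimize(fn, rbind(rep(-2, 2), rep(2, 2)),
                       n_iterations = 25, rng_seed = 1)
  expect_lt(sqrt(sum(bo$best_x^2)), 0.05)
})

test_that("repeated reconstruction tallies decodes with conservation", {
  om <- overfit_model()
  rec <- om$records[1, , drop = FALSE]
  tab <- reconstruct_repeated(om$model, rec, n_samples = 200,
                              rng_seed = 5)
  expect_identical(sum(tab$count), 200L)
  expect_true(all(diff(tab$count) <= 0))
  # modal decode of an overfit model is the input cage
  expect_identical(tab$bb2_smiles[1], rec$bb2_smiles)
  expect_identical(tab$bb1_id[1], rec$bb1_id)
  # zero-noise limit: a single decoded cage
  tab0 <- reconstruct_repeated(om$model, rec, n_samples = 50,
                               rng_seed = 5, clamp_log_variance = -60)
  expect_identical(nrow(tab0), 1L)
  expect_identical(tab0$count, 50L)
  expect_lt(tab0$mean_latent_distance, 1e-8)
})

test_that("interpolation generation respects its threshold contract", {
  om <- overfit_model()
  p_persist <- 1 - predict_persistence(
    om$model, encode(om$model, om$records)$mean)
  start <- om$records[which.max(p_persist), , drop = FALSE]
  end <- om$records[which.min(p_persist), , drop = FALSE]

  all_pts <- interpolation_generate(start, end, om$model, threshold = 0,
                                    steps = 8)
  expect_identical(nrow(all_pts), 8L)
  none <- interpolation_generate(start, end, om$model, threshold = 1 + 1e-9,
                                 steps = 8)
  expect_identical(nrow(none), 0L)
  # retained fraction is monotone non-increasing in the threshold
  kept <- vapply(c(0, 0.25, 0.5, 0.75, max(p_persist)), function(th) {
    nrow(interpolation_generate(start, end, om$model, threshold = th,
                                steps = 8))
  }, 1L)
  expect_true(all(diff(kept) <= 0))
  expect_error(
    interpolation_generate(end, start, om$model,
                           threshold = 1 - 1e-12, steps = 4),
    "fails the persistence threshold")
})
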