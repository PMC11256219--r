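# DRAM MCMC and interval summaries: analytic-posterior oracles and the
# shortest-percentile machinery.

test_that("shortest interval matches brute-force and analytic values", {
  set.seed(100)
  x <- rnorm(1e6)
  ci <- shortest_interval(x, 0.65)
  # symmetric 65% normal interval: +/- qnorm(0.825) = 0.9346. The width is
  # the stable statistic; the location slides with sd ~ 0.01 at this n.
  expect_equal(diff(ci), 2 * qnorm(0.825), tolerance = 0.006)
  expect_equal(ci[1], -qnorm(0.825), tolerance = 0.04)
  expect_equal(ci[2], qnorm(0.825), tolerance = 0.04)

  # brute-force sliding-window oracle on a small sample
  y <- rexp(500)
  m <- ceiling(0.65 * 500)
  s <- sort(y)
  widths <- s[m:500] - s[1:(500 - m + 1)]
  i <- which.min(widths)
  expect_equal(shortest_interval(y, 0.65), c(s[i], s[i + m - 1]))

  # uniform: any 65%-wide window; width ~ 0.65
  u <- runif(2e5)
  ciu <- shortest_interval(u, 0.65)
  expect_equal(diff(ciu), 0.65, tolerance = 0.01)

  # constant samples give a degenerate interval
  expect_equal(shortest_interval(rep(3, 100)), c(3, 3))
  # level -> 1: the full range; level -> 0: the closest pair
  z <- rnorm(200)
  expect_equal(shortest_interval(z, 0.9999), range(z))
  tight <- shortest_interval(z, 1e-6)
  sz <- sort(z)
  expect_equal(diff(tight), min(diff(sz)), tolerance = 1e-12)
  expect_error(shortest_interval(rnorm(10)), "at least 50")
  expect_error(shortest_interval(rnorm(100), 1.2), "level")
})

# a linear-Gaussian toy wrapped as an nr_problem: a single point on the
# total-reflection plateau (model R = 1), so the free scale parameter has
# chi-squared ((s - mu)/sigma)^2 and an exactly Gaussian posterior
gaussian_toy_problem <- function(mu = 0.3, sigma = 0.05) {
  d <- tibble::tibble(dataset = "toy", q = 0.012, r = mu, dr = sigma,
                      dq = NA_real_, contrast = "D2O", phase = "bare",
                      condition = NA_character_)
  u <- underlayers(si_roughness = 0, mix_roughness = 0,
                   permalloy_roughness = 0, gold_roughness = 0,
                   sam_roughness = 0)
  fit_problem(d, u, engine = "nevot_croce", dq_over_q = 0,
              vary = tibble::tibble(name = "obs.toy.scale",
                                    lower = 0.0001, upper = 2))
}

test_that("DRAM reproduces a one-dimensional Gaussian posterior", {
  pr <- gaussian_toy_problem()
  r0 <- model_reflectivity(pr, 1)$r_model
  expect_equal(r0, 1, tolerance = 1e-9)   # plateau: below every critical edge
  mu_s <- 0.3
  sd_s <- 0.05
  post <- run_dram(pr, n_steps = 15000, seed = 99, start = mu_s,
                   init_scale = 0.03)
  draws <- posterior_samples(post)[, 1]
  # mean within ~3 autocorrelation-inflated standard errors; sd within 10%
  expect_equal(mean(draws), mu_s, tolerance = 0.02)
  expect_equal(sd(draws), sd_s, tolerance = 0.1)
  ci <- shortest_interval(draws, 0.65)
  expect_equal(diff(ci), 2 * qnorm(0.825) * sd_s, tolerance = 0.08)
})

test_that("DRAM recovers the analytic covariance of a 2-parameter problem", {
  # two independent plateau measurements with free scales: the posterior is
  # a product of Gaussians with known (diagonal) covariance
  d <- dplyr::bind_rows(
    tibble::tibble(dataset = "a", q = 0.012, r = 0.9, dr = 0.04,
                   dq = NA_real_, contrast = "D2O", phase = "bare",
                   condition = NA_character_),
    tibble::tibble(dataset = "b", q = 0.012, r = 1.1, dr = 0.08,
                   dq = NA_real_, contrast = "D2O", phase = "bare",
                   condition = NA_character_))
  u <- underlayers(si_roughness = 0, mix_roughness = 0,
                   permalloy_roughness = 0, gold_roughness = 0,
                   sam_roughness = 0)
  vary <- tibble::tibble(name = c("obs.a.scale", "obs.b.scale"),
                         lower = c(0.5, 0.5), upper = c(1.5, 1.5))
  pr <- fit_problem(d, u, vary = vary, engine = "nevot_croce", dq_over_q = 0)
  post <- run_dram(pr, n_steps = 15000, seed = 17, start = c(0.9, 1.1),
                   init_scale = 0.03)
  draws <- posterior_samples(post)
  expect_equal(sd(draws[, 1]), 0.04, tolerance = 0.12)
  expect_equal(sd(draws[, 2]), 0.08, tolerance = 0.12)
  expect_lt(abs(cor(draws)[1, 2]), 0.1)
  expect_equal(colMeans(draws), c(obs.a.scale = 0.9, obs.b.scale = 1.1),
               tolerance = 0.02)
})

test_that("degenerate and failing chains are handled explicitly", {
  pr <- gaussian_toy_problem()
  expect_error(run_dram(fit_problem(pr$data, underlayers(),
                                    engine = "nevot_croce"),
                        n_steps = 100, seed = 1),
               "no varying parameters")
  expect_error(run_dram(pr, n_steps = 100, seed = 1, start = 5),
               "zero posterior density|bounds")
})

test_that("posterior bands have the documented structure and limits", {
  u <- underlayers(sam_roughness = 3)
  m <- floating_membrane(bilayer_roughness = 3, peripheral_roughness = 3)
  inst <- fast_instrument(40)
  data <- dplyr::bind_rows(
    simulate_dataset(u, m, "D2O", inst, seed = 31, condition = "Ca",
                     engine = "nevot_croce"),
    simulate_dataset(u, m, "H2O", inst, seed = 32, condition = "Ca",
                     engine = "nevot_croce"))
  vary <- tibble::tibble(name = "membranes.Ca.interlayer_thickness",
                         lower = 8, upper = 14)
  pr <- fit_problem(data, u, list(Ca = m), vary = vary,
                    engine = "nevot_croce")
  post <- run_dram(pr, n_steps = 1500, seed = 44, start = 11)
  bands <- posterior_bands(post, n_draws = 120, seed = 2)
  expect_named(bands, c("reflectivity", "sld", "volume"))
  expect_equal(nrow(bands$reflectivity), nrow(data))
  expect_true(all(bands$reflectivity$lo <= bands$reflectivity$hi))
  expect_true(all(bands$sld$lo <= bands$sld$hi + 1e-12))
  # a near-delta posterior yields near-zero-width bands
  post_delta <- post
  keep <- posterior_samples(post)
  post_delta$chain <- matrix(rep(mean(keep), nrow(post$chain)),
                             ncol = 1,
                             dimnames = dimnames(post$chain))
  bd <- posterior_bands(post_delta, n_draws = 60, seed = 3)
  expect_lt(max(bd$reflectivity$hi - bd$reflectivity$lo), 1e-12)
  # the reported centre is the mean of sampled curves (contract)
  expect_equal(bd$reflectivity$mean,
               model_reflectivity(set_param_values(pr, mean(keep)))$r_model,
               tolerance = 1e-9)
})
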