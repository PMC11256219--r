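# Co-refinement: chi-squared definition, dataset-order invariance, and the
# global/local optimisers on cheap Nevot-Croce problems.

make_tiny_problem <- function(seed = 5, n_bins = 60, counting_scale = 1,
                              vary = NULL, engine = "nevot_croce") {
  # small-roughness truth so the Nevot-Croce engine is self-consistent
  u <- underlayers(sam_roughness = 3)
  m <- floating_membrane(bilayer_roughness = 3, peripheral_roughness = 3)
  inst <- fast_instrument(n_bins)
  data <- dplyr::bind_rows(
    simulate_dataset(u, m, "D2O", inst, seed = seed, condition = "Ca",
                     counting_scale = counting_scale, engine = engine),
    simulate_dataset(u, m, "H2O", inst, seed = seed + 1, condition = "Ca",
                     counting_scale = counting_scale, engine = engine))
  fit_problem(data, u, list(Ca = m), vary = vary, engine = engine)
}

test_that("chi-squared matches its definition", {
  # noise-free data: exact zero at the generating parameters
  pr0 <- make_tiny_problem(counting_scale = Inf)
  expect_lt(chi_squared(pr0), 1e-16 * nrow(pr0$data))

  # one point with a 2-sigma residual contributes exactly 4
  d <- tibble::tibble(dataset = "one", q = 0.05, r = 1e-4, dr = 5e-6,
                      dq = NA_real_, contrast = "D2O", phase = "bare",
                      condition = NA_character_)
  pr <- fit_problem(d, underlayers(), engine = "nevot_croce")
  m <- model_reflectivity(pr)
  d2 <- d
  d2$r <- m$r_model + 2 * d$dr
  pr2 <- fit_problem(d2, underlayers(), engine = "nevot_croce")
  expect_equal(chi_squared(pr2), 4, tolerance = 1e-9)
})

test_that("chi-squared at truth is consistent with the noise model", {
  # E[chi^2] = N under the generating Gaussian noise; average over seeds
  set.seed(1)
  vals <- vapply(1:100, function(k) {
    pr <- make_tiny_problem(seed = 1000 + 7 * k, n_bins = 30)
    chi_squared(pr) / nrow(pr$data)
  }, numeric(1))
  # mean of N(0,1)^2 over 100*60 points: s.e. ~ sqrt(2/6000) ~ 0.018
  expect_equal(mean(vals), 1, tolerance = 0.06)
})

test_that("the objective is invariant to dataset ordering", {
  pr <- make_tiny_problem()
  data_rev <- dplyr::arrange(pr$data, dplyr::desc(.data$dataset))
  pr_rev <- fit_problem(data_rev, underlayers(sam_roughness = 3),
                        list(Ca = floating_membrane(bilayer_roughness = 3,
                                                    peripheral_roughness = 3)),
                        engine = "nevot_croce")
  expect_equal(chi_squared(pr_rev), chi_squared(pr), tolerance = 1e-12)
})

test_that("fixed-parameter problems pass through the optimisers unchanged", {
  pr <- make_tiny_problem()
  f <- fit_global(pr, seed = 1)
  expect_equal(f$chisq, chi_squared(pr))
  expect_equal(f$problem$params, pr$params)
  l <- fit_local(pr)
  expect_equal(l$chisq, chi_squared(pr))
})

test_that("a one-parameter fit recovers the truth found by a grid scan", {
  vary <- tibble::tibble(name = "membranes.Ca.interlayer_thickness",
                         lower = 2, upper = 30)
  pr <- make_tiny_problem(counting_scale = Inf, vary = vary)
  # independent oracle: dense grid scan over the bounds
  grid <- seq(2, 30, by = 0.25)
  cost <- vapply(grid, function(g) chi_squared(pr, g), numeric(1))
  best_grid <- grid[which.min(cost)]
  expect_equal(best_grid, 11, tolerance = 0.25)   # truth on the grid
  fit <- fit_corefine(pr, seed = 3, population = 12, generations = 25)
  expect_equal(unname(param_values(fit$problem)), 11, tolerance = 0.1)
})

test_that("local polish never increases chi-squared and stays at a minimum", {
  vary <- tibble::tibble(
    name = c("membranes.Ca.interlayer_thickness",
             "membranes.Ca.tail_thickness"),
    lower = c(2, 20), upper = c(30, 40))
  pr <- make_tiny_problem(counting_scale = Inf, vary = vary)
  # start at truth: polish must stay (gradient ~ 0)
  at_truth <- fit_local(pr, start = c(11, 30))
  expect_lt(at_truth$chisq, 1e-10)
  expect_equal(unname(param_values(at_truth$problem)), c(11, 30),
               tolerance = 1e-3)
  # start perturbed 5%: polish returns to truth
  pert <- fit_local(pr, start = c(11 * 1.05, 30 * 1.05))
  expect_equal(unname(param_values(pert$problem)), c(11, 30),
               tolerance = 0.05)
  expect_lte(pert$chisq, chi_squared(pr, c(11 * 1.05, 30 * 1.05)))
  expect_error(fit_local(pr, start = c(50, 30)), "bounds")
})

test_that("noise-free three-parameter fits reach machine-level chi-squared", {
  vary <- tibble::tibble(
    name = c("membranes.Ca.interlayer_thickness",
             "membranes.Ca.tail_thickness", "membranes.Ca.tail_lipid"),
    lower = c(5, 22, 0.4), upper = c(20, 38, 0.75))
  pr <- make_tiny_problem(counting_scale = Inf, vary = vary)
  fit <- fit_corefine(pr, seed = 11, population = 15, generations = 40)
  expect_lt(fit$chisq, 1e-6 * nrow(pr$data))
})

test_that("bare-only and joint fits give consistent under-layer values", {
  u <- underlayers(sam_roughness = 3)
  m <- floating_membrane(bilayer_roughness = 3, peripheral_roughness = 3)
  inst <- fast_instrument(60)
  bare <- dplyr::bind_rows(
    simulate_dataset(u, NULL, "D2O", inst, seed = 21, engine = "nevot_croce"),
    simulate_dataset(u, NULL, "H2O", inst, seed = 22, engine = "nevot_croce"))
  mem <- dplyr::bind_rows(
    simulate_dataset(u, m, "D2O", inst, seed = 23, condition = "Ca",
                     engine = "nevot_croce"),
    simulate_dataset(u, m, "H2O", inst, seed = 24, condition = "Ca",
                     engine = "nevot_croce"))
  vary <- tibble::tibble(name = "underlayers.gold_thickness",
                         lower = 70, upper = 110)
  pr_bare <- fit_problem(bare, u, vary = vary, engine = "nevot_croce")
  pr_joint <- fit_problem(dplyr::bind_rows(bare, mem), u, list(Ca = m),
                          vary = vary, engine = "nevot_croce")
  f_bare <- fit_corefine(pr_bare, seed = 31, population = 10, generations = 20)
  f_joint <- fit_corefine(pr_joint, seed = 32, population = 10,
                          generations = 20)
  est_b <- unname(param_values(f_bare$problem))
  est_j <- unname(param_values(f_joint$problem))
  # both near truth and near each other (co-refinement constrains, not
  # distorts)
  expect_equal(est_b, 90, tolerance = 0.02)
  expect_equal(est_j, 90, tolerance = 0.02)
  expect_lt(abs(est_b - est_j), 1)
})

test_that("glance and tidy expose the fit summary", {
  vary <- tibble::tibble(name = "membranes.Ca.interlayer_thickness",
                         lower = 2, upper = 30)
  pr <- make_tiny_problem(vary = vary)
  fit <- fit_local(pr)
  td <- tidy(fit)
  expect_equal(td$term, "membranes.Ca.interlayer_thickness")
  gl <- glance(fit)
  expect_equal(gl$n_free, 1)
  expect_equal(gl$chisq_per_point, gl$chisq / gl$n_points)
})
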