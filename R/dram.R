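# Bayesian uncertainty quantification: Delayed-Rejection Adaptive Metropolis
# (DRAM) sampling of exp(-chi^2/2) with uniform priors on the parameter
# bounds, shortest-percentile interval summaries, and uncertainty bands from
# resampled chain draws.

#' Shortest percentile interval
#'
#' The narrowest contiguous window of sorted samples containing a fraction
#' `level` of them (ties broken leftmost). With `level` near 1 this is the
#' sample range; near 0 it degenerates to the closest pair.
#'
#' @param samples Numeric vector (at least 50 values).
#' @param level Coverage in `(0, 1)`; default the 65\% used for parameter
#'   uncertainties.
#' @return `c(lo, hi)`.
#' @export
shortest_interval <- function(samples, level = 0.65) {
  if (length(samples) < 50) {
    stop("need at least 50 samples for a shortest interval", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  s <- sort(samples)
  n <- length(s)
  m <- max(2L, as.integer(ceiling(level * n)))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

# log target: -chi^2/2 inside the bounds, -Inf outside.
make_log_post <- function(problem) {
  lo <- problem$vary$lower
  hi <- problem$vary$upper
  function(x) {
    if (any(x < lo) || any(x > hi)) return(-Inf)
    -0.5 * chi_squared(problem, x)
  }
}

dram_sample <- function(log_post, start, n_steps, cov0,
                        adapt_interval = 100, dr_scale = 1 / 5,
                        adapt_start = 200, eps = 1e-10) {
  d <- length(start)
  chain <- matrix(NA_real_, n_steps, d)
  x <- start
  lp_x <- log_post(x)
  if (!is.finite(lp_x)) stop("start has zero posterior density", call. = FALSE)
  sd_fac <- 2.4^2 / d
  C <- cov0
  R <- chol(C)
  accepted <- 0
  log_q <- function(from, to, R) {
    z <- backsolve(R, to - from, transpose = TRUE)
    -0.5 * sum(z^2)
  }
  for (t in seq_len(n_steps)) {
    y1 <- x + drop(rnorm(d) %*% R)
    lp_y1 <- log_post(y1)
    a1 <- min(1, exp(lp_y1 - lp_x))
    if (is.finite(lp_y1) && runif(1) < a1) {
      x <- y1; lp_x <- lp_y1; accepted <- accepted + 1
    } else {
      # delayed-rejection second stage with a scaled-down proposal
      R2 <- R * sqrt(dr_scale)
      y2 <- x + drop(rnorm(d) %*% R2)
      lp_y2 <- log_post(y2)
      if (is.finite(lp_y2)) {
        a1_rev <- min(1, exp(lp_y1 - lp_y2))   # alpha1(y2 -> y1)
        num <- lp_y2 + log_q(y2, y1, R) + log1p(-min(a1_rev, 1 - 1e-15))
        den <- lp_x + log_q(x, y1, R) + log1p(-min(a1, 1 - 1e-15))
        if (runif(1) < exp(num - den)) {
          x <- y2; lp_x <- lp_y2; accepted <- accepted + 1
        }
      }
    }
    chain[t, ] <- x
    if (t >= adapt_start && t %% adapt_interval == 0) {
      Ct <- sd_fac * (cov(chain[seq_len(t), , drop = FALSE]) +
                        eps * diag(d))
      Rt <- tryCatch(chol(Ct), error = function(e) NULL)
      if (!is.null(Rt)) { C <- Ct; R <- Rt }
    }
  }
  list(chain = chain, acceptance_rate = accepted / n_steps)
}

#' DRAM MCMC over a fit problem
#'
#' Samples the posterior \eqn{\propto \exp(-\chi^2/2)} with uniform priors
#' on the `vary` bounds using the Delayed-Rejection Adaptive Metropolis
#' algorithm: a Gaussian random walk whose proposal covariance adapts to the
#' running chain covariance, with a scaled-down second-stage proposal tried
#' after each first-stage rejection. Deterministic given `seed`.
#'
#' @param problem An `nr_problem` (typically `fit$problem` after
#'   [fit_corefine()]); must have at least one varying parameter.
#' @param n_steps Chain length (user-defined; must exceed the burn-in).
#' @param seed Integer RNG seed.
#' @param start Starting vector (defaults to the problem's current values).
#' @param burn_in Fraction of initial steps discarded by summaries
#'   (default 0.25).
#' @param adapt_interval Steps between covariance adaptations.
#' @param dr_scale Variance scale of the delayed-rejection proposal.
#' @param init_scale Initial proposal s.d. as a fraction of each bound range.
#' @param level Interval coverage for summaries.
#' @return An `nr_posterior`: chains (steps x parameters), burn-in count,
#'   acceptance rate, shortest intervals, and the generating problem.
#' @export
run_dram <- function(problem, n_steps = 5000, seed, start = NULL,
                     burn_in = 0.25, adapt_interval = 100, dr_scale = 1 / 5,
                     init_scale = 0.02, level = 0.65) {
  stopifnot(inherits(problem, "nr_problem"))
  nv <- nrow(problem$vary)
  if (nv == 0) stop("no varying parameters to sample", call. = FALSE)
  start <- start %||% unname(param_values(problem))
  set.seed(seed)
  rng <- problem$vary$upper - problem$vary$lower
  cov0 <- diag((init_scale * rng)^2, nv)
  res <- dram_sample(make_log_post(problem), start, n_steps, cov0,
                     adapt_interval = adapt_interval, dr_scale = dr_scale)
  if (res$acceptance_rate <= 1 / n_steps) {
    stop("DRAM chain never moved: check the start point, bounds and ",
         "init_scale (the proposal may be far too wide for the posterior)",
         call. = FALSE)
  }
  colnames(res$chain) <- problem$vary$name
  n_burn <- floor(burn_in * n_steps)
  post <- res$chain[(n_burn + 1):n_steps, , drop = FALSE]
  ints <- t(apply(post, 2, shortest_interval, level = level))
  structure(list(
    chain = res$chain, burn_in = n_burn,
    acceptance_rate = res$acceptance_rate,
    level = level,
    intervals = tibble(term = problem$vary$name,
                       mean = colMeans(post),
                       lo = ints[, 1], hi = ints[, 2]),
    problem = problem, seed = seed
  ), class = "nr_posterior")
}

#' Post-burn-in samples of a posterior
#' @param posterior An `nr_posterior`.
#' @return Matrix of retained draws (rows) by parameters (columns).
#' @export
posterior_samples <- function(posterior) {
  posterior$chain[(posterior$burn_in + 1):nrow(posterior$chain), ,
                  drop = FALSE]
}

#' @export
print.nr_posterior <- function(x, ...) {
  cat("<nr_posterior> ", nrow(x$chain), " steps (", x$burn_in,
      " burn-in), acceptance ", sprintf("%.2f", x$acceptance_rate), "\n",
      sep = "")
  print(x$intervals, n = Inf)
  invisible(x)
}

#' Tidy a posterior: per-parameter shortest-interval summary
#' @param x An `nr_posterior`.
#' @param ... Unused.
#' @return Tibble `term`, `mean`, `lo`, `hi` (shortest 65\% by default).
#' @export
tidy.nr_posterior <- function(x, ...) x$intervals

#' One-row posterior summary
#' @param x An `nr_posterior`.
#' @param ... Unused.
#' @return Tibble with `n_steps`, `burn_in`, `acceptance_rate`, `level`.
#' @export
glance.nr_posterior <- function(x, ...) {
  tibble(n_steps = nrow(x$chain), burn_in = x$burn_in,
         acceptance_rate = x$acceptance_rate, level = x$level)
}

# Pointwise shortest-interval envelope over a draws x points matrix.
envelope <- function(mat, level) {
  lo <- numeric(ncol(mat)); hi <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    ci <- shortest_interval(mat[, j], level)
    lo[j] <- ci[1]; hi[j] <- ci[2]
  }
  list(mean = colMeans(mat), lo = lo, hi = hi)
}

#' Resampled uncertainty bands for reflectivity and structure
#'
#' Randomly samples parameter draws from the (post-burn-in) chains, computes
#' the model reflectivity for every dataset and the SLD and volume-fraction
#' profiles for every membrane condition for each draw, and reports the
#' pointwise shortest-`level` envelope together with the mean curve (the
#' best-fit line is the mean of the resampled curves, not the curve of the
#' mean parameters).
#'
#' @param posterior An `nr_posterior`.
#' @param n_draws Number of chain draws (default 1000).
#' @param seed RNG seed for the resampling.
#' @param level Envelope coverage.
#' @param profile_contrast Contrast at which SLD-profile bands are computed.
#' @return A list of tibbles: `reflectivity` (`dataset`, `q`, `mean`, `lo`,
#'   `hi`), `sld` (`condition`, `z`, `mean`, `lo`, `hi`) and `volume`
#'   (`condition`, `component`, `z`, `mean`, `lo`, `hi`).
#' @export
posterior_bands <- function(posterior, n_draws = 1000, seed = 1,
                            level = NULL, profile_contrast = "D2O") {
  level <- level %||% posterior$level
  problem <- posterior$problem
  post <- posterior_samples(posterior)
  set.seed(seed)
  idx <- sample.int(nrow(post), n_draws, replace = TRUE)
  draws <- post[idx, , drop = FALSE]

  refl <- vector("list", n_draws)
  conds <- unique(problem$data$condition[problem$data$phase == "membrane"])
  conds <- conds[!is.na(conds)]
  sldp <- list(); volp <- list()
  # fix a common z grid per condition from the first draw
  z_grid <- list()
  vol_components <- c("sam", "lipid_heads", "lipid_tails", "protein", "water")
  for (k in seq_len(n_draws)) {
    x <- draws[k, ]
    refl[[k]] <- model_reflectivity(problem, x)$r_model
    mod <- rebuild_models(apply_values(problem, x))
    for (cn in conds) {
      prof <- component_profile(mod$under, mod$membranes[[cn]])
      sldc <- sld_profile(mod$under, mod$membranes[[cn]], profile_contrast,
                          materials = problem$materials,
                          contrasts = problem$contrasts)
      if (is.null(z_grid[[cn]])) {
        z_grid[[cn]] <- prof$z
        sldp[[cn]] <- matrix(NA_real_, n_draws, length(prof$z))
        volp[[cn]] <- lapply(setNames(vol_components, vol_components),
                             function(x) matrix(NA_real_, n_draws,
                                                length(prof$z)))
      }
      z0 <- z_grid[[cn]]
      sldp[[cn]][k, ] <- approx(sldc$z, sldc$sld, z0, rule = 2)$y
      for (cc in vol_components) {
        volp[[cn]][[cc]][k, ] <- approx(prof$z, prof[[cc]], z0, rule = 2)$y
      }
    }
  }
  rmat <- do.call(rbind, refl)
  re <- envelope(rmat, level)
  base <- model_reflectivity(problem)
  refl_tbl <- tibble(dataset = base$dataset, q = base$q,
                     mean = re$mean, lo = re$lo, hi = re$hi)
  sld_tbl <- dplyr::bind_rows(lapply(conds, function(cn) {
    e <- envelope(sldp[[cn]], level)
    tibble(condition = cn, z = z_grid[[cn]], mean = e$mean,
           lo = e$lo, hi = e$hi)
  }))
  vol_tbl <- dplyr::bind_rows(lapply(conds, function(cn) {
    dplyr::bind_rows(lapply(vol_components, function(cc) {
      e <- envelope(volp[[cn]][[cc]], level)
      tibble(condition = cn, component = cc, z = z_grid[[cn]],
             mean = e$mean, lo = e$lo, hi = e$hi)
    }))
  }))
  list(reflectivity = refl_tbl, sld = sld_tbl, volume = vol_tbl)
}
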