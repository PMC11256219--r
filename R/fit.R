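# Global + local optimisation of the co-refinement chi-squared: a
# differential-evolution (rand/1/bin) global stage followed by a bounded
# quasi-Newton polish, mirroring the genetic + least-squares workflow used
# in reflectometry fitting software.

# Minimal rand/1/bin differential evolution within box bounds.
# Deterministic given the RNG state on entry.
de_optimize <- function(fn, lower, upper, population = NULL,
                        generations = 100, f = 0.8, cr = 0.9,
                        tol = 1e-8, trace = FALSE) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  np <- population %||% max(15 * d, 20)
  pop <- matrix(runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  evals <- np
  for (gen in seq_len(generations)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3)
      donor <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, donor, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial)
      evals <- evals + 1
      if (ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
    if (trace && gen %% 10 == 0) {
      message(sprintf("DE gen %d: best %.6g", gen, min(cost)))
    }
    if (diff(range(cost)) <= tol * (abs(mean(cost)) + tol)) break
  }
  b <- which.min(cost)
  list(par = pop[b, ], value = cost[b], evals = evals, generations = gen)
}

#' Global fit by differential evolution
#'
#' Minimises [chi_squared()] over the problem's free parameters with a
#' rand/1/bin differential-evolution search constrained to the `vary`
#' bounds (the "genetic" global stage). Deterministic given `seed`.
#'
#' @param problem An `nr_problem` with at least one varying parameter (a
#'   problem with none is returned unchanged).
#' @param seed Integer RNG seed (required: every stochastic stage logs one).
#' @param population Population size (default `15 * n_params`).
#' @param generations Maximum generations.
#' @param ... Passed to the optimiser (`f`, `cr`, `tol`, `trace`).
#' @return An `nr_fit`: list with the updated `problem`, the best values,
#'   `chisq`, and bookkeeping (`evals`, `seed`).
#' @export
fit_global <- function(problem, seed, population = NULL, generations = 100,
                       ...) {
  stopifnot(inherits(problem, "nr_problem"))
  nv <- nrow(problem$vary)
  if (nv == 0) {
    return(new_fit(problem, chi_squared(problem), evals = 1, seed = seed,
                   stage = "none"))
  }
  if (any(!is.finite(problem$vary$lower)) || any(!is.finite(problem$vary$upper))) {
    stop("every varying parameter needs finite bounds", call. = FALSE)
  }
  set.seed(seed)
  fn <- function(x) chi_squared(problem, x)
  res <- de_optimize(fn, problem$vary$lower, problem$vary$upper,
                     population = population, generations = generations, ...)
  new_fit(set_param_values(problem, res$par), res$value,
          evals = res$evals, seed = seed, stage = "global")
}

#' Local least-squares polish
#'
#' Bounded quasi-Newton refinement of the chi-squared from a starting
#' vector, guaranteed not to increase the objective (if the optimiser fails
#' to improve, the start is returned).
#'
#' @param problem An `nr_problem`.
#' @param start Starting free-parameter vector (defaults to the problem's
#'   current values); must lie within bounds.
#' @return An `nr_fit`.
#' @export
fit_local <- function(problem, start = NULL) {
  stopifnot(inherits(problem, "nr_problem"))
  nv <- nrow(problem$vary)
  if (nv == 0) {
    return(new_fit(problem, chi_squared(problem), evals = 1, stage = "none"))
  }
  start <- start %||% unname(param_values(problem))
  if (any(start < problem$vary$lower - 1e-12) ||
      any(start > problem$vary$upper + 1e-12)) {
    stop("start is outside the parameter bounds", call. = FALSE)
  }
  start <- pmin(pmax(start, problem$vary$lower), problem$vary$upper)
  c0 <- chi_squared(problem, start)
  res <- tryCatch(
    nlminb(start, function(x) chi_squared(problem, x),
           lower = problem$vary$lower, upper = problem$vary$upper,
           control = list(iter.max = 200)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$objective) || res$objective > c0) {
    return(new_fit(set_param_values(problem, start), c0, evals = 1,
                   stage = "local"))
  }
  new_fit(set_param_values(problem, res$par), res$objective,
          evals = res$evaluations[["function"]], stage = "local")
}

#' Global + local co-refinement
#'
#' The standard two-stage workflow: differential-evolution global search
#' followed by a bounded local polish.
#'
#' @inheritParams fit_global
#' @return An `nr_fit`.
#' @export
fit_corefine <- function(problem, seed, population = NULL, generations = 100,
                         ...) {
  g <- fit_global(problem, seed, population = population,
                  generations = generations, ...)
  l <- fit_local(g$problem)
  l$seed <- seed
  l$evals <- l$evals + g$evals
  l$stage <- "global+local"
  l
}

new_fit <- function(problem, chisq, evals, seed = NA_integer_, stage) {
  structure(list(problem = problem, chisq = chisq,
                 n_points = nrow(problem$data),
                 n_free = nrow(problem$vary),
                 evals = evals, seed = seed, stage = stage),
            class = "nr_fit")
}

#' @export
print.nr_fit <- function(x, ...) {
  cat("<nr_fit> ", x$stage, ": chi^2 = ", format(x$chisq, digits = 6),
      " over ", x$n_points, " points, ", x$n_free, " free parameters\n",
      sep = "")
  if (x$n_free > 0) print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a fit: one row per free parameter
#' @param x An `nr_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `lower`, `upper`.
#' @export
tidy.nr_fit <- function(x, ...) {
  tibble(term = x$problem$vary$name,
         estimate = unname(param_values(x$problem)),
         lower = x$problem$vary$lower,
         upper = x$problem$vary$upper)
}

#' One-row fit summary
#' @param x An `nr_fit`.
#' @param ... Unused.
#' @return Tibble with `chisq`, `n_points`, `n_free`, `chisq_per_point`,
#'   `evals`.
#' @export
glance.nr_fit <- function(x, ...) {
  tibble(chisq = x$chisq, n_points = x$n_points, n_free = x$n_free,
         chisq_per_point = x$chisq / x$n_points, evals = x$evals)
}
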