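# Simultaneous (co-refined) fitting across contrasts and conditions: a
# FitProblem holds the measured curves, the shared under-layers, one
# membrane model per condition, and per-dataset scale/background nuisance
# parameters. Varying parameters are addressed by path strings such as
# "underlayers.sam_coverage", "membranes.Ca.interlayer_thickness" or
# "obs.m_ca_d2o.scale".

#' Assemble a reflectivity dataset tibble
#'
#' One measured curve: (Q, R, dR[, dQ]) tagged with its solvent contrast,
#' sample phase and condition label. Datasets combine by `dplyr::bind_rows()`
#' into the single tidy table consumed by [fit_problem()].
#'
#' @param q,r,dr Momentum transfer (\eqn{\AA^{-1}}, ascending), reflectivity
#'   and its uncertainty (`dr > 0`).
#' @param dq Optional per-point resolution FWHM (\eqn{\AA^{-1}}).
#' @param contrast Contrast name (see [standard_contrasts()]).
#' @param phase `"bare"` (before membrane deposition) or `"membrane"`.
#' @param condition Condition label (e.g. `"Ca"`, `"CaNa"`, `"EDTA"`); `NA`
#'   for bare datasets.
#' @param dataset Unique dataset id (no dots).
#' @return A tibble with one row per point.
#' @export
reflectivity_data <- function(q, r, dr, dq = NULL, contrast, phase, condition = NA,
                              dataset) {
  phase <- match.arg(phase, c("bare", "membrane"))
  n <- length(q)
  stopifnot(length(r) == n, length(dr) == n)
  if (any(dr <= 0)) stop("dr must be strictly positive", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q must be strictly increasing", call. = FALSE)
  }
  if (grepl("\\.", dataset)) stop("dataset ids must not contain '.'", call. = FALSE)
  tibble(dataset = dataset, q = q, r = r, dr = dr,
         dq = if (is.null(dq)) NA_real_ else dq,
         contrast = contrast, phase = phase, condition = condition)
}

#' Define a co-refinement fit problem
#'
#' Binds a tidy table of measured curves to a structural model: shared
#' under-layers, one floating-membrane model per condition, and per-dataset
#' scale and background. The parameters listed in `vary` are free within
#' their bounds; all others are fixed at the model values.
#'
#' @param data Tibble with columns `dataset`, `q`, `r`, `dr`, optionally
#'   `dq`, `contrast`, `phase`, `condition` (see [reflectivity_data()]).
#' @param under Shared [underlayers()] model.
#' @param membranes Named list of [floating_membrane()] models keyed by the
#'   condition labels appearing in `data` (may be empty for bare-only fits).
#' @param vary Data frame with columns `name`, `lower`, `upper` naming the
#'   free parameters by path: `underlayers.<field>`,
#'   `membranes.<condition>.<field>`, `obs.<dataset>.scale` or
#'   `obs.<dataset>.background`.
#' @param dq_over_q Fractional resolution used where `data$dq` is absent.
#' @param engine Roughness treatment for membrane-phase stacks:
#'   `"microslice"` (reference; required at large roughness), `"nevot_croce"`
#'   or `"auto"` (microslice whenever any roughness exceeds one third of an
#'   adjacent layer thickness). Bare stacks always use Nevot-Croce unless
#'   `engine = "microslice"`.
#' @param dz Microslice sub-slab thickness (Angstrom).
#' @param scale,background Default per-dataset nuisance values (recycled).
#' @param materials,contrasts Lookup tables.
#' @param quad_points Resolution-smearing quadrature nodes per point.
#' @return An object of class `nr_problem`.
#' @export
fit_problem <- function(data, under, membranes = list(), vary = NULL,
                        dq_over_q = 0.035,
                        engine = c("auto", "microslice", "nevot_croce"),
                        dz = 1, scale = 1, background = 0,
                        materials = default_materials(),
                        contrasts = standard_contrasts(),
                        quad_points = 21) {
  engine <- match.arg(engine)
  stopifnot(is.data.frame(data),
            all(c("dataset", "q", "r", "dr", "contrast", "phase") %in% names(data)))
  if (!"condition" %in% names(data)) data$condition <- NA_character_
  if (!"dq" %in% names(data)) data$dq <- NA_real_
  if (any(data$dr <= 0)) stop("dr must be strictly positive", call. = FALSE)
  ds_ids <- unique(data$dataset)
  conds <- unique(data$condition[data$phase == "membrane"])
  missing_m <- setdiff(conds, names(membranes))
  if (length(missing_m)) {
    stop("no membrane model for condition(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  obs <- setNames(
    rep(list(NULL), length(ds_ids)), ds_ids)
  scale <- rep_len(scale, length(ds_ids))
  background <- rep_len(background, length(ds_ids))
  for (i in seq_along(ds_ids)) {
    obs[[i]] <- list(scale = scale[i], background = background[i])
  }
  params <- list(underlayers = unclass(under),
                 membranes = lapply(membranes, unclass),
                 obs = obs)
  if (!is.null(vary)) {
    stopifnot(all(c("name", "lower", "upper") %in% names(vary)))
    for (nm in vary$name) param_get(params, nm)  # validates the paths
    if (any(vary$lower > vary$upper)) {
      stop("vary bounds must satisfy lower <= upper", call. = FALSE)
    }
    v <- vapply(vary$name, function(nm) param_get(params, nm), numeric(1))
    clamped <- pmin(pmax(v, vary$lower), vary$upper)
    for (i in seq_along(v)) params <- param_set(params, vary$name[i], clamped[i])
    vary <- tibble::as_tibble(vary[c("name", "lower", "upper")])
  } else {
    vary <- tibble(name = character(), lower = numeric(), upper = numeric())
  }
  # precomputed per-dataset access for the objective hot path
  index <- lapply(ds_ids, function(id) {
    d <- data[data$dataset == id, ]
    list(dataset = id, q = d$q, r = d$r, dr = d$dr,
         dq = if (all(is.finite(d$dq))) d$dq else NULL,
         contrast_f = resolve_d2o_fraction(d$contrast[1], contrasts),
         phase = d$phase[1], condition = d$condition[1])
  })
  structure(list(
    data = tibble::as_tibble(data), params = params, vary = vary,
    index = index, endpoints = component_endpoints(materials),
    dq_over_q = dq_over_q, engine = engine, dz = dz,
    materials = materials, contrasts = contrasts, quad_points = quad_points
  ), class = "nr_problem")
}

param_path <- function(name) strsplit(name, ".", fixed = TRUE)[[1]]

param_get <- function(params, name) {
  v <- purrr::pluck(params, !!!as.list(param_path(name)))
  if (is.null(v)) stop("unknown parameter: ", name, call. = FALSE)
  v
}

param_set <- function(params, name, value) {
  purrr::assign_in(params, as.list(param_path(name)), unname(value))
}

# Current values of the varying parameters, in `vary` order.
#' Free-parameter vector of a problem
#' @param problem An `nr_problem`.
#' @return Named numeric vector of the varying parameters.
#' @export
param_values <- function(problem) {
  setNames(vapply(problem$vary$name, function(nm) param_get(problem$params, nm),
                  numeric(1)),
           problem$vary$name)
}

# Return the parameter tree with the free parameters set to x.
apply_values <- function(problem, x) {
  p <- problem$params
  if (is.null(x)) return(p)
  stopifnot(length(x) == nrow(problem$vary))
  for (i in seq_along(x)) p <- param_set(p, problem$vary$name[i], x[i])
  p
}

#' Replace a problem's free-parameter values
#' @param problem An `nr_problem`.
#' @param x Numeric vector in `vary` order.
#' @return The updated problem.
#' @export
set_param_values <- function(problem, x) {
  problem$params <- apply_values(problem, x)
  problem
}

rebuild_models <- function(params) {
  list(
    under = structure(params$underlayers, class = "nr_underlayers"),
    membranes = lapply(params$membranes, structure, class = "nr_membrane")
  )
}

# Engine choice for a given stack: "auto" microslices when any internal
# roughness is >= 1/3 of an adjacent layer thickness (Nevot-Croce validity).
# Accepts a slab tibble or a plain list of the three vectors.
pick_engine <- function(engine, slabs) {
  if (engine != "auto") return(engine)
  n <- length(slabs$thickness)
  if (n < 3) return("nevot_croce")
  d <- slabs$thickness
  for (i in seq_len(n - 1)) {            # interface below slab i+1
    s <- slabs$roughness[i]
    adj <- c(if (i > 1) d[i], if (i < n) d[i + 1])
    adj <- adj[adj > 0]
    if (length(adj) && s >= min(adj) / 3) return("microslice")
  }
  "nevot_croce"
}

#' Model reflectivity for every dataset of a problem
#'
#' Renders each dataset's slab stack at its contrast/phase/condition,
#' evaluates the smeared Abeles reflectivity on the dataset's own Q grid
#' (never interpolating datasets onto each other), and applies the
#' per-dataset scale and background.
#'
#' @param problem An `nr_problem`.
#' @param x Optional vector of free-parameter values (defaults to current).
#' @return Tibble `dataset`, `q`, `r_model`.
#' @export
model_reflectivity <- function(problem, x = NULL) {
  curves <- model_curves(problem, x)
  tibble(
    dataset = rep(vapply(problem$index, `[[`, character(1), "dataset"),
                  lengths(lapply(problem$index, `[[`, "q"))),
    q = unlist(lapply(problem$index, `[[`, "q")),
    r_model = unlist(curves)
  )
}

# List of model curves, one numeric vector per dataset (hot path: plain
# vectors, layer tables cached per phase/condition, slab stacks per
# phase/condition/contrast).
model_curves <- function(problem, x = NULL) {
  params <- apply_values(problem, x)
  under <- structure(params$underlayers, class = "nr_underlayers")
  lt_cache <- list()
  slab_cache <- list()
  curves <- vector("list", length(problem$index))
  for (i in seq_along(problem$index)) {
    di <- problem$index[[i]]
    lkey <- paste(di$phase, di$condition, sep = "|")
    if (is.null(lt_cache[[lkey]])) {
      mem <- if (di$phase == "membrane") {
        structure(params$membranes[[di$condition]], class = "nr_membrane")
      }
      lt_cache[[lkey]] <- layer_table(under, mem)
    }
    skey <- paste(lkey, di$contrast_f, sep = "|")
    if (is.null(slab_cache[[skey]])) {
      slab_cache[[skey]] <- render_slabs_fast(lt_cache[[lkey]], di$contrast_f,
                                              problem$endpoints)
    }
    slabs <- slab_cache[[skey]]
    eng <- pick_engine(problem$engine, slabs)
    r <- reflectivity_smeared(slabs, di$q,
                              dq_over_q = problem$dq_over_q, dq = di$dq,
                              roughness_model = eng, dz = problem$dz,
                              points = problem$quad_points)
    ob <- params$obs[[di$dataset]]
    curves[[i]] <- ob$scale * r + ob$background
  }
  curves
}

#' Chi-squared goodness of fit of a problem
#'
#' The likelihood of the co-refinement is defined through
#' \eqn{\chi^2 = \sum_{\mathrm{datasets}} \sum_i ((R_{\mathrm{model},i} -
#' R_i)/\mathrm{d}R_i)^2}, with the model curve including resolution
#' smearing, scale and background.
#'
#' @inheritParams model_reflectivity
#' @return A single number.
#' @export
chi_squared <- function(problem, x = NULL) {
  curves <- model_curves(problem, x)
  total <- 0
  for (i in seq_along(curves)) {
    di <- problem$index[[i]]
    if (length(curves[[i]]) != length(di$r)) {
      stop("model/data grid mismatch for dataset ", di$dataset, call. = FALSE)
    }
    total <- total + sum(((curves[[i]] - di$r) / di$dr)^2)
  }
  total
}
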