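# Readers, writers, configuration and pipeline orchestration. Reflectivity
# files are '#'-commented ASCII with whitespace- or comma-delimited columns
# Q [1/Angstrom], R, dR [, dQ FWHM]; configs are YAML.

#' Read a multi-column ASCII reflectivity file
#'
#' Parses comment lines starting with `#`, then columns Q, R, dR and
#' optionally dQ (FWHM), delimited by whitespace or commas. Uncertainties
#' are required (the chi-squared likelihood needs them); malformed rows and
#' non-positive dR raise errors naming the offending line. Descending-Q
#' files are sorted ascending with a warning.
#'
#' @param path File path.
#' @param contrast,phase,condition,dataset Metadata attached to the result
#'   (defaults: file name as dataset id).
#' @return A [reflectivity_data()] tibble.
#' @export
read_reflectivity <- function(path, contrast = NA, phase = "membrane",
                              condition = NA, dataset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path, call. = FALSE)
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 3 || anyNA(vals)) {
      stop("malformed row at line ", i, " of ", path, call. = FALSE)
    }
    c(vals, NA_real_)[1:4]
  })
  m <- do.call(rbind, parsed)
  bad_dr <- which(!is.finite(m[, 3]) | m[, 3] <= 0)
  if (length(bad_dr)) {
    stop("non-positive or missing dR at line ", rows[bad_dr[1]], " of ",
         path, call. = FALSE)
  }
  q <- m[, 1]
  if (is.unsorted(q, strictly = TRUE)) {
    if (is.unsorted(rev(q), strictly = TRUE)) {
      stop("q values are not monotone in ", path, call. = FALSE)
    }
    warning("descending Q in ", path, "; sorted ascending", call. = FALSE)
    m <- m[order(q), , drop = FALSE]
  }
  dataset <- dataset %||% sub("\\.[^.]*$", "", basename(path))
  dataset <- gsub("\\.", "_", dataset)
  reflectivity_data(q = m[, 1], r = m[, 2], dr = m[, 3],
                    dq = if (all(is.finite(m[, 4]))) m[, 4] else NULL,
                    contrast = contrast, phase = phase,
                    condition = condition, dataset = dataset)
}

#' Write a reflectivity dataset as ASCII
#'
#' Columns Q, R, dR[, dQ] with a unit-bearing `#` header carrying the
#' dataset's metadata; the output round-trips through
#' [read_reflectivity()].
#'
#' @param data One dataset's rows (a [reflectivity_data()] tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reflectivity <- function(data, path) {
  stopifnot(length(unique(data$dataset)) == 1)
  has_dq <- all(is.finite(data$dq))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# dataset: ", data$dataset[1]),
    paste0("# contrast: ", data$contrast[1], "  phase: ", data$phase[1],
           "  condition: ", data$condition[1]),
    paste0("# columns: Q [1/Angstrom]  R  dR",
           if (has_dq) "  dQ_FWHM [1/Angstrom]")
  ), con)
  cols <- if (has_dq) c("q", "r", "dr", "dq") else c("q", "r", "dr")
  utils::write.table(format(as.data.frame(data[cols]), digits = 15,
                            scientific = TRUE, trim = TRUE),
                     con, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML configuration with blocks `datasets` (path, contrast, phase,
#' condition), optional `simulate` (use the synthetic generator instead of
#' files), `underlayers`, `membranes` (per condition), `vary` (name, lower,
#' upper), `fit` (seed, generations, population, dram_steps, engine, dz) and
#' `output`.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Executes (optional) simulation or file reading, the global + local
#' co-refinement, a DRAM chain, uncertainty bands and profile export, and
#' writes a parameter table, chains and a log (seed and config hash) to the
#' output directory. Re-running with the same seed reproduces the parameter
#' table.
#'
#' @param config A configuration list (from [read_run_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (default from the config, else tempdir).
#' @param seed Overrides the config seed.
#' @return A list with `fit`, `posterior`, `bands`, `profiles` and the
#'   output paths, invisibly printed components written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- seed %||% config$fit$seed
  if (is.null(seed)) stop("a seed is required (config$fit$seed)", call. = FALSE)
  out_dir <- out_dir %||% config$output %||% tempfile("nreflect_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  under <- do.call(underlayers, config$underlayers %||% list())
  membranes <- lapply(config$membranes %||% list(), function(m) {
    do.call(floating_membrane, m)
  })

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    instrument <- do.call(instrument_spec, sim$instrument %||% list())
    plan <- sim$datasets
    data <- dplyr::bind_rows(lapply(seq_along(plan), function(i) {
      p <- plan[[i]]
      mem <- if (identical(p$phase, "membrane")) membranes[[p$condition]]
      simulate_dataset(under, mem, p$contrast, instrument,
                       seed = seed + i,
                       condition = p$condition %||% NA,
                       counting_scale = sim$counting_scale %||% 1)
    }))
  } else {
    data <- dplyr::bind_rows(lapply(config$datasets, function(d) {
      read_reflectivity(d$path, contrast = d$contrast, phase = d$phase,
                        condition = d$condition %||% NA,
                        dataset = d$dataset %||% NULL)
    }))
  }
  if (!any(data$phase == "bare")) {
    warning("no bare-surface datasets in the manifest: under-layer ",
            "parameters may not be identifiable", call. = FALSE)
  }

  vary <- if (!is.null(config$vary)) {
    dplyr::bind_rows(lapply(config$vary, tibble::as_tibble))
  }
  fitcfg <- config$fit %||% list()
  problem <- fit_problem(data, under, membranes, vary = vary,
                         engine = fitcfg$engine %||% "auto",
                         dz = fitcfg$dz %||% 1)
  fit <- fit_corefine(problem, seed = seed,
                      generations = fitcfg$generations %||% 60,
                      population = fitcfg$population)
  dram_steps <- fitcfg$dram_steps %||% 2000
  posterior <- NULL
  bands <- NULL
  if (nrow(problem$vary) > 0 && dram_steps > 0) {
    posterior <- run_dram(fit$problem, n_steps = dram_steps, seed = seed)
    bands <- posterior_bands(posterior,
                             n_draws = fitcfg$band_draws %||% 200,
                             seed = seed)
  }

  # outputs
  par_tbl <- if (!is.null(posterior)) tidy(posterior) else tidy(fit)
  par_path <- file.path(out_dir, "parameters.tsv")
  utils::write.table(par_tbl, par_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(posterior)) {
    utils::write.table(as.data.frame(posterior$chain),
                       file.path(out_dir, "chains.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  profiles <- list()
  mod <- rebuild_models(fit$problem$params)
  for (cn in names(membranes)) {
    profiles[[cn]] <- component_profile(mod$under, mod$membranes[[cn]])
    write_profile(profiles[[cn]],
                  file.path(out_dir, paste0("profile_", cn, ".tsv")))
  }
  cfg_hash <- substr(paste(
    as.hexmode(utils::head(utf8ToInt(paste(deparse(config), collapse = "")),
                           200)), collapse = ""), 1, 40)
  writeLines(c(
    paste0("seed: ", seed),
    paste0("config_sha_fragment: ", cfg_hash),
    paste0("chisq: ", format(fit$chisq, digits = 10)),
    paste0("n_points: ", fit$n_points),
    paste0("package: nreflect ",
           as.character(utils::packageVersion("nreflect")))
  ), file.path(out_dir, "run_log.txt"))

  invisible(list(fit = fit, posterior = posterior, bands = bands,
                 profiles = profiles, out_dir = out_dir,
                 parameter_table = par_tbl))
}
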