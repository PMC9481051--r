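# JSON configuration, synthetic fixtures, and result serialization.
#
# The core model is deterministic: the single seed in a run config feeds
# only the fixture generator. Unknown configuration keys are rejected with
# the offending path so typos (e.g. ecosystem.g5) fail loudly.

#' Default run configuration
#'
#' Nested list of every tunable with its default (the printed parameter
#' set): `spectrum` (slope, anchor abundance, size limits, carbon model),
#' `growth` (transport context), `ecosystem` (grazing constants,
#' integration controls, variant switches), `output` (directory) and
#' `seed` (fixture noise only).
#'
#' @return Nested list.
#' @export
default_config <- function() {
  list(
    spectrum = list(
      xi = 4.5, anchor_count = 2e4, bin = c(0.6, 0.8),
      dmin = 0.6, dmax = 500, d0 = 1, carbon_model = "non_diatom"
    ),
    growth = list(
      D = 1500, capture_eff = 0.9, velocity_dialect = "bracket_only",
      element = "N", np_ratio = 16
    ),
    ecosystem = list(
      g1 = 3.24, g2 = 0.5, g3 = 0.06, g4 = 1.6,
      dt = 1 / 96, t_max = 1095, extinct_frac = 1e-6,
      p_init = 0.18, z_init = 0.04, n_classes = 25,
      group = "non_diatom", multispecies = FALSE,
      m_loss = 0, kappa = 0, use_g4 = TRUE, per_generation_m = 0,
      ward_init = FALSE
    ),
    output = list(dir = "."),
    seed = 1L
  )
}

pd_merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      pd_stop(sprintf("unknown configuration key `%s`", here), "schema_error")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        pd_stop(sprintf("configuration key `%s` must be a block", here),
                "schema_error")
      }
      defaults[[key]] <- pd_merge_config(defaults[[key]], user[[key]],
                                         c(path, key))
    } else {
      value <- user[[key]]
      # normalize JSON integer/double so configs round-trip identically
      if (is.double(defaults[[key]]) && is.numeric(value)) {
        value <- as.double(value)
      }
      defaults[[key]] <- value
    }
  }
  defaults
}

#' Load and validate a JSON run configuration
#'
#' Reads a JSON file, overlays it on [default_config()], and rejects any
#' key not present in the defaults (error class `"schema_error"`, naming
#' the offending path). An empty file yields the all-defaults
#' configuration.
#'
#' @param path Path to a JSON file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    pd_stop(sprintf("configuration file not found: %s", path), "domain_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(user)) {
    pd_stop("configuration must be a JSON object", "schema_error")
  }
  pd_merge_config(default_config(), user)
}

#' Generate a synthetic production-resource fixture
#'
#' Evaluates one of the four curve forms on a resource grid and applies
#' mean-one multiplicative lognormal noise with the stated coefficient of
#' variation. Deterministic under a fixed seed; `noise_cv = 0` returns the
#' exact curve.
#'
#' @param model One of `"pi_tanh"`, `"mu_irradiance"`, `"uptake_tanh"`,
#'   `"mu_substrate"`.
#' @param true_params Named numeric vector in the order of the model's
#'   parameters (see [fit_curve()]).
#' @param n_points Number of points (\eqn{\ge} 3).
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   \eqn{\ge 0}.
#' @param seed Integer seed (consumed locally; the session RNG state is
#'   restored on exit).
#' @param resource_max Upper end of the resource grid; defaults to 5
#'   saturation indices of the true curve.
#' @return Data frame with columns `resource`, `rate`.
#' @export
generate_fixture <- function(model = pd_fit_models, true_params, n_points = 30,
                             noise_cv = 0, seed = 1, resource_max = NULL) {
  model <- match.arg(model)
  if (n_points < 3) pd_stop("`n_points` must be >= 3", "domain_error")
  pd_check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  p <- unname(true_params)
  if (length(p) != length(pd_model_parnames(model))) {
    pd_stop(sprintf("`true_params` must have %d values for model %s",
                    length(pd_model_parnames(model)), model), "domain_error")
  }
  if (is.null(resource_max)) {
    sat <- p[1] / p[2]
    if (model == "mu_substrate") sat <- p[2]
    if (model == "mu_irradiance") sat <- sat + p[3]
    resource_max <- 5 * sat
  }
  x <- seq(resource_max / n_points, resource_max, length.out = n_points)
  rate <- pd_model_fun(model)(p, x)
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    sdlog <- sqrt(log1p(noise_cv^2))
    rate <- rate * stats::rlnorm(n_points, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(resource = x, rate = rate)
}

#' Write result tables and a run manifest
#'
#' Writes each table as CSV (full-precision floats, fixed column order)
#' plus `manifest.json` recording the configuration, package version and a
#' timestamp. CSV bytes are identical across reruns of the same
#' configuration.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @param config Optional configuration list to embed in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      pd_stop(sprintf("cannot create output directory %s", out_dir), "io_error")
    }
  }
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  manifest <- list(
    tool = "phytodisc",
    version = as.character(utils::packageVersion("phytodisc")),
    timestamp = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ"),
    config = config
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, mpath))
}
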