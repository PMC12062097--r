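config_defaults <- list(
  model = "fourth_order", scheme = "quadratic_local4",
  gamma = 2, sigma = 0.1, m = 10, delta = 0.1, p = 1,
  kernel = "laplace",
  env = list(type = "clump", n = 1, amplitude = 1),
  ic = "flat_min",
  dx = 0.01, dt = NULL, tol = 1e-8, max_time = 10,
  r_min = 0.001, r_max = 1, r_steps = 200,
  seed = NULL, out = NULL, log = NULL)

config_allowed_env <- c("fourier", "clump", "two_clump")

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, validates it against the known schema
#' (unknown keys are rejected; parameter signs are checked) and fills in the
#' documented defaults, reporting every applied default via `message()`.
#'
#' @param path Path to a JSON file, or a named list of settings (already
#'   parsed).
#' @param quiet Suppress the applied-default messages.
#' @return A validated \code{aggdiff_config} list.
#' @export
load_config <- function(path, quiet = FALSE) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) abort_config(sprintf("config file '%s' not found", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) path
  else abort_config("'path' must be a file path or a list")
  unknown <- setdiff(names(cfg), names(config_defaults))
  if (length(unknown))
    abort_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  if (is.null(names(cfg)) && length(cfg))
    abort_config("config must be a named object")
  applied <- setdiff(names(config_defaults), names(cfg))
  out <- utils::modifyList(config_defaults, cfg, keep.null = TRUE)
  if (!quiet && length(applied))
    message("applied defaults: ", paste(applied, collapse = ", "))
  # validation
  for (key in c("gamma", "sigma", "m", "delta", "p", "dx", "tol", "max_time"))
    stopifnot_scalar(out[[key]], key, positive = TRUE)
  if (!is.null(out$dt)) stopifnot_scalar(out$dt, "dt", positive = TRUE)
  if (!out$model %in% c("fourth_order", "laplace"))
    abort_config("model must be 'fourth_order' or 'laplace'")
  if (!out$scheme %in% c("quadratic_local4", "quadratic_nonlocal", "linear_nonlocal"))
    abort_config("unknown scheme")
  if (!out$kernel %in% c("laplace", "tophat"))
    abort_config("kernel must be 'laplace' or 'tophat'")
  if (!is.list(out$env) || is.null(out$env$type) ||
      !out$env$type %in% config_allowed_env)
    abort_config("env block must have type fourier|clump|two_clump")
  class(out) <- "aggdiff_config"
  out
}

config_env <- function(cfg) {
  e <- cfg$env
  switch(e$type,
         clump = clump_env(e$n, e$amplitude),
         two_clump = two_clump_env(e$amplitude),
         fourier = fourier_env(a0 = if (is.null(e$a0)) 0 else e$a0,
                               cosine_coeffs = if (is.null(e$coeffs)) numeric() else unlist(e$coeffs),
                               sine_coeffs = if (is.null(e$sine_coeffs)) numeric() else unlist(e$sine_coeffs)))
}

config_kernel <- function(cfg)
  if (cfg$kernel == "laplace") laplace_kernel(cfg$m) else tophat_kernel(cfg$delta)

config_params <- function(cfg)
  model_params(gamma = cfg$gamma, sigma = cfg$sigma, m = cfg$m, p = cfg$p,
               family = cfg$model)

#' Export a profile as two-column delimited text
#'
#' Writes `(x, u)` pairs as CSV preceded by `#` header comments recording
#' the model parameters and package version. Re-export of identical inputs
#' is bit-identical; [read_profile()] inverts it.
#'
#' @param x Grid coordinates (or an \code{aggdiff_candidate} with `u`
#'   omitted, in which case the profile is sampled on `grid_n` points across
#'   its support).
#' @param u Density values.
#' @param path Output file path.
#' @param params Optional named list recorded in the header.
#' @param grid_n Sample count for candidate input.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, u = NULL, path, params = list(), grid_n = 801L) {
  if (inherits(x, "aggdiff_candidate")) {
    sol <- x
    params <- c(list(r = sol$r, alpha0 = sol$alpha0, alpha_n = sol$alpha_n,
                     Q = sol$Q, gamma = sol$params$gamma, p = sol$params$p,
                     family = sol$params$family), params)
    x <- seq(-1, 1, length.out = grid_n)
    u <- candidate_value(sol, x)
  }
  if (length(x) != length(u)) abort_config("x and u lengths differ")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# aggdiffenv %s profile export",
                     as.character(utils::packageVersion("aggdiffenv"))), con)
  for (k in names(params))
    writeLines(sprintf("# %s = %s", k, format(params[[k]], digits = 17)), con)
  writeLines("x,u", con)
  if (length(x))
    writeLines(paste(format(x, digits = 17, trim = TRUE),
                     format(u, digits = 17, trim = TRUE), sep = ","), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) <= 1L)
    return(data.frame(x = numeric(), u = numeric()))
  utils::read.csv(text = body)
}
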