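## Configuration handling, named presets, tabular output, fixture
## generation. All commands share one flat YAML/JSON parameter schema with
## keys exactly: alpha_max, fold, hill_n, K, beta, burst, volume. Time unit
## of the shipped presets: minutes.

PARAM_KEYS <- c("alpha_max", "fold", "hill_n", "K", "beta", "burst", "volume")
OPTION_KEYS <- c("s_cutoff", "t_max", "f_min", "theta", "level", "seed",
                 "reps", "t_end")

#' Named parameter presets
#'
#' Presets mirroring the parameter choices used for the package's standard
#' analyses (time unit: minutes; concentration unit: copies per cell volume,
#' `volume = 1`):
#' * `"toy"`: unit-rate circuit (`alpha_max = 1`, `fold = 100`,
#'   `hill_n = 1`, `K = 1`, `beta = 1`, `burst = 1`, `volume = 1`) used by
#'   the worked sensitivity example (`S_max = 5.5`).
#' * `"fig2"`: bistability phase diagram conditions (composite `c = 10`).
#' * `"fig3"`: threshold-response conditions (`c = 4`, threshold input
#'   `theta_c = 1/c = 0.25`).
#' * `"fig4"`: induction-time conditions — `alpha_max = 1` per min,
#'   `beta = 0.025` per min (dilution at a ~28 min doubling time),
#'   `burst = 5`, `K = 20` copies, `volume = 1` (`c = 10`); `fold` and
#'   `hill_n` are the scanned axes and default to 100 and 1.
#' * `"fig5"`: as `"fig4"`, plus the admissibility cutoffs
#'   (`s_cutoff = 3`, `t_max = 50` min, `f_min = 10`) as options.
#'
#' @param name Preset name.
#' @return A list with elements `params` ([circuit_params()]) and `options`
#'   (possibly empty list).
#' @export
preset <- function(name) {
  base <- list(alpha_max = 1, fold = 100, hill_n = 1, K = 20, beta = 0.025,
               burst = 5, volume = 1)
  cfg <- switch(name,
    toy  = list(params = list(alpha_max = 1, fold = 100, hill_n = 1, K = 1,
                              beta = 1, burst = 1, volume = 1),
                options = list()),
    fig2 = list(params = utils::modifyList(base, list(hill_n = 2)),
                options = list()),
    fig3 = list(params = utils::modifyList(base, list(K = 50)),
                options = list(theta = 0.5)),
    fig4 = list(params = base, options = list(level = 0.5)),
    fig5 = list(params = base,
                options = list(s_cutoff = 3, t_max = 50, f_min = 10,
                               level = 0.5)),
    stop(sprintf("unknown preset '%s' (known: toy, fig2, fig3, fig4, fig5)",
                 name), call. = FALSE))
  cfg$params <- do.call(circuit_params, cfg$params)
  cfg$preset <- name
  cfg
}

#' Load a run configuration from file, preset, and overrides
#'
#' Reads a flat YAML or JSON mapping with parameter keys exactly
#' `alpha_max, fold, hill_n, K, beta, burst, volume` (a nested `params:`
#' block is also accepted; recognised option keys such as `s_cutoff`,
#' `t_max`, `f_min`, `theta`, `level`, `seed`, `reps`, `t_end` are collected
#' separately). Unknown keys raise a warning; missing parameter keys are an
#' error. Overrides win over file values, which win over preset values.
#'
#' @param path Path to a YAML/JSON file, or NULL.
#' @param preset_name Optional preset name (see [preset()]).
#' @param overrides Named list of parameter/option overrides (e.g. from CLI
#'   flags).
#' @return A list of class `run_config` with `params` ([circuit_params()])
#'   and `options`.
#' @export
load_config <- function(path = NULL, preset_name = NULL, overrides = list()) {
  params <- list(); options <- list()
  if (!is.null(preset_name)) {
    pr <- preset(preset_name)
    params <- unclass(pr$params)[PARAM_KEYS]
    options <- pr$options
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                                 call. = FALSE)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.null(raw$params)) {
      file_params <- raw$params
      file_opts <- raw[setdiff(names(raw), "params")]
    } else {
      file_params <- raw[intersect(names(raw), PARAM_KEYS)]
      file_opts <- raw[setdiff(names(raw), PARAM_KEYS)]
    }
    unknown <- setdiff(names(file_params), PARAM_KEYS)
    unknown <- c(unknown, setdiff(names(file_opts), OPTION_KEYS))
    if (length(unknown))
      warning(sprintf("ignoring unknown config keys: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    params <- utils::modifyList(params, file_params[intersect(names(file_params),
                                                       PARAM_KEYS)])
    options <- utils::modifyList(options, file_opts[intersect(names(file_opts),
                                                       OPTION_KEYS)])
  }
  if (length(overrides)) {
    ov_par <- overrides[intersect(names(overrides), PARAM_KEYS)]
    ov_opt <- overrides[intersect(names(overrides), OPTION_KEYS)]
    bad <- setdiff(names(overrides), c(PARAM_KEYS, OPTION_KEYS))
    if (length(bad))
      warning(sprintf("ignoring unknown overrides: %s",
                      paste(bad, collapse = ", ")), call. = FALSE)
    params <- utils::modifyList(params, ov_par)
    options <- utils::modifyList(options, ov_opt)
  }
  missing <- setdiff(PARAM_KEYS, names(params))
  if (length(missing))
    stop(sprintf("missing parameter keys: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cfg <- list(params = do.call(circuit_params, params[PARAM_KEYS]),
              options = options)
  class(cfg) <- "run_config"
  cfg
}

#' Write a table with a JSON metadata sidecar
#'
#' Writes a data frame as TSV (floats at 10 significant digits, deterministic
#' column order as given) or JSON, plus a `<path>.meta.json` sidecar holding
#' the resolved configuration and package version. An empty table produces a
#' header-only file.
#'
#' @param x A data frame (e.g. `as.data.frame(phase_grid)`, or a trace).
#' @param path Output path; `"-"` writes TSV to stdout (no sidecar).
#' @param format `"tsv"` (default) or `"json"`.
#' @param config Optional configuration recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, format = c("tsv", "json"), config = NULL) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(col) signif(col, 10))
  if (identical(path, "-")) {
    utils::write.table(x, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (format == "tsv") {
    ok <- tryCatch({
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("failed to write '%s': %s", path,
                   conditionMessage(ok)), call. = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  meta <- list(
    tool = "autocircuit",
    version = as.character(utils::packageVersion("autocircuit")),
    columns = names(x), rows = nrow(x),
    config = if (!is.null(config)) {
      list(params = unclass(config$params)[PARAM_KEYS],
           options = config$options)
    })
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Generate preset files and small reference outputs
#'
#' Writes every named preset as a flat YAML file under `out_dir`, plus
#' reference outputs for the `"toy"` preset (steady states at the signal-off
#' and saturating inputs, and the sensitivity report) used by the test
#' suite. Generation is fully deterministic.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in c("toy", "fig2", "fig3", "fig4", "fig5")) {
    cfg <- preset(nm)
    flat <- c(unclass(cfg$params)[PARAM_KEYS], cfg$options)
    f <- file.path(out_dir, paste0(nm, ".yaml"))
    yaml::write_yaml(flat, f)
    files <- c(files, f)
  }
  toy <- preset("toy")$params
  ref <- data.frame(
    quantity = c("x_star_theta0", "x_star_theta1", "s_max_closed_form"),
    value = c(min(steady_states(0, toy)$roots$x_star),
              max(steady_states(1, toy)$roots$x_star),
              as.numeric(smax_closed_form(toy$fold, toy$hill_n))))
  f <- file.path(out_dir, "toy_reference.tsv")
  write_table(ref, f, config = preset("toy"))
  invisible(c(files, f))
}
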