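# Run-configuration files: the CLI tunables as a YAML document.

# The recognized keys and their built-in defaults (window geometry, mRMR,
# SVM, CV plan, seed, property-table path).
run_config_defaults <- function() {
  list(xi = 6L, eta = 9L,
       `n-features` = 50L, scheme = "MID",
       gamma = 0.0125, cost = 1, theta = 0.5,
       k = "6,8,10", repeats = 30L,
       seed = 1L, `property-table` = NULL)
}

#' Read / write a run-configuration file
#'
#' A YAML file holding the pipeline tunables (`xi`, `eta`, `n-features`,
#' `scheme`, `gamma`, `cost`, `theta`, `k`, `repeats`, `seed`,
#' `property-table`). Values round-trip without loss; unknown keys are
#' rejected so typos fail loudly. The model-level CLI commands
#' (`build-dataset`, `select-features`, `train`, `evaluate`) accept
#' `--config`; explicit command-line flags take precedence over the file,
#' which takes precedence over the built-in defaults.
#'
#' @param path Path to the YAML file.
#' @return Named list of tunables (`read_run_config`); `path` invisibly
#'   (`write_run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(run_config_defaults()))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  defaults <- run_config_defaults()
  for (k in names(cfg)) {
    if (!is.null(defaults[[k]]) && is.numeric(defaults[[k]]) &&
        is.integer(defaults[[k]]))
      cfg[[k]] <- as.integer(cfg[[k]])
  }
  if (!is.null(cfg$k)) cfg$k <- paste(cfg$k, collapse = ",")
  cfg
}

#' @rdname read_run_config
#' @param config Named list of tunables (a subset of the recognized keys).
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), names(run_config_defaults()))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  yaml::write_yaml(config, path)
  invisible(path)
}

# Merge precedence: explicit flag > config file > built-in default.
# optparse does not record which flags were given, so a flag is treated as
# explicit when its parsed value differs from the parser default.
merge_run_config <- function(opt, args) {
  if (is.null(opt$config)) return(opt)
  cfg <- read_run_config(opt$config)
  for (key in names(cfg)) {
    flag <- paste0("--", key)
    explicit <- any(args == flag | startsWith(args, paste0(flag, "=")))
    if (key %in% names(opt) && !explicit) opt[[key]] <- cfg[[key]]
  }
  opt
}
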