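# Structured run configuration: every model rate, seeding value and solver
# setting can be set from a YAML or JSON file; unspecified fields fall back
# to the baseline values, and unknown keys are rejected.

.config_keys <- list(
  model = c("n", "n_c", "sigma", "sigma_c", "sigma_c_ratio", "p", "q",
            "d_del", "eta", "f", "d_G", "d_B", "kappa", "alpha_base"),
  seeding = c("B1_0", "B2_0", "G1_0", "G2_0"),
  solver = c("rel_tol", "abs_tol", "t_max", "termination_floor", "store_dt"),
  experiment = c("type", "ratios", "fractions", "p_grid", "total_B",
                 "clone", "bracket", "tol", "success_threshold")
)

.experiment_types <- c("simulate", "sweep-sigma", "sweep-seeding", "sweep-p",
                       "thresholds")

check_keys <- function(block, name) {
  if (is.null(block)) return(list())
  if (!is.list(block)) {
    stop("config block `", name, "` must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(block), .config_keys[[name]])
  if (length(unknown)) {
    stop("unknown key(s) in config block `", name, "`: ",
         paste(unknown, collapse = ", "),
         "\n  allowed: ", paste(.config_keys[[name]], collapse = ", "),
         call. = FALSE)
  }
  block
}

#' Assemble a validated run configuration
#'
#' Builds the full set of model parameters, seeding values, solver settings
#' and experiment description from (possibly empty) partial blocks. All type
#' invariants are enforced: the mutation probabilities must form a simplex,
#' rates must be non-negative, and `n_c` is derived from `n` unless
#' overridden.
#'
#' @param model Named list of model-parameter overrides. `sigma_c` may be
#'   given either absolutely or as `sigma_c_ratio` (relative to `sigma`), not
#'   both.
#' @param seeding Named list of seeding overrides.
#' @param solver Named list of solver-setting overrides.
#' @param experiment Named list describing the experiment to run: `type` is
#'   one of `"simulate"`, `"sweep-sigma"`, `"sweep-seeding"`, `"sweep-p"`,
#'   `"thresholds"`, plus any grid/bracket fields the experiment needs.
#' @return An object of class `run_config` with elements `params`
#'   ([gc_parameters()]), `seeding` ([gc_seeding()]), `settings`
#'   ([solver_settings()]) and `experiment`.
#' @examples
#' run_config()                                   # full baseline
#' run_config(model = list(n = 50))               # n_c auto-derived as 34
#' @export
run_config <- function(model = list(), seeding = list(), solver = list(),
                       experiment = list()) {
  model <- check_keys(model, "model")
  seeding <- check_keys(seeding, "seeding")
  solver <- check_keys(solver, "solver")
  experiment <- check_keys(experiment, "experiment")

  # [[ ]] throughout: `$` would partially match (e.g. model$n to n_c)
  kernel <- mutation_kernel(
    p = model[["p"]] %||% 0.18,
    q = model[["q"]] %||% 0.5,
    d_del = model[["d_del"]] %||% 0.3
  )
  n <- model[["n"]] %||% 8
  sigma <- model[["sigma"]] %||% 1.7e-4
  if (!is.null(model[["sigma_c"]]) && !is.null(model[["sigma_c_ratio"]])) {
    stop("specify `sigma_c` or `sigma_c_ratio`, not both", call. = FALSE)
  }
  sigma_c <- model[["sigma_c"]] %||%
    ((model[["sigma_c_ratio"]] %||% 0.5) * sigma)
  params <- gc_parameters(
    n = n, sigma = sigma, sigma_c = sigma_c, kernel = kernel,
    eta = model[["eta"]] %||% 1e-5, f = model[["f"]] %||% 1e-5,
    d_G = model[["d_G"]] %||% 0.01, d_B = model[["d_B"]] %||% 0.8,
    kappa = model[["kappa"]] %||% 1.2,
    alpha_base = model[["alpha_base"]] %||% 8,
    n_c = model[["n_c"]] %||% plasma_threshold_stage(n)
  )
  seeding_obj <- gc_seeding(
    B1_0 = seeding[["B1_0"]] %||% 50, B2_0 = seeding[["B2_0"]] %||% 50,
    G1_0 = seeding[["G1_0"]] %||% 5000, G2_0 = seeding[["G2_0"]] %||% 5000
  )
  settings <- solver_settings(
    rel_tol = solver[["rel_tol"]] %||% 1e-8,
    abs_tol = solver[["abs_tol"]] %||% 1e-10,
    t_max = solver[["t_max"]] %||% 250,
    termination_floor = solver[["termination_floor"]] %||% 1,
    store_dt = solver[["store_dt"]] %||% 0.1
  )
  type <- experiment[["type"]] %||% "simulate"
  if (!type %in% .experiment_types) {
    stop("unknown experiment type `", type, "`; must be one of: ",
         paste(.experiment_types, collapse = ", "), call. = FALSE)
  }
  experiment$type <- type
  structure(
    list(params = params, seeding = seeding_obj, settings = settings,
         experiment = experiment),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>  experiment:", x$experiment$type, "\n")
  print(x$params)
  print(x$seeding)
  invisible(x)
}

#' Canonical plain-list form of a run configuration
#'
#' Fully resolved (every default filled in), suitable for serialization;
#' [load_run_config()] of a file written from this form reproduces the
#' configuration exactly.
#'
#' @param config A [run_config()] object.
#' @return A nested plain list with blocks `model`, `seeding`, `solver`,
#'   `experiment`.
#' @export
as_config_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  list(
    model = list(n = p$n, n_c = p$n_c, sigma = p$sigma, sigma_c = p$sigma_c,
                 p = p$kernel$p, q = p$kernel$q, d_del = p$kernel$d_del,
                 eta = p$eta, f = p$f, d_G = p$d_G, d_B = p$d_B,
                 kappa = p$kappa, alpha_base = p$alpha_base),
    seeding = unclass(config$seeding),
    solver = unclass(config$settings),
    experiment = config$experiment
  )
}

#' Load a run configuration from a YAML or JSON file
#'
#' Files with extension `.json` are parsed with jsonlite, everything else
#' with the yaml parser. An empty file yields the full baseline
#' configuration. Unknown keys and invariant violations (e.g. mutation
#' probabilities summing past 1) are rejected with field-level messages.
#'
#' @param path Path to the configuration file.
#' @return A [run_config()] object.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # keep YAML 1.1 implicit booleans as literal strings so that the key
    # `n:` is not read as FALSE (the config has no boolean fields)
    yaml::read_yaml(path, handlers = list("bool#no" = identity,
                                          "bool#yes" = identity))
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), names(.config_keys))
  if (length(unknown)) {
    stop("unknown top-level config block(s): ",
         paste(unknown, collapse = ", "),
         "\n  allowed: ", paste(names(.config_keys), collapse = ", "),
         call. = FALSE)
  }
  run_config(model = raw$model %||% list(),
             seeding = raw$seeding %||% list(),
             solver = raw$solver %||% list(),
             experiment = raw$experiment %||% list())
}

#' Write a run configuration to a YAML or JSON file
#'
#' The fully resolved configuration is written, so the file round-trips
#' losslessly through [load_run_config()].
#'
#' @param config A [run_config()] object.
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return The path, invisibly.
#' @export
save_run_config <- function(config, path) {
  lst <- as_config_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # I(17) significant digits: doubles survive the decimal round trip
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    # 17 significant digits: doubles survive the decimal round trip exactly
    yaml::write_yaml(lst, path, precision = 17)
  }
  invisible(path)
}
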