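#' Build / load a run configuration
#'
#' A run configuration bundles condition filters, replication count, master
#' seed, criteria and network-protocol overrides. Configurations live in a
#' small YAML file (documented below) or are given inline as `overrides`;
#' every field has a replication-mode default, so an empty file reproduces
#' the full published grid at 1000 replications per cell.
#'
#' Recognised keys: `reps`, `base_seed`, `workers`, `dv_types`, `iv_dists`,
#' `sample_sizes`, `n_ivs`, `shapes` (shape strings such as `"(10,10)"`),
#' `criteria` (list of `{metric, threshold}`), `nn` (any of `max_epochs`,
#' `patience`, `validation_fraction`, `learning_rate`, `beta1`, `beta2`,
#' `epsilon`, `batch_size`, `standardize_dv`), `results_path`, `jsonl_path`.
#' Unknown keys are rejected.
#'
#' @param path Optional YAML file path.
#' @param overrides Named list merged over the file (and over the defaults).
#' @return Object of class `"nn_run_config"`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    reps = 1000L, base_seed = 1L, workers = 1L,
    dv_types = grid_levels$dv_types,
    iv_dists = grid_levels$iv_dists,
    sample_sizes = grid_levels$sample_sizes,
    n_ivs = grid_levels$n_ivs,
    shapes = vapply(grid_levels$shapes, shape_to_string, character(1)),
    criteria = NULL, nn = list(),
    results_path = NULL, jsonl_path = NULL
  )
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    from_file <- yaml::read_yaml(path)
    if (is.null(from_file)) from_file <- list()
  }
  cfg <- utils::modifyList(defaults, from_file, keep.null = TRUE)
  cfg <- utils::modifyList(cfg, overrides, keep.null = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nn_keys <- c("max_epochs", "patience", "validation_fraction",
               "learning_rate", "beta1", "beta2", "epsilon", "batch_size",
               "standardize_dv")
  bad_nn <- setdiff(names(cfg$nn), nn_keys)
  if (length(bad_nn) > 0L) {
    stop("unknown `nn` override(s): ", paste(bad_nn, collapse = ", "),
         call. = FALSE)
  }
  cfg$reps <- as.integer(cfg$reps)
  if (is.na(cfg$reps) || cfg$reps < 1L) {
    stop("configuration field `reps` must be a positive integer", call. = FALSE)
  }
  if (!all(cfg$dv_types %in% grid_levels$dv_types)) {
    stop("configuration field `dv_types` outside the grid levels", call. = FALSE)
  }
  if (!all(cfg$iv_dists %in% grid_levels$iv_dists)) {
    stop("configuration field `iv_dists` outside the grid levels", call. = FALSE)
  }
  for (s in cfg$shapes) parse_shape(s)
  if (!is.null(cfg$criteria)) {
    cfg$criteria <- lapply(cfg$criteria, function(cr) {
      de_criterion(cr$metric, cr$threshold)
    })
  }
  structure(cfg, class = "nn_run_config")
}

#' @export
print.nn_run_config <- function(x, ...) {
  cat(sprintf(
    "<nn_run_config> %d conditions x %d reps, seed %d\n",
    length(x$dv_types) * length(x$iv_dists) * length(x$sample_sizes) *
      length(x$n_ivs) * length(x$shapes),
    x$reps, x$base_seed
  ))
  invisible(x)
}

config_conditions <- function(cfg) {
  paper_grid(dv_types = cfg$dv_types, iv_dists = cfg$iv_dists,
             sample_sizes = cfg$sample_sizes, n_ivs = cfg$n_ivs,
             shapes = lapply(cfg$shapes, parse_shape))
}

config_nn <- function(cfg, cond) {
  task <- condition_task(cond)
  do.call(network_config, c(list(hidden_sizes = cond$shape, task = task),
                            cfg$nn))
}

#' Execute a run configuration
#'
#' Expands the configured condition filters into a grid and runs it.
#'
#' @param cfg An [load_config()] result.
#' @param progress Emit per-condition progress to standard error?
#' @return Results `data.frame` (written to `cfg$results_path` when set).
#' @export
run_config <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "nn_run_config"))
  conds <- config_conditions(cfg)
  rows <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    res <- run_condition(conds[[i]], cfg$reps, cfg$base_seed,
                         nn_config = config_nn(cfg, conds[[i]]),
                         criteria = cfg$criteria, workers = cfg$workers,
                         jsonl = cfg$jsonl_path)
    if (progress) {
      message(sprintf("[%d/%d] %s", i, length(conds),
                      condition_key(conds[[i]])))
    }
    rows[[i]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  if (!is.null(cfg$results_path)) write_results(out, cfg$results_path)
  out
}

#' Write / read a results table as CSV
#'
#' Numeric columns are written with 17 significant digits so a read-back
#' reproduces every value bit-exactly; rounding for display belongs in the
#' comparison report, not the data file.
#'
#' @param results Results `data.frame` in the [run_grid()] schema.
#' @param path File path.
#' @return `write_results()`: `path`, invisibly. `read_results()`: the
#'   `data.frame`.
#' @export
write_results <- function(results, path) {
  schema <- c("dv_type", "iv_dist", "sample_size", "n_iv", "shape",
              "criterion_metric", "criterion_threshold", "reps", "excluded",
              "de_count", "de_proportion")
  if (!all(schema %in% names(results))) {
    stop("results table is missing schema columns: ",
         paste(setdiff(schema, names(results)), collapse = ", "),
         call. = FALSE)
  }
  out <- results[schema]
  for (col in c("criterion_threshold", "de_proportion")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write results to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

cli_usage <- function() {
  paste(
    "usage: nullnet <subcommand> [flags]",
    "",
    "subcommands:",
    "  simulate        run a condition grid and write a results CSV",
    "    --config PATH --reps N --seed N --workers N --out PATH --jsonl PATH",
    "    --dv-types a,b --iv-dists a,b --sample-sizes 50,100 --n-ivs 3,5",
    "    --shapes '(2),(10,10)' --progress",
    "  audit           draw one large null dataset, print max |IV-DV r|",
    "    --n N --n-iv K --iv-dist d --dv-type t --seed N",
    "  compare         check a results CSV against a reference table",
    "    --results PATH --fixture 1..6|PATH --k-sigma K --out PATH",
    "  replicate-cell  re-run one replication verbosely",
    "    --sample-size N --n-iv K --shape '(7)' --iv-dist d --dv-type t",
    "    --seed BASE --rep INDEX",
    sep = "\n"
  )
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (key %in% c("progress")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("flag --", key, " needs a value", call. = FALSE)
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

split_csv_flag <- function(x) trimws(strsplit(x, ",")[[1]])

# Shapes arrive as "(2),(10,10)"; split on commas between closing and
# opening parentheses.
split_shapes_flag <- function(x) {
  trimws(strsplit(gsub("\\)\\s*,\\s*\\(", ")|(", x), "|", fixed = TRUE)[[1]])
}

cli_simulate <- function(flags) {
  overrides <- list()
  if (!is.null(flags$reps)) overrides$reps <- as.integer(flags$reps)
  if (!is.null(flags$seed)) overrides$base_seed <- as.integer(flags$seed)
  if (!is.null(flags$workers)) overrides$workers <- as.integer(flags$workers)
  if (!is.null(flags$`dv-types`)) overrides$dv_types <- split_csv_flag(flags$`dv-types`)
  if (!is.null(flags$`iv-dists`)) overrides$iv_dists <- split_csv_flag(flags$`iv-dists`)
  if (!is.null(flags$`sample-sizes`)) {
    overrides$sample_sizes <- as.integer(split_csv_flag(flags$`sample-sizes`))
  }
  if (!is.null(flags$`n-ivs`)) overrides$n_ivs <- as.integer(split_csv_flag(flags$`n-ivs`))
  if (!is.null(flags$shapes)) overrides$shapes <- split_shapes_flag(flags$shapes)
  if (!is.null(flags$out)) overrides$results_path <- flags$out
  if (!is.null(flags$jsonl)) overrides$jsonl_path <- flags$jsonl
  cfg <- load_config(flags$config, overrides)
  results <- run_config(cfg, progress = isTRUE(flags$progress))
  if (is.null(cfg$results_path)) {
    utils::write.csv(results, stdout(), row.names = FALSE, quote = FALSE)
  }
  0L
}

cli_audit <- function(flags) {
  n <- as.numeric(flags$n %||% 1e6)
  spec <- dataset_spec(
    n_total = 50L, n_iv = as.integer(flags$`n-iv` %||% 3L),
    iv_probs = flags$`iv-dist` %||% "uniform",
    dv_kind = if ((flags$`dv-type` %||% "continuous") == "continuous")
      "continuous" else "binary",
    dv_positive_rate = if ((flags$`dv-type` %||% "continuous") ==
                           "binary_imbalanced") 0.1 else 0.5
  )
  r <- independence_audit(spec, n_audit = n,
                          seed = as.integer(flags$seed %||% 1L))
  cat(sprintf("max |IV-DV correlation| at n = %g: %.6f (3-sigma null bound %.6f)\n",
              n, r, 3 / sqrt(n)))
  0L
}

cli_compare <- function(flags) {
  if (is.null(flags$results)) stop("--results is required", call. = FALSE)
  results <- read_results(flags$results)
  fixture <- flags$fixture %||% stop("--fixture is required", call. = FALSE)
  reference <- if (file.exists(fixture)) read_results(fixture) else
    reference_results(as.integer(fixture))
  comp <- compare_to_reference(results, reference,
                               k_sigma = as.numeric(flags$`k-sigma` %||% 3))
  if (!is.null(flags$out)) {
    utils::write.csv(as.data.frame(comp), flags$out, row.names = FALSE)
  }
  print(comp)
  if (sum(comp$pass %in% FALSE) > 0L) 1L else 0L
}

cli_replicate_cell <- function(flags) {
  cond <- condition(
    sample_size = as.integer(flags$`sample-size` %||% 50L),
    n_iv = as.integer(flags$`n-iv` %||% 3L),
    shape = flags$shape %||% "(2)",
    iv_dist = flags$`iv-dist` %||% "uniform",
    dv_type = flags$`dv-type` %||% "continuous"
  )
  base_seed <- as.integer(flags$seed %||% 1L)
  rep_index <- as.integer(flags$rep %||% 0L)
  seed <- derive_seed(base_seed, cond, rep_index)
  message(sprintf("condition %s, base seed %d, rep %d -> seed %d",
                  condition_key(cond), base_seed, rep_index, seed))
  out <- run_replication(cond, seed)
  message(sprintf("best epoch %d, stopped epoch %d", out$best_epoch,
                  out$stopped_epoch))
  print(out$metrics)
  cat(metrics_to_json(out$metrics,
                      extra = list(condition = condition_key(cond),
                                   seed = seed)), "\n")
  0L
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `audit`, `compare` and `replicate-cell`
#' subcommands (see `inst/cli/nullnet.R` for the `Rscript` launcher).
#' Progress and logs go to standard error; results go to files or standard
#' output. Returns instead of quitting so it can be driven in-process.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` in the launcher).
#' @return Integer exit status: 0 on success, 1 for failed comparisons, 2 on
#'   usage or configuration errors.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(2L)
  }
  sub <- args[1]
  handler <- switch(sub,
    simulate = cli_simulate,
    audit = cli_audit,
    compare = cli_compare,
    `replicate-cell` = cli_replicate_cell,
    NULL
  )
  if (is.null(handler)) {
    message("unknown subcommand: ", sub, "\n\n", cli_usage())
    return(2L)
  }
  tryCatch(
    handler(parse_flags(args[-1])),
    error = function(e) {
      message("error: ", conditionMessage(e))
      2L
    }
  )
}
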