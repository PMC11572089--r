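#' The simulation grid axes used in replication mode
#'
#' @format Named list with the canonical factor levels: sample sizes
#'   (50, 100, 200, 500), IV counts (3, 5, 10), network shapes
#'   ((2), (7), (30), (10,10), (50,50)), IV distributions (uniform, skewed)
#'   and DV types (continuous, binary_balanced, binary_imbalanced).
#' @export
grid_levels <- list(
  sample_sizes = c(50L, 100L, 200L, 500L),
  n_ivs = c(3L, 5L, 10L),
  shapes = list(2L, 7L, 30L, c(10L, 10L), c(50L, 50L)),
  iv_dists = c("uniform", "skewed"),
  dv_types = c("continuous", "binary_balanced", "binary_imbalanced")
)

#' Format / parse a network shape
#'
#' Shapes are printed as parenthesised hidden-layer widths, e.g. `"(10,10)"`.
#'
#' @param shape Integer vector of hidden-layer widths.
#' @return `shape_to_string()`: character scalar; `parse_shape()`: integer
#'   vector.
#' @export
shape_to_string <- function(shape) {
  paste0("(", paste(as.integer(shape), collapse = ","), ")")
}

#' @rdname shape_to_string
#' @param text Shape string such as `"(50,50)"` (parentheses optional).
#' @export
parse_shape <- function(text) {
  out <- as.integer(strsplit(gsub("[()[:space:]]", "", text), ",")[[1]])
  if (length(out) == 0L || any(is.na(out)) || any(out < 1L)) {
    stop("cannot parse network shape from '", text, "'", call. = FALSE)
  }
  out
}

#' Define one cell of the simulation grid
#'
#' @param sample_size Total sample size (train + test).
#' @param n_iv Number of ordinal IVs.
#' @param shape Hidden-layer widths (integer vector) or a shape string.
#' @param iv_dist `"uniform"` or `"skewed"` category probabilities.
#' @param dv_type `"continuous"`, `"binary_balanced"` (Bernoulli .5) or
#'   `"binary_imbalanced"` (Bernoulli .1).
#' @param replication_mode Restrict every axis to the canonical grid levels?
#'   Default `FALSE` so ad-hoc conditions can be explored.
#' @return Object of class `"nn_condition"`.
#' @export
condition <- function(sample_size, n_iv, shape, iv_dist = "uniform",
                      dv_type = "continuous", replication_mode = FALSE) {
  if (is.character(shape)) shape <- parse_shape(shape)
  shape <- as.integer(shape)
  iv_dist <- match.arg(iv_dist, grid_levels$iv_dists)
  dv_type <- match.arg(dv_type, grid_levels$dv_types)
  sample_size <- as.integer(sample_size)
  n_iv <- as.integer(n_iv)
  if (replication_mode) {
    ok <- sample_size %in% grid_levels$sample_sizes &&
      n_iv %in% grid_levels$n_ivs &&
      shape_to_string(shape) %in% vapply(grid_levels$shapes, shape_to_string,
                                         character(1))
    if (!ok) stop("condition outside the canonical grid", call. = FALSE)
  }
  if (sample_size < 10L || n_iv < 1L || any(shape < 1L)) {
    stop("invalid condition", call. = FALSE)
  }
  structure(list(sample_size = sample_size, n_iv = n_iv, shape = shape,
                 iv_dist = iv_dist, dv_type = dv_type),
            class = "nn_condition")
}

#' @export
print.nn_condition <- function(x, ...) {
  cat(sprintf("<nn_condition> n = %d, %d IVs, shape %s, %s IVs, %s DV\n",
              x$sample_size, x$n_iv, shape_to_string(x$shape), x$iv_dist,
              x$dv_type))
  invisible(x)
}

condition_key <- function(cond) {
  sprintf("n=%d|iv=%d|shape=%s|dist=%s|dv=%s",
          cond$sample_size, cond$n_iv, shape_to_string(cond$shape),
          cond$iv_dist, cond$dv_type)
}

condition_dataset_spec <- function(cond) {
  dataset_spec(
    n_total = cond$sample_size, n_iv = cond$n_iv, iv_probs = cond$iv_dist,
    dv_kind = if (cond$dv_type == "continuous") "continuous" else "binary",
    dv_positive_rate = if (cond$dv_type == "binary_imbalanced") 0.1 else 0.5,
    label = cond$iv_dist
  )
}

condition_task <- function(cond) {
  if (cond$dv_type == "continuous") "regression" else "classification"
}

# 32-bit FNV-1a over a string, in double arithmetic (exact below 2^53).
fnv1a32 <- function(text) {
  h <- 2166136261
  for (b in utf8ToInt(text)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h_hi <- h %/% 65536
    h_lo <- h %% 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive the RNG seed for one replication
#'
#' Stable hash (32-bit FNV-1a) of the base seed, the condition's canonical
#' text and the replication index, folded into `[0, 2^31 - 2]`. Any
#' replication in any grid can therefore be re-run in isolation from
#' `(base_seed, condition, rep_index)` alone, and subset grids reproduce the
#' full grid's cells exactly.
#'
#' @param base_seed Integer master seed for the whole grid.
#' @param cond An [condition()].
#' @param rep_index Replication index (>= 0).
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(base_seed, cond, rep_index) {
  stopifnot(inherits(cond, "nn_condition"), rep_index >= 0)
  text <- sprintf("%d|%s|rep=%d", as.integer(base_seed), condition_key(cond),
                  as.integer(rep_index))
  as.integer(fnv1a32(text) %% 2147483647)
}

#' Run one replication end to end
#'
#' Seeds the RNG, generates a null dataset for the condition, splits it
#' 80:20, trains the configured network on the training partition
#' (standardization, validation holdout, Adam, early stopping), scores the
#' test partition, applies the exclusion rules and evaluates the
#' decision-error criteria. The RNG stream is consumed in a fixed order
#' (IV matrix column-major, DV, split permutation, validation holdout, weight
#' initialisation, per-epoch batch shuffles), so the outcome is a pure
#' function of `(condition, config, seed)`.
#'
#' @param cond An [condition()].
#' @param seed Integer seed for this replication (see [derive_seed()]).
#' @param nn_config Optional [network_config()]; by default the condition's
#'   shape and task with protocol defaults.
#' @param criteria Optional list of [de_criterion()]; defaults to
#'   [default_criteria()] for the condition's DV kind.
#' @param train_fraction Train share of the 80:20 split.
#' @return Object of class `"nn_replication"`: `condition`, `seed`,
#'   `metrics` ([metrics_report()]), `flags` (named DE logicals, `NA` when
#'   excluded), `best_epoch`, `stopped_epoch`.
#' @export
run_replication <- function(cond, seed, nn_config = NULL, criteria = NULL,
                            train_fraction = 0.8) {
  stopifnot(inherits(cond, "nn_condition"))
  task <- condition_task(cond)
  if (is.null(nn_config)) nn_config <- network_config(cond$shape, task)
  if (nn_config$task != task) {
    stop("network task does not match the condition's DV type", call. = FALSE)
  }
  if (is.null(criteria)) {
    criteria <- default_criteria(if (task == "regression") "continuous"
                                 else "binary")
  }
  set.seed(as.integer(seed))
  data <- generate_dataset(condition_dataset_spec(cond))
  split <- split_dataset(data, train_fraction)
  fit <- train_network(split, nn_config)
  scores <- predict_scores(fit, split$test$iv_matrix)
  report <- metrics_report(split$test$dv_vector, scores, task)
  structure(
    list(condition = cond, seed = as.integer(seed), metrics = report,
         flags = evaluate_criteria(report, criteria),
         best_epoch = fit$trace$best_epoch,
         stopped_epoch = fit$trace$stopped_epoch),
    class = "nn_replication"
  )
}

#' Estimate decision-error proportions for one condition
#'
#' Runs `reps` independent replications (seeded via [derive_seed()], so the
#' result is identical for any worker count or execution order) and
#' aggregates the per-criterion decision-error flags. Excluded replications
#' are removed from both the numerator and the denominator: the proportion is
#' `DE count / (reps - excluded)`.
#'
#' @param cond An [condition()].
#' @param reps Number of replications (>= 1).
#' @param base_seed Master seed.
#' @param nn_config,criteria Optional overrides as in [run_replication()].
#' @param workers Parallel workers for replications (forked via
#'   `parallel::mclapply`; default 1 = serial).
#' @param jsonl Optional path: appends one JSON metrics record per
#'   replication.
#' @return Object of class `"nn_condition_result"`: the condition,
#'   `reps_attempted`, `reps_excluded`, named `de_count` and `de_proportion`
#'   vectors, and `degenerate` (`TRUE` when every replication was excluded,
#'   leaving the proportions undefined).
#' @export
run_condition <- function(cond, reps, base_seed, nn_config = NULL,
                          criteria = NULL, workers = 1L, jsonl = NULL) {
  stopifnot(inherits(cond, "nn_condition"))
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  run_one <- function(i) {
    run_replication(cond, derive_seed(base_seed, cond, i - 1L),
                    nn_config = nn_config, criteria = criteria)
  }
  outcomes <- if (workers > 1L) {
    parallel::mclapply(seq_len(reps), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(reps), run_one)
  }
  if (!is.null(jsonl)) {
    con <- file(jsonl, open = "a")
    on.exit(close(con))
    for (o in outcomes) {
      writeLines(metrics_to_json(o$metrics, extra = list(
        condition = condition_key(cond), seed = o$seed
      )), con)
    }
  }
  flags <- do.call(rbind, lapply(outcomes, `[[`, "flags"))
  excluded <- sum(vapply(outcomes, function(o) o$metrics$exclusion != "INCLUDED",
                         logical(1)))
  m <- reps - excluded
  de_count <- colSums(flags, na.rm = TRUE)
  structure(
    list(condition = cond, reps_attempted = as.integer(reps),
         reps_excluded = as.integer(excluded),
         de_count = de_count,
         de_proportion = if (m > 0) de_count / m else de_count * NA_real_,
         degenerate = m == 0L,
         exclusions = table(vapply(outcomes, function(o) o$metrics$exclusion,
                                   character(1)))),
    class = "nn_condition_result"
  )
}

#' @export
print.nn_condition_result <- function(x, ...) {
  print(x$condition)
  cat(sprintf("  %d replications, %d excluded%s\n", x$reps_attempted,
              x$reps_excluded, if (x$degenerate) " (all: degenerate)" else ""))
  for (k in names(x$de_proportion)) {
    cat(sprintf("  %-10s DE proportion %.4f (%d/%d)\n", k,
                x$de_proportion[[k]], x$de_count[[k]],
                x$reps_attempted - x$reps_excluded))
  }
  invisible(x)
}

#' @export
as.data.frame.nn_condition_result <- function(x, ...) {
  keys <- names(x$de_count)
  parts <- strsplit(keys, ">=", fixed = TRUE)
  data.frame(
    dv_type = x$condition$dv_type,
    iv_dist = x$condition$iv_dist,
    sample_size = x$condition$sample_size,
    n_iv = x$condition$n_iv,
    shape = shape_to_string(x$condition$shape),
    criterion_metric = vapply(parts, `[[`, character(1), 1L),
    criterion_threshold = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    reps = x$reps_attempted,
    excluded = x$reps_excluded,
    de_count = as.integer(x$de_count),
    de_proportion = as.numeric(x$de_proportion),
    row.names = NULL
  )
}

#' Build the replication grid (or a filtered subset)
#'
#' The full factorial is 4 sample sizes x 3 IV counts x 5 shapes per
#' (DV type, IV distribution) pair — the 60 cells of each reference table.
#'
#' @param dv_types,iv_dists,sample_sizes,n_ivs,shapes Subsets of
#'   [grid_levels]; defaults give the full grid for the chosen DV types.
#' @return List of [condition()] objects.
#' @export
paper_grid <- function(dv_types = grid_levels$dv_types,
                       iv_dists = grid_levels$iv_dists,
                       sample_sizes = grid_levels$sample_sizes,
                       n_ivs = grid_levels$n_ivs,
                       shapes = grid_levels$shapes) {
  if (!is.list(shapes)) shapes <- list(shapes)
  conds <- list()
  for (dv in dv_types) for (dist in iv_dists) for (n in sample_sizes)
    for (k in n_ivs) for (s in shapes) {
      conds[[length(conds) + 1L]] <-
        condition(n, k, s, iv_dist = dist, dv_type = dv)
    }
  conds
}

#' Run a list of conditions and collect a results table
#'
#' @param conditions List of [condition()] objects (non-empty).
#' @param reps Replications per condition.
#' @param base_seed Master seed; every replication's seed is derived from it.
#' @param criteria,nn_config Optional overrides as in [run_replication()].
#' @param workers Parallel workers per condition.
#' @param jsonl Optional JSONL log path.
#' @param progress Emit a progress line per condition to standard error?
#' @return `data.frame` in the results schema: `dv_type, iv_dist,
#'   sample_size, n_iv, shape, criterion_metric, criterion_threshold, reps,
#'   excluded, de_count, de_proportion`.
#' @export
run_grid <- function(conditions, reps, base_seed, criteria = NULL,
                     nn_config = NULL, workers = 1L, jsonl = NULL,
                     progress = FALSE) {
  if (length(conditions) == 0L) stop("empty condition list", call. = FALSE)
  rows <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    res <- run_condition(conditions[[i]], reps, base_seed,
                         nn_config = nn_config, criteria = criteria,
                         workers = workers, jsonl = jsonl)
    if (progress) {
      message(sprintf("[%d/%d] %s: %d excluded", i, length(conditions),
                      condition_key(conditions[[i]]), res$reps_excluded))
    }
    rows[[i]] <- as.data.frame(res)
  }
  do.call(rbind, rows)
}

#' Load a reference table shipped with the package
#'
#' The six published result tables, transcribed to delimited text, exposed in
#' the long results schema (`reps`, `excluded` and `de_count` are `NA`: the
#' source prints proportions only).
#'
#' @param table Table number 1..6, or omit and give `dv_type` + `iv_dist`.
#' @param dv_type,iv_dist Alternative lookup by condition family.
#' @return `data.frame` in the results schema.
#' @export
reference_results <- function(table = NULL, dv_type = NULL, iv_dist = NULL) {
  map <- data.frame(
    table = 1:6,
    dv_type = c("continuous", "continuous", "binary_balanced",
                "binary_imbalanced", "binary_balanced", "binary_imbalanced"),
    iv_dist = c("uniform", "skewed", "uniform", "uniform", "skewed", "skewed")
  )
  if (is.null(table)) {
    hit <- map$table[map$dv_type == dv_type & map$iv_dist == iv_dist]
    if (length(hit) != 1L) stop("no reference table for that combination",
                                call. = FALSE)
    table <- hit
  }
  table <- as.integer(table)
  if (!table %in% 1:6) stop("`table` must be 1..6", call. = FALSE)
  path <- system.file("extdata", sprintf("table%d.tsv", table),
                      package = "nullnet", mustWork = TRUE)
  raw <- utils::read.delim(path, check.names = FALSE)
  dv <- map$dv_type[table]
  dist <- map$iv_dist[table]
  rows <- list()
  if (table <= 2L) {
    shape_cols <- setdiff(names(raw), c("sample_size", "n_iv"))
    for (i in seq_len(nrow(raw))) for (sc in shape_cols) {
      rows[[length(rows) + 1L]] <- data.frame(
        dv_type = dv, iv_dist = dist,
        sample_size = raw$sample_size[i], n_iv = raw$n_iv[i], shape = sc,
        criterion_metric = "R2", criterion_threshold = 0.1,
        reps = NA_integer_, excluded = NA_integer_, de_count = NA_integer_,
        de_proportion = raw[[sc]][i]
      )
    }
  } else {
    metric_cols <- setdiff(names(raw), c("sample_size", "n_iv", "shape"))
    for (i in seq_len(nrow(raw))) for (mc in metric_cols) {
      parts <- strsplit(mc, ">=", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        dv_type = dv, iv_dist = dist,
        sample_size = raw$sample_size[i], n_iv = raw$n_iv[i],
        shape = raw$shape[i],
        criterion_metric = parts[1], criterion_threshold = as.numeric(parts[2]),
        reps = NA_integer_, excluded = NA_integer_, de_count = NA_integer_,
        de_proportion = raw[[mc]][i]
      )
    }
  }
  do.call(rbind, rows)
}

#' Compare simulated results with a reference table
#'
#' For each cell present in both tables the estimated proportion passes when
#' `|p_hat - p_ref| <= k_sigma * sqrt(p_ref (1 - p_ref) / m) + 1/m`, where
#' `m` is the number of included (non-excluded) replications behind the
#' estimate. The `1/m` floor keeps printed-zero cells testable: a single
#' decision error among `m` runs is then still a pass. Cells missing from the
#' reference are reported as untestable (`pass = NA`), not failures.
#'
#' @param results Results `data.frame` from [run_grid()].
#' @param reference Reference `data.frame` from [reference_results()] (or any
#'   table in the same schema).
#' @param k_sigma Width of the binomial band in standard errors (default 3).
#' @return `data.frame` of matched cells with `p_hat`, `p_ref`, `m`,
#'   `tolerance`, `z` and `pass`; attribute `"n_pass"`/`"n_fail"` summaries
#'   are printed by its `summary()`-style print.
#' @export
compare_to_reference <- function(results, reference, k_sigma = 3) {
  keys <- c("dv_type", "iv_dist", "sample_size", "n_iv", "shape",
            "criterion_metric", "criterion_threshold")
  merged <- merge(results, reference[, c(keys, "de_proportion")],
                  by = keys, all.x = TRUE, suffixes = c("", "_ref"))
  m <- merged$reps - merged$excluded
  p_ref <- merged$de_proportion_ref
  se <- sqrt(p_ref * (1 - p_ref) / m)
  tol <- k_sigma * se + 1 / m
  out <- data.frame(
    merged[keys],
    p_hat = merged$de_proportion, p_ref = p_ref, m = m,
    tolerance = tol,
    z = ifelse(se > 0, (merged$de_proportion - p_ref) / se, NA_real_),
    pass = ifelse(is.na(p_ref), NA,
                  abs(merged$de_proportion - p_ref) <= tol)
  )
  class(out) <- c("nn_comparison", "data.frame")
  out
}

#' @export
print.nn_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Reference comparison: %d cells, %d pass, %d fail, %d untestable\n",
              nrow(df), sum(df$pass %in% TRUE), sum(df$pass %in% FALSE),
              sum(is.na(df$pass))))
  print.data.frame(df, ...)
  invisible(x)
}
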