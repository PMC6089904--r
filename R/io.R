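# File I/O and the end-to-end pipeline.

#' Read a long-format dose-response assay CSV
#'
#' Expects header \code{group,dose_uM,replicate,viability}. Rows with
#' viability outside [0, 1] or non-numeric doses are rejected with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return A validated \code{drmix_data} data.frame.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("cannot parse ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (nrow(raw) == 0) stop("empty input file: ", path, call. = FALSE)
  need <- c("group", "dose_uM", "replicate", "viability")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  dose <- suppressWarnings(as.numeric(raw$dose_uM))
  if (anyNA(dose))
    stop("non-numeric dose_uM at data row(s): ",
         paste(which(is.na(dose)), collapse = ", "), call. = FALSE)
  viab <- suppressWarnings(as.numeric(raw$viability))
  bad <- which(is.na(viab) | viab < 0 | viab > 1)
  if (length(bad))
    stop("viability outside [0, 1] at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dose_response_data(raw$group, dose, raw$replicate, viab)
}

#' Write a dose-response dataset as CSV
#'
#' @param data a \code{drmix_data} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_assay_csv <- function(data, path) {
  data <- as_drmix_data(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Read a weekly cell-count CSV
#'
#' Expects header \code{week,replicate,count} with positive counts.
#'
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week", "replicate", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(raw$count) | raw$count <= 0))
    stop("counts must be positive", call. = FALSE)
  raw
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Fit all three structural models, compare them by AIC/MSE, bootstrap the
#' winning model's parameters, and (when weekly counts are supplied) build
#' the resistant/sensitive cell-number trajectory. All result tables are
#' written as CSVs under \code{out_dir} together with a run log recording the
#' seed and package version.
#'
#' @param config a named list, or path to a YAML file with the same keys:
#'   \describe{
#'     \item{input}{path to the assay CSV (or \code{dataset}, an in-memory
#'       \code{drmix_data}).}
#'     \item{counts}{optional path to a weekly counts CSV; enables the
#'       trajectory stage. Requires the winning model to be two_population.}
#'     \item{v_max}{optional fixed maximum viability; default estimated from
#'       dose-0 records.}
#'     \item{n_boot}{bootstrap resamples (default 500).}
#'     \item{ci_level}{confidence level (default 0.95).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{n_starts}{multi-start count (default 10).}
#'     \item{aicc}{use small-sample AIC (default FALSE).}
#'     \item{out_dir}{output directory (created if absent).}
#'   }
#' @return Invisibly, a list with \code{comparison}, \code{bootstrap},
#'   \code{trajectory} (or NULL) and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  cfg <- utils::modifyList(
    list(input = NULL, dataset = NULL, counts = NULL, v_max = NULL,
         n_boot = 500, ci_level = 0.95, seed = 1L, n_starts = 10,
         aicc = FALSE, out_dir = "drmix_results", n0 = NULL), config)
  data <- pipeline_stage("read", {
    if (!is.null(cfg$dataset)) as_drmix_data(cfg$dataset)
    else if (!is.null(cfg$input)) read_assay_csv(cfg$input)
    else stop("config needs 'input' (CSV path) or 'dataset'")
  })
  v_max <- if (is.null(cfg$v_max)) pipeline_stage("vmax", estimate_vmax(data))
           else cfg$v_max
  cmp <- pipeline_stage("compare",
    compare_models(data, v_max, n_starts = cfg$n_starts, aicc = cfg$aicc))
  boot <- pipeline_stage("bootstrap",
    bootstrap_ci(data, cmp$winner, n_boot = cfg$n_boot,
                 level = cfg$ci_level, v_max = v_max, seed = cfg$seed,
                 fit = cmp$fits[[cmp$winner]]))
  traj <- NULL
  if (!is.null(cfg$counts)) {
    traj <- pipeline_stage("dynamics", {
      if (cmp$winner != "two_population")
        stop("trajectory stage needs the two_population model to win")
      counts <- read_counts_csv(cfg$counts)
      gr <- growth_rate_series(counts, level = cfg$ci_level)
      n0 <- if (is.null(cfg$n0))
        mean(counts$count[counts$week == min(counts$week)]) else cfg$n0
      totals <- project_totals(n0, gr$rate, gr$lower, gr$upper)
      labs <- order_groups(data$group)
      fs <- boot[match(paste0("f_sens.", labs), boot$parameter), ]
      weeks_avail <- totals$week %in% seq_along(labs)
      fractions <- data.frame(week = seq_along(labs),
                              f_res = 1 - fs$estimate,
                              lower = 1 - fs$upper, upper = 1 - fs$lower)
      subpopulation_counts(totals[match(fractions$week, totals$week), ],
                           fractions)
    })
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_stage("write", {
    p <- list(
      comparison = file.path(cfg$out_dir, "model_comparison.csv"),
      parameters = file.path(cfg$out_dir, "parameters.csv"),
      bootstrap = file.path(cfg$out_dir, "bootstrap_ci.csv"),
      log = file.path(cfg$out_dir, "run_log.txt"))
    utils::write.csv(cmp$table, p$comparison, row.names = FALSE)
    est <- coef(cmp$fits[[cmp$winner]])
    utils::write.csv(data.frame(parameter = names(est),
                                estimate = unname(est)),
                     p$parameters, row.names = FALSE)
    utils::write.csv(as.data.frame(boot), p$bootstrap, row.names = FALSE)
    if (!is.null(traj)) {
      p$trajectory <- file.path(cfg$out_dir, "trajectory.csv")
      utils::write.csv(as.data.frame(traj), p$trajectory, row.names = FALSE)
    }
    writeLines(c(
      sprintf("drmix version: %s",
              as.character(utils::packageVersion("drmix"))),
      sprintf("seed: %d", as.integer(cfg$seed)),
      sprintf("input: %s", if (is.null(cfg$input)) "<in-memory dataset>"
              else cfg$input),
      sprintf("counts: %s", if (is.null(cfg$counts)) "<none>" else cfg$counts),
      sprintf("v_max: %.6g", v_max),
      sprintf("n_boot: %d", as.integer(cfg$n_boot)),
      sprintf("ci_level: %g", cfg$ci_level),
      sprintf("winner: %s", cmp$winner)), p$log)
    p
  })
  invisible(list(comparison = cmp, bootstrap = boot, trajectory = traj,
                 paths = paths))
}
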