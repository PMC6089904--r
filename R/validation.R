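# Mixture validation against known resistant fractions, and simulate-and-
# refit identifiability studies.

#' Estimate resistant fractions of known mixtures
#'
#' Runs the joint two-population fit with the assay grouped by mixture
#' composition (rather than by week) and reports the estimated resistant
#' fraction \code{1 - f_sens} per mixture. When measured fractions are
#' supplied, the coefficient of determination between measured and estimated
#' fractions is computed, and bootstrap intervals can be attached.
#'
#' @inheritParams fit_single_static
#' @param measured optional named numeric vector of measured resistant
#'   fractions; names must be the mixture group labels.
#' @param n_boot bootstrap resamples for fraction CIs (0 to skip).
#' @param seed bootstrap seed.
#' @return An object of class \code{drmix_mixture_validation}: list with
#'   \code{table} (per-mixture measured/estimated fractions and optional CI),
#'   \code{r_squared} (NULL without measurements) and \code{fit}.
#' @export
fit_mixture_fractions <- function(data, v_max = NULL, measured = NULL,
                                  n_boot = 0, seed = 1L, n_starts = 10) {
  data <- as_drmix_data(data)
  labs <- order_groups(data$group)
  if (length(labs) < 2)
    warning("single mixture group: fractions are unidentifiable with free LD50s",
            call. = FALSE)
  fit <- fit_two_population(data, v_max, n_starts = n_starts)
  f_res <- 1 - fit$parameters$f_sens[labs]
  tab <- data.frame(mixture = labs, estimated_f_res = unname(f_res),
                    stringsAsFactors = FALSE)
  if (n_boot > 0) {
    bs <- bootstrap_ci(data, "two_population", n_boot = n_boot,
                       v_max = fit$v_max, seed = seed, fit = fit)
    fr <- bs[match(paste0("f_sens.", labs), bs$parameter), ]
    tab$lower <- 1 - fr$upper
    tab$upper <- 1 - fr$lower
  }
  r2 <- NULL
  if (!is.null(measured)) {
    if (is.null(names(measured)) || !all(labs %in% names(measured)))
      stop("'measured' must be named by mixture group label", call. = FALSE)
    tab$measured_f_res <- unname(measured[labs])
    r2 <- r_squared(tab$measured_f_res, tab$estimated_f_res)
  }
  structure(list(table = tab, r_squared = r2, fit = fit),
            class = "drmix_mixture_validation")
}

#' @export
print.drmix_mixture_validation <- function(x, ...) {
  cat("Mixture validation (estimated resistant fraction per mixture):\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$r_squared))
    cat(sprintf("R-squared (about the line of unity): %.4f\n", x$r_squared))
  invisible(x)
}

#' Coefficient of determination between measured and estimated values
#'
#' Default convention takes residuals about the line of unity (the
#' measurement is treated as truth): \code{1 - sum((est - meas)^2) /
#' sum((meas - mean(meas))^2)}. The \code{"regression"} convention instead
#' returns the squared Pearson correlation.
#'
#' @param measured,estimated equal-length numeric vectors, n >= 2.
#' @param convention \code{"unity"} (default) or \code{"regression"}.
#' @return The R-squared value (can be negative under \code{"unity"} for
#'   predictions worse than the mean).
#' @export
r_squared <- function(measured, estimated,
                      convention = c("unity", "regression")) {
  convention <- match.arg(convention)
  if (length(measured) != length(estimated) || length(measured) < 2)
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  if (stats::var(measured) == 0)
    stop("measured values have zero variance; R-squared undefined",
         call. = FALSE)
  if (convention == "unity")
    1 - sum((estimated - measured)^2) / sum((measured - mean(measured))^2)
  else stats::cor(measured, estimated)^2
}

#' Simulate-and-refit parameter identifiability study
#'
#' Repeatedly simulates mixture assays from known two-state parameters with
#' dose-dependent noise, refits the joint two-population model to each, and
#' summarises the distribution of every parameter estimate: its 95\% band
#' across simulations and whether the generative truth lies inside.
#'
#' @param truth a \code{\link{two_pop_params}} giving the generative state
#'   parameters (its \code{f_sens} is ignored).
#' @param fractions_res resistant fractions of the simulated mixtures
#'   (default the five reference mixtures 0, 0.25, 0.5, 0.75, 1).
#' @param noise_sd scalar or per-dose noise standard deviation (with
#'   \code{noise_doses}).
#' @param noise_doses doses for a dose-dependent \code{noise_sd} profile.
#' @param n_sim number of simulated datasets (default 100).
#' @param dose_panel,replicates assay design.
#' @param seed root seed; simulation b uses a stream derived from it.
#' @param n_starts multi-start count per refit.
#' @param level band level.
#' @return An object of class \code{drmix_identifiability}: list with
#'   \code{draws} (matrix, one row per converged simulation, one column per
#'   parameter), \code{summary} (per parameter: truth, mean, band, coverage
#'   flag), \code{n_failed}, and the study settings.
#' @export
run_identifiability_study <- function(truth,
                                      fractions_res = c(0, 0.25, 0.5, 0.75, 1),
                                      noise_sd = 0.05, noise_doses = NULL,
                                      n_sim = 100,
                                      dose_panel = dox_dose_panel,
                                      replicates = 4, seed = 1L,
                                      n_starts = 10, level = 0.95) {
  if (!inherits(truth, "drmix_two_pop_params"))
    stop("'truth' must be a two_pop_params object", call. = FALSE)
  design <- make_mixture_design(fractions_res, truth, dose_panel, replicates)
  labs <- names(design$groups)
  true_vec <- c(c_sens = truth$c_sens, m_sens = truth$m_sens,
                c_res = truth$c_res, m_res = truth$m_res,
                stats::setNames(1 - fractions_res, paste0("f_res.", labs)))
  draws <- matrix(NA_real_, n_sim, length(true_vec),
                  dimnames = list(NULL, names(true_vec)))
  failed <- 0L
  for (b in seq_len(n_sim)) {
    nm <- noise_model(sd = noise_sd, doses = noise_doses,
                      seed = derive_seed(seed, b))
    sim <- simulate_assay(design, nm)
    fit <- tryCatch(
      suppressWarnings(fit_two_population(sim, v_max = truth$v_max,
                                          n_starts = n_starts)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- failed + 1L; next }
    p <- fit$parameters
    draws[b, ] <- c(p$c_sens, p$m_sens, p$c_res, p$m_res,
                    unname(p$f_sens[labs]))
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) stop("no identifiability refit converged", call. = FALSE)
  # fraction columns were collected as f_sens; report them as f_res
  fcols <- grep("^f_res\\.", colnames(draws))
  draws[, fcols] <- 1 - draws[, fcols]
  true_vec[grep("^f_res\\.", names(true_vec))] <-
    fractions_res
  a <- (1 - level) / 2
  sm <- do.call(rbind, lapply(colnames(draws), function(nm) {
    x <- draws[ok, nm]
    q <- stats::quantile(x, c(a, 1 - a), names = FALSE)
    # tiny tolerance so a degenerate (zero-noise) band still covers a truth
    # matched to optimizer precision
    tol <- 1e-5 * max(1, abs(true_vec[nm]))
    data.frame(parameter = nm, truth = unname(true_vec[nm]),
               mean = mean(x), lower = q[1], upper = q[2],
               truth_covered = true_vec[nm] >= q[1] - tol &
                 true_vec[nm] <= q[2] + tol,
               stringsAsFactors = FALSE)
  }))
  rownames(sm) <- NULL
  structure(list(draws = draws[ok, , drop = FALSE], summary = sm,
                 n_sim = n_sim, n_failed = failed, level = level,
                 fractions_res = stats::setNames(fractions_res, labs)),
            class = "drmix_identifiability")
}

#' @export
print.drmix_identifiability <- function(x, ...) {
  cat(sprintf("Identifiability study: %d simulations (%d failed refits)\n",
              x$n_sim, x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pairwise t-tests between mixture fraction-estimate distributions
#'
#' Welch two-sample t-tests between every pair of per-mixture resistant
#' fraction estimate distributions from an identifiability study, asking
#' whether neighbouring mixture compositions are statistically resolvable.
#'
#' @param report a \code{drmix_identifiability} object, or a numeric matrix
#'   with one column of fraction estimates per mixture.
#' @param correction p-value adjustment method (\code{"none"} by default;
#'   any \code{\link[stats]{p.adjust}} method, e.g. \code{"bonferroni"}).
#' @return A symmetric matrix of p-values with unit diagonal. Pairs where
#'   both distributions are degenerate (zero variance) use an exact-equality
#'   shortcut: p = 1 when the means are equal, p = 0 otherwise.
#' @export
pairwise_fraction_tests <- function(report, correction = "none") {
  mat <- if (inherits(report, "drmix_identifiability"))
    report$draws[, grep("^f_res\\.", colnames(report$draws)), drop = FALSE]
  else as.matrix(report)
  K <- ncol(mat)
  if (K < 2) stop("need >= 2 mixture distributions", call. = FALSE)
  if (nrow(mat) < 2) stop("need >= 2 estimates per mixture", call. = FALSE)
  p <- matrix(1, K, K, dimnames = list(colnames(mat), colnames(mat)))
  pairs <- utils::combn(K, 2)
  pv <- apply(pairs, 2, function(ij) {
    x <- mat[, ij[1]]; y <- mat[, ij[2]]
    if (stats::sd(x) < 1e-14 && stats::sd(y) < 1e-14) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else stats::t.test(x, y)$p.value
  })
  pv <- stats::p.adjust(pv, method = correction)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p[i, j] <- p[j, i] <- pv[k]
  }
  p
}
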