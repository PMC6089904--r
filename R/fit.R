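# Nonlinear least-squares calibration of the three structural models.
# All fits use bounded Levenberg-Marquardt (minpack.lm) with multi-start
# initialisation; the two-population fit is a single joint minimisation with
# shared state parameters across groups and a per-group mixing fraction.

fit_control <- function(maxiter = 500) {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8, maxiter = maxiter)
}

# Validate/coerce a plain data.frame into a drmix_data dataset.
as_drmix_data <- function(data) {
  if (inherits(data, "drmix_data")) return(data)
  need <- c("group", "dose_uM", "replicate", "viability")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dose_response_data(data$group, data$dose_uM, data$replicate, data$viability)
}

#' Estimate the maximum-viability normalisation from dose-0 records
#'
#' The drug-free baseline viability \code{v_max} normalises for naturally
#' occurring cell death. It is taken as the mean viability over all dose-0
#' records and then held fixed during fitting (it is not a free parameter, so
#' it never enters the model parameter counts).
#'
#' @param data a dose-response dataset containing dose-0 records.
#' @return Scalar \code{v_max} in (0, 1].
#' @export
estimate_vmax <- function(data) {
  data <- as_drmix_data(data)
  v0 <- data$viability[data$dose_uM == 0]
  if (length(v0) == 0)
    stop("no dose-0 records: supply an explicit v_max to the fit",
         call. = FALSE)
  max(mean(v0), .Machine$double.eps)
}

# Deterministic multi-start points: heuristic start + Latin-hypercube draws
# over the bounds, generated under a fixed internal seed so a fit is a
# deterministic function of its data.
lhs_starts <- function(n, ranges, log_scale) {
  if (n <= 0) return(NULL)
  u <- with_local_seed(20231117, lhs::randomLHS(n, nrow(ranges)))
  t(apply(u, 1, function(r) {
    vapply(seq_len(nrow(ranges)), function(i) {
      lo <- ranges[i, 1]; hi <- ranges[i, 2]
      if (log_scale[i]) exp(log(lo) + r[i] * (log(hi) - log(lo)))
      else lo + r[i] * (hi - lo)
    }, numeric(1))
  }))
}

# Dose whose pooled mean viability is nearest half of v_max.
dose_at_half_vmax <- function(data, v_max) {
  mu <- tapply(data$viability, data$dose_uM, mean)
  d <- as.numeric(names(mu))
  d[which.min(abs(mu - v_max / 2))]
}

run_lm <- function(fn, par, lower, upper, maxiter = 500) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par, lower = lower, upper = upper, fn = fn,
                       control = fit_control(maxiter)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(par = par, rss = Inf, ok = FALSE, info = 0))
  list(par = fit$par, rss = fit$deviance, ok = fit$info %in% 1:4,
       info = fit$info)
}

best_of_starts <- function(fn, starts, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    cand <- run_lm(fn, pmin(pmax(starts[i, ], lower), upper), lower, upper)
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  best
}

new_fit <- function(model_kind, parameters, v_max, rss, n_obs, k, converged,
                    data, diagnostics = list()) {
  structure(list(model_kind = model_kind, parameters = parameters,
                 v_max = v_max, rss = rss, n_obs = n_obs, k = k,
                 converged = converged, data = data,
                 diagnostics = diagnostics),
            class = "drmix_fit")
}

# Core single-sigmoid least squares on pooled records.
fit_sigmoid_core <- function(dose, viab, v_max, n_starts, start = NULL) {
  dmax <- max(dose)
  lower <- c(1e-3, 1e-4)
  upper <- c(2 * dmax, 10)
  fn <- function(p) viab - v_max * sigmoid_decreasing(dose, p[1], p[2])
  if (!is.null(start)) {
    starts <- matrix(start, nrow = 1)
  } else {
    mu <- tapply(viab, dose, mean)
    d <- as.numeric(names(mu))
    c0 <- d[which.min(abs(mu - v_max / 2))]
    if (c0 <= 0) c0 <- dmax / 4
    m0 <- 4 / (dmax - min(dose))
    extra <- lhs_starts(n_starts - 1,
                        rbind(c(0.05 * dmax, 1.5 * dmax),
                              c(0.25 / dmax, 40 / dmax)),
                        log_scale = c(FALSE, TRUE))
    starts <- rbind(c(c0, m0), extra)
  }
  best_of_starts(fn, starts, lower, upper)
}

#' Fit the single static sigmoid model
#'
#' Pools all records across groups and fits one decreasing logistic viability
#' curve (LD50 and slope; \code{v_max} fixed). This is the null model in
#' which drug response has no group (time) dependency.
#'
#' @param data a dose-response dataset (see \code{\link{dose_response_data}}).
#' @param v_max fixed maximum viability; defaults to
#'   \code{\link{estimate_vmax}(data)}.
#' @param n_starts number of multi-start initialisations (heuristic start
#'   plus Latin-hypercube draws over the parameter bounds).
#' @param start optional explicit start \code{c(c, m)}; suppresses
#'   multi-start (used by the bootstrap refits).
#' @return A \code{drmix_fit} with \code{k = 2} free parameters.
#' @export
fit_single_static <- function(data, v_max = NULL, n_starts = 10, start = NULL) {
  data <- as_drmix_data(data)
  if (length(unique(data$dose_uM)) < 3)
    stop("need >= 3 distinct doses", call. = FALSE)
  if (is.null(v_max)) v_max <- estimate_vmax(data)
  n <- nrow(data)
  if (stats::sd(data$viability) < 1e-12)
    return(new_fit("single_static", NULL, v_max, rss = 0, n_obs = n, k = 2,
                   converged = FALSE,
                   data = data,
                   diagnostics = list(reason = "no dose effect: all viabilities equal")))
  best <- fit_sigmoid_core(data$dose_uM, data$viability, v_max, n_starts, start)
  pars <- single_params(best$par[1], best$par[2], v_max)
  new_fit("single_static", pars, v_max, best$rss, n, k = 2,
          converged = best$ok, data = data,
          diagnostics = list(info = best$info))
}

#' Fit the single dynamic (per-group sigmoid) model
#'
#' Fits an independent sigmoid to each group, sharing only the fixed
#' \code{v_max}; equivalent to fitting a dose-response curve to each week
#' separately. The pooled residual sum of squares is the sum over groups and
#' the free-parameter count is 2 per group.
#'
#' @inheritParams fit_single_static
#' @return A \code{drmix_fit} with \code{k = 2 * n_groups}.
#' @export
fit_single_dynamic <- function(data, v_max = NULL, n_starts = 10) {
  data <- as_drmix_data(data)
  if (is.null(v_max)) v_max <- estimate_vmax(data)
  labs <- order_groups(data$group)
  per <- lapply(labs, function(g) {
    sub <- data[data$group == g, ]
    if (length(unique(sub$dose_uM)) < 3)
      stop("group '", g, "' has < 3 distinct doses", call. = FALSE)
    if (stats::sd(sub$viability) < 1e-12)
      return(list(par = c(NA, NA), rss = 0, ok = FALSE))
    fit_sigmoid_core(sub$dose_uM, sub$viability, v_max, n_starts)
  })
  ok <- vapply(per, `[[`, logical(1), "ok")
  rss <- sum(vapply(per, `[[`, numeric(1), "rss"))
  pars <- if (all(ok))
    single_dynamic_params(labs,
                          c = vapply(per, function(p) p$par[1], numeric(1)),
                          m = vapply(per, function(p) p$par[2], numeric(1)),
                          v_max = v_max)
  else NULL
  new_fit("single_dynamic", pars, v_max, rss, nrow(data),
          k = 2L * length(labs), converged = all(ok), data = data,
          diagnostics = list(group_converged = stats::setNames(ok, labs)))
}

#' Fit the two-subpopulation mixture model jointly across groups
#'
#' A single constrained least-squares problem: the sensitive and resistant
#' LD50s and slopes are shared by every group while each group has its own
#' sensitive fraction in [0, 1]. The ordering \code{c_sens < c_res} is
#' enforced by reparameterising \code{c_res = c_sens + delta} with
#' \code{delta > 0}, which removes label switching. Free parameters: 4 shared
#' plus one fraction per group.
#'
#' @inheritParams fit_single_static
#' @param start optional named list or numeric vector
#'   \code{c(c_sens, delta, m_sens, m_res, f_1..f_G)} to refit from (single
#'   start; used by the bootstrap).
#' @return A \code{drmix_fit} with \code{k = 4 + n_groups} whose
#'   \code{parameters} are a \code{\link{two_pop_params}} object and whose
#'   \code{per_group_fractions} element of \code{diagnostics} repeats the
#'   fitted sensitive fractions by group label.
#' @export
fit_two_population <- function(data, v_max = NULL, n_starts = 10,
                               start = NULL) {
  data <- as_drmix_data(data)
  if (length(unique(data$dose_uM)) < 5)
    stop("need >= 5 distinct doses", call. = FALSE)
  if (is.null(v_max)) v_max <- estimate_vmax(data)
  labs <- order_groups(data$group)
  G <- length(labs)
  gi <- match(as.character(data$group), labs)
  dose <- data$dose_uM
  viab <- data$viability
  dmax <- max(dose)
  lower <- c(1e-3, 1e-3, 1e-4, 1e-4, rep(0, G))
  upper <- c(2 * dmax, 2 * dmax, 10, 10, rep(1, G))
  fn <- function(p) {
    f <- p[4 + seq_len(G)]
    pred <- v_max * (f[gi] * sigmoid_decreasing(dose, p[1], p[3]) +
      (1 - f[gi]) * sigmoid_decreasing(dose, p[1] + p[2], p[4]))
    viab - pred
  }
  if (!is.null(start)) {
    starts <- matrix(unlist(start), nrow = 1)
    if (ncol(starts) != 4 + G) stop("start must have length 4 + n_groups",
                                    call. = FALSE)
  } else {
    c_mid <- dose_at_half_vmax(data, v_max)
    if (c_mid <= 0) c_mid <- dmax / 3
    m0 <- 4 / dmax
    heur <- c(max(c_mid / 2, 1), c_mid, m0, m0, rep(0.5, G))
    extra <- lhs_starts(n_starts - 1,
                        rbind(c(0.02 * dmax, 0.8 * dmax),
                              c(0.1 * dmax, 1.2 * dmax),
                              c(0.25 / dmax, 40 / dmax),
                              c(0.25 / dmax, 40 / dmax),
                              matrix(rep(c(0.05, 0.95), G), ncol = 2,
                                     byrow = TRUE)),
                        log_scale = c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, G)))
    starts <- rbind(heur, extra)
  }
  best <- best_of_starts(fn, starts, lower, upper)
  p <- best$par
  if (p[2] < 0.02 * dmax)
    warning("recovered LD50s nearly identical (delta = ", signif(p[2], 3),
            " uM): mixture may be unidentifiable", call. = FALSE)
  f <- stats::setNames(p[4 + seq_len(G)], labs)
  pars <- two_pop_params(p[1], p[3], p[1] + p[2], p[4], f_sens = f,
                         v_max = v_max)
  new_fit("two_population", pars, v_max, best$rss, nrow(data), k = 4L + G,
          converged = best$ok, data = data,
          diagnostics = list(info = best$info, per_group_fractions = f))
}

#' @export
coef.drmix_fit <- function(object, ...) {
  p <- object$parameters
  if (is.null(p)) return(NULL)
  switch(object$model_kind,
    single_static = c(c_ss = p$c, m_ss = p$m),
    single_dynamic = c(stats::setNames(unname(p$c), paste0("c_sd.", p$groups)),
                       stats::setNames(unname(p$m), paste0("m_sd.", p$groups))),
    two_population = c(c_sens = p$c_sens, m_sens = p$m_sens,
                       c_res = p$c_res, m_res = p$m_res,
                       stats::setNames(unname(p$f_sens),
                                       paste0("f_sens.", names(p$f_sens)))))
}

#' @export
fitted.drmix_fit <- function(object, ...) {
  p <- object$parameters
  if (is.null(p)) return(rep(NA_real_, object$n_obs))
  d <- object$data
  switch(object$model_kind,
    single_static = predict_viability(p, d$dose_uM),
    single_dynamic = vapply(seq_len(nrow(d)), function(i)
      predict_viability(p, d$dose_uM[i], group = d$group[i]), numeric(1)),
    two_population = vapply(seq_len(nrow(d)), function(i)
      predict_viability(p, d$dose_uM[i], group = d$group[i]), numeric(1)))
}

#' @export
residuals.drmix_fit <- function(object, ...) {
  object$data$viability - fitted(object)
}

#' @export
print.drmix_fit <- function(x, ...) {
  cat(sprintf("drmix fit: %s model\n", x$model_kind))
  cat(sprintf("  n_obs = %d, k = %d, rss = %.6g, mse = %.6g, converged = %s\n",
              x$n_obs, x$k, x$rss, x$rss / x$n_obs, x$converged))
  if (!is.null(x$parameters)) print(x$parameters)
  invisible(x)
}
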