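# Weekly cell counts -> per-capita growth rates -> subpopulation trajectories.

#' Per-capita growth rate between two counts
#'
#' Births per cell per day minus deaths per cell per day, estimated as
#' \code{log(n1/n0) / delta_days}.
#'
#' @param n0,n1 positive cell counts at the start and end of the interval.
#' @param delta_days elapsed days; positive.
#' @return Rate in 1/day (vectorised).
#' @export
per_capita_growth <- function(n0, n1, delta_days = 7) {
  stopifnot_finite(n0, "n0"); stopifnot_finite(n1, "n1")
  if (any(n0 <= 0) || any(n1 <= 0)) stop("counts must be > 0", call. = FALSE)
  if (any(delta_days <= 0)) stop("delta_days must be > 0", call. = FALSE)
  log(n1 / n0) / delta_days
}

#' Per-week growth rates with replicate confidence intervals
#'
#' Computes the per-capita growth rate between consecutive weeks within each
#' replicate, then summarises each week-to-week interval across replicates
#' with a t-based confidence interval.
#'
#' @param counts data.frame with columns \code{week}, \code{replicate},
#'   \code{count} (positive).
#' @param days_per_week days between consecutive week indices.
#' @param level confidence level.
#' @return data.frame with one row per interval: \code{week} (interval end),
#'   \code{rate}, \code{lower}, \code{upper}, \code{n_replicates}. Intervals
#'   with a single replicate carry \code{NA} bounds.
#' @export
growth_rate_series <- function(counts, days_per_week = 7, level = 0.95) {
  need <- c("week", "replicate", "count")
  if (!all(need %in% names(counts)))
    stop("counts needs columns week, replicate, count", call. = FALSE)
  if (any(counts$count <= 0)) stop("counts must be > 0", call. = FALSE)
  weeks <- sort(unique(counts$week))
  if (length(weeks) < 2) stop("need counts at >= 2 weeks", call. = FALSE)
  out <- lapply(seq_len(length(weeks) - 1), function(i) {
    w0 <- counts[counts$week == weeks[i], ]
    w1 <- counts[counts$week == weeks[i + 1], ]
    common <- intersect(w0$replicate, w1$replicate)
    if (length(common) == 0)
      stop("no shared replicates between weeks ", weeks[i], " and ",
           weeks[i + 1], call. = FALSE)
    dt <- (weeks[i + 1] - weeks[i]) * days_per_week
    r <- per_capita_growth(w0$count[match(common, w0$replicate)],
                           w1$count[match(common, w1$replicate)], dt)
    if (length(r) >= 2 && stats::sd(r) > 0) {
      tt <- stats::t.test(r, conf.level = level)
      data.frame(week = weeks[i + 1], rate = mean(r),
                 lower = tt$conf.int[1], upper = tt$conf.int[2],
                 n_replicates = length(r))
    } else {
      data.frame(week = weeks[i + 1], rate = mean(r),
                 lower = if (length(r) >= 2) mean(r) else NA_real_,
                 upper = if (length(r) >= 2) mean(r) else NA_real_,
                 n_replicates = length(r))
    }
  })
  do.call(rbind, out)
}

#' Project total cell numbers from per-week growth rates
#'
#' Exponential projection \code{N(w+1) = N(w) * exp(rate_w * days_per_week)}
#' starting from \code{n0}. When rate confidence bounds are supplied the
#' projection is repeated along the lower and upper rate sequences, giving a
#' compounded interval on each week's total.
#'
#' @param n0 positive starting count (week 0).
#' @param rates per-interval growth rates (1/day), in week order; \code{NA}
#'   entries are gaps and raise an error rather than being interpolated.
#' @param lower,upper optional per-interval rate confidence bounds.
#' @param days_per_week days per interval.
#' @return data.frame with \code{week} (0..length(rates)), \code{n_total}
#'   and, when bounds were given, \code{lower}/\code{upper}.
#' @export
project_totals <- function(n0, rates, lower = NULL, upper = NULL,
                           days_per_week = 7) {
  if (n0 <= 0) stop("n0 must be > 0", call. = FALSE)
  if (anyNA(rates))
    stop("missing growth rate at interval(s): ",
         paste(which(is.na(rates)), collapse = ", "), call. = FALSE)
  n <- n0 * exp(cumsum(c(0, rates * days_per_week)))
  out <- data.frame(week = 0:length(rates), n_total = n)
  if (!is.null(lower) && !is.null(upper)) {
    out$lower <- n0 * exp(cumsum(c(0, lower * days_per_week)))
    out$upper <- n0 * exp(cumsum(c(0, upper * days_per_week)))
  }
  out
}

# Interval product for positive quantities: [a_lo*b_lo, a_hi*b_hi] given
# monotone dependence; used for compounding fraction and total-count CIs.
interval_product <- function(a_lo, a_hi, b_lo, b_hi) {
  cbind(lo = a_lo * b_lo, hi = a_hi * b_hi)
}

#' Combine total cell numbers with resistant-fraction estimates
#'
#' Splits the projected total into resistant and sensitive cell numbers,
#' \code{N_res = f_res * N_total} and \code{N_sens = (1 - f_res) * N_total},
#' so that the two always sum exactly to the total. Interval compounding
#' multiplies the fraction interval with the total-count interval
#' (\code{method = "interval"}); \code{method = "mc"} instead propagates by
#' Monte-Carlo sampling of both inputs (truncated normal for the fraction,
#' log-normal for the total).
#'
#' @param totals data.frame from \code{\link{project_totals}} (columns
#'   \code{week}, \code{n_total}, optionally \code{lower}, \code{upper}).
#' @param fractions data.frame with columns \code{week}, \code{f_res} and
#'   optionally \code{lower}, \code{upper} (bootstrap CI of the resistant
#'   fraction). Weeks must match \code{totals} exactly.
#' @param method interval-arithmetic or Monte-Carlo compounding.
#' @param n_mc Monte-Carlo draws when \code{method = "mc"}.
#' @param seed seed for Monte-Carlo compounding.
#' @return data.frame of class \code{drmix_trajectory} with per-week
#'   \code{n_total}, \code{n_res}, \code{n_sens} and compounded
#'   \code{*_lower}/\code{*_upper} bounds where inputs provided them.
#' @export
subpopulation_counts <- function(totals, fractions,
                                 method = c("interval", "mc"),
                                 n_mc = 2000, seed = 1L) {
  method <- match.arg(method)
  if (!identical(as.numeric(totals$week), as.numeric(fractions$week)))
    stop("week indices of totals and fractions are misaligned", call. = FALSE)
  f <- fractions$f_res
  if (any(f < 0 | f > 1)) stop("f_res must lie in [0, 1]", call. = FALSE)
  out <- data.frame(week = totals$week, n_total = totals$n_total,
                    n_res = f * totals$n_total,
                    n_sens = (1 - f) * totals$n_total)
  have_ci <- all(c("lower", "upper") %in% names(totals)) &&
    all(c("lower", "upper") %in% names(fractions))
  if (have_ci) {
    f_lo <- pmin(pmax(fractions$lower, 0), 1)
    f_hi <- pmin(pmax(fractions$upper, 0), 1)
    if (method == "interval") {
      r <- interval_product(f_lo, f_hi, totals$lower, totals$upper)
      s <- interval_product(1 - f_hi, 1 - f_lo, totals$lower, totals$upper)
      out$n_res_lower <- r[, "lo"]; out$n_res_upper <- r[, "hi"]
      out$n_sens_lower <- s[, "lo"]; out$n_sens_upper <- s[, "hi"]
    } else {
      z <- stats::qnorm(0.975)
      qr <- with_local_seed(derive_seed(seed, 1), {
        sapply(seq_along(f), function(i) {
          fs <- stats::rnorm(n_mc, f[i], (f_hi[i] - f_lo[i]) / (2 * z))
          fs <- pmin(pmax(fs, 0), 1)
          sdlog <- (log(totals$upper[i]) - log(totals$lower[i])) / (2 * z)
          ns <- stats::rlnorm(n_mc, log(totals$n_total[i]), max(sdlog, 0))
          c(stats::quantile(fs * ns, c(0.025, 0.975)),
            stats::quantile((1 - fs) * ns, c(0.025, 0.975)))
        })
      })
      out$n_res_lower <- qr[1, ]; out$n_res_upper <- qr[2, ]
      out$n_sens_lower <- qr[3, ]; out$n_sens_upper <- qr[4, ]
    }
    out$n_total_lower <- totals$lower; out$n_total_upper <- totals$upper
  }
  class(out) <- c("drmix_trajectory", "data.frame")
  out
}
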