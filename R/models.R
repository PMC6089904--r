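#' Single sigmoid dose-response parameters
#'
#' Parameters of the single-population sigmoidal viability model
#' \deqn{V(d) = V_{max} / (1 + \exp(m (d - c)))}
#' where \code{c} is the LD50 (the dose at which viability is half of
#' \code{v_max}) and \code{m} the slope, the reciprocal of the spread of the
#' underlying lethal-dose distribution.
#'
#' @param c LD50 in µM; positive.
#' @param m slope in 1/µM; positive.
#' @param v_max maximum (drug-free) viability fraction, in (0, 1].
#' @return An object of class \code{drmix_single_params}.
#' @examples
#' p <- single_params(c = 37, m = 0.055, v_max = 0.9)
#' predict_viability(p, dose = c(0, 37, 144))
#' @export
single_params <- function(c, m, v_max = 1) {
  stopifnot_finite(c, "c"); stopifnot_finite(m, "m"); stopifnot_finite(v_max, "v_max")
  if (length(c) != 1 || length(m) != 1 || length(v_max) != 1)
    stop("single_params fields must be scalars", call. = FALSE)
  if (c <= 0) stop("LD50 'c' must be > 0", call. = FALSE)
  if (m <= 0) stop("slope 'm' must be > 0", call. = FALSE)
  if (v_max <= 0 || v_max > 1) stop("'v_max' must be in (0, 1]", call. = FALSE)
  structure(list(c = c, m = m, v_max = v_max), class = "drmix_single_params")
}

#' Per-group (dynamic) single sigmoid parameters
#'
#' One independent (LD50, slope) pair per assay group (typically week
#' post-treatment), sharing a common \code{v_max}.
#'
#' @param groups character vector of group labels.
#' @param c,m numeric vectors of per-group LD50s (µM) and slopes (1/µM),
#'   one entry per group.
#' @param v_max shared maximum viability fraction.
#' @return An object of class \code{drmix_dynamic_params}.
#' @export
single_dynamic_params <- function(groups, c, m, v_max = 1) {
  groups <- as.character(groups)
  if (length(c) != length(groups) || length(m) != length(groups))
    stop("one (c, m) pair per group required", call. = FALSE)
  stopifnot_finite(c, "c"); stopifnot_finite(m, "m")
  if (any(c <= 0)) stop("all LD50s must be > 0", call. = FALSE)
  if (any(m <= 0)) stop("all slopes must be > 0", call. = FALSE)
  if (v_max <= 0 || v_max > 1) stop("'v_max' must be in (0, 1]", call. = FALSE)
  structure(list(groups = groups, c = stats::setNames(c, groups),
                 m = stats::setNames(m, groups), v_max = v_max),
            class = "drmix_dynamic_params")
}

#' Two-subpopulation mixture parameters
#'
#' Parameters of the two-state viability model: a weighted sum of a sensitive
#' and a resistant sigmoid whose LD50s and slopes are shared across groups,
#' with a per-group sensitive fraction
#' \deqn{V(d, g) = V_{max} [ f_g S(d; c_s, m_s) + (1 - f_g) S(d; c_r, m_r) ]}
#' where \eqn{S(d; c, m) = 1/(1 + \exp(m (d - c)))}. Canonical state labelling
#' \code{c_sens < c_res} is enforced here so the sensitive state is always the
#' lower-LD50 state (the model is otherwise symmetric under relabelling).
#'
#' @param c_sens,c_res LD50s (µM) of the sensitive and resistant states;
#'   \code{c_sens < c_res} required.
#' @param m_sens,m_res slopes (1/µM); positive.
#' @param f_sens named numeric vector of per-group sensitive fractions in
#'   [0, 1]; names are the group labels. The resistant fraction is
#'   \code{1 - f_sens} by construction.
#' @param v_max shared maximum viability fraction.
#' @return An object of class \code{drmix_two_pop_params}.
#' @examples
#' p <- two_pop_params(c_sens = 22.4, m_sens = 0.06, c_res = 79.7,
#'                     m_res = 0.028, f_sens = c(wk1 = 0.8, wk2 = 0.4))
#' predict_viability(p, dose = 48, group = "wk2")
#' @export
two_pop_params <- function(c_sens, m_sens, c_res, m_res, f_sens, v_max = 1) {
  for (v in list(c_sens, m_sens, c_res, m_res)) stopifnot_finite(v, "parameters")
  stopifnot_finite(f_sens, "f_sens")
  if (c_sens <= 0 || c_res <= 0) stop("LD50s must be > 0", call. = FALSE)
  if (!(c_sens < c_res))
    stop("canonical ordering violated: need c_sens < c_res", call. = FALSE)
  if (m_sens <= 0 || m_res <= 0) stop("slopes must be > 0", call. = FALSE)
  if (any(f_sens < 0 | f_sens > 1)) stop("f_sens must lie in [0, 1]", call. = FALSE)
  if (v_max <= 0 || v_max > 1) stop("'v_max' must be in (0, 1]", call. = FALSE)
  if (is.null(names(f_sens))) names(f_sens) <- as.character(seq_along(f_sens))
  structure(list(c_sens = c_sens, m_sens = m_sens, c_res = c_res,
                 m_res = m_res, f_sens = f_sens, v_max = v_max),
            class = "drmix_two_pop_params")
}

# Numerically stable decreasing logistic: 1 / (1 + exp(m * (d - c))).
# plogis evaluates the logistic CDF in a overflow-safe way.
sigmoid_decreasing <- function(dose, c, m) stats::plogis(m * (c - dose))

#' Evaluate a viability model at given doses
#'
#' Generic over the three parameter classes. For the mixture model a
#' \code{group} label selects the per-group sensitive fraction; for the
#' dynamic model it selects the per-group sigmoid.
#'
#' @param params a parameter object created by \code{\link{single_params}},
#'   \code{\link{single_dynamic_params}} or \code{\link{two_pop_params}}.
#' @param dose numeric vector of doses (µM), non-negative.
#' @param ... passed to methods (\code{group} where applicable).
#' @return Numeric vector of viability fractions in (0, v_max).
#' @export
predict_viability <- function(params, dose, ...) UseMethod("predict_viability")

#' @rdname predict_viability
#' @export
predict_viability.drmix_single_params <- function(params, dose, ...) {
  stopifnot_finite(dose, "dose")
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  params$v_max * sigmoid_decreasing(dose, params$c, params$m)
}

#' @param group group label (dynamic and two-population methods).
#' @rdname predict_viability
#' @export
predict_viability.drmix_dynamic_params <- function(params, dose, group, ...) {
  stopifnot_finite(dose, "dose")
  group <- as.character(group)
  if (!group %in% params$groups)
    stop("unknown group label: ", group, call. = FALSE)
  params$v_max * sigmoid_decreasing(dose, params$c[[group]], params$m[[group]])
}

#' @rdname predict_viability
#' @export
predict_viability.drmix_two_pop_params <- function(params, dose, group, ...) {
  stopifnot_finite(dose, "dose")
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  group <- as.character(group)
  if (!group %in% names(params$f_sens))
    stop("unknown group label: ", group, call. = FALSE)
  f <- params$f_sens[[group]]
  params$v_max * (f * sigmoid_decreasing(dose, params$c_sens, params$m_sens) +
    (1 - f) * sigmoid_decreasing(dose, params$c_res, params$m_res))
}

#' Convert a sigmoid slope to the lethal-dose spread
#'
#' The slope of the viability sigmoid is the reciprocal of the spread (sigma)
#' of the underlying unimodal lethal-dose distribution.
#'
#' @param m slope in 1/µM; strictly positive.
#' @return Spread sigma in µM, \code{1/m}.
#' @export
sigma_from_slope <- function(m) {
  stopifnot_finite(m, "m")
  if (any(m <= 0)) stop("slope must be > 0", call. = FALSE)
  1 / m
}

#' @export
print.drmix_single_params <- function(x, ...) {
  cat(sprintf("Single sigmoid: LD50 = %.3g uM, slope = %.3g 1/uM, Vmax = %.3g\n",
              x$c, x$m, x$v_max))
  invisible(x)
}

#' @export
print.drmix_two_pop_params <- function(x, ...) {
  cat(sprintf(paste0("Two-population mixture: sensitive LD50 = %.4g uM (m = %.3g),",
                     " resistant LD50 = %.4g uM (m = %.3g), Vmax = %.3g\n"),
              x$c_sens, x$m_sens, x$c_res, x$m_res, x$v_max))
  cat("Sensitive fraction per group:\n")
  print(round(x$f_sens, 4))
  invisible(x)
}

#' @export
print.drmix_dynamic_params <- function(x, ...) {
  cat(sprintf("Per-group sigmoids (Vmax = %.3g):\n", x$v_max))
  print(data.frame(group = x$groups, ld50 = unname(x$c), slope = unname(x$m)))
  invisible(x)
}
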