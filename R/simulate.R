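#' Default 12-dose doxorubicin panel (µM)
#'
#' The dose panel used by the weekly drug-sensitivity assay design:
#' 0, 4, 14, 24, 36, 48, 60, 72, 84, 96, 120, 144 µM.
#' @export
dox_dose_panel <- c(0, 4, 14, 24, 36, 48, 60, 72, 84, 96, 120, 144)

#' Assay design: groups, dose panel and replicate structure
#'
#' @param groups named list; one entry per assay group. Each entry is a
#'   generating parameter object (\code{\link{single_params}} or a
#'   \code{\link{two_pop_params}} whose \code{f_sens} carries that group's
#'   label).
#' @param dose_panel strictly increasing non-negative doses including 0 (µM).
#' @param replicates replicates per (group, dose) cell; at least 1.
#' @return An object of class \code{drmix_design}.
#' @export
assay_design <- function(groups, dose_panel = dox_dose_panel, replicates = 4) {
  stopifnot_finite(dose_panel, "dose_panel")
  if (any(dose_panel < 0) || is.unsorted(dose_panel, strictly = TRUE))
    stop("dose_panel must be non-negative and strictly increasing", call. = FALSE)
  if (!0 %in% dose_panel) stop("dose_panel must include dose 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!is.list(groups) || length(groups) == 0 || is.null(names(groups)))
    stop("'groups' must be a non-empty named list of parameter objects",
         call. = FALSE)
  structure(list(groups = groups, dose_panel = dose_panel,
                 replicates = as.integer(replicates)),
            class = "drmix_design")
}

#' Dose-dependent measurement-noise model
#'
#' Gaussian viability noise whose standard deviation may vary with dose,
#' mirroring replicate variability measured as a function of dose. A scalar
#' \code{sd} gives dose-independent noise; a table of (dose, sd) pairs is
#' linearly interpolated (constant extrapolation beyond its range).
#'
#' @param sd scalar standard deviation, or numeric vector matching
#'   \code{doses}.
#' @param doses doses at which \code{sd} is specified (required when \code{sd}
#'   has length > 1).
#' @param seed integer root seed; all simulation randomness derives from it.
#' @return An object of class \code{drmix_noise}.
#' @export
noise_model <- function(sd = 0.05, doses = NULL, seed = 1L) {
  stopifnot_finite(sd, "sd")
  if (any(sd < 0)) stop("noise sd must be >= 0", call. = FALSE)
  if (length(sd) > 1) {
    if (is.null(doses) || length(doses) != length(sd))
      stop("'doses' must accompany a vector 'sd'", call. = FALSE)
    o <- order(doses)
    doses <- doses[o]; sd <- sd[o]
  }
  structure(list(sd = sd, doses = doses, seed = as.integer(seed)),
            class = "drmix_noise")
}

#' @rdname noise_model
#' @param noise a \code{drmix_noise} object.
#' @param dose doses at which to evaluate the noise sd.
#' @export
noise_sd_at <- function(noise, dose) {
  if (length(noise$sd) == 1) rep(noise$sd, length(dose))
  else stats::approx(noise$doses, noise$sd, xout = dose, rule = 2)$y
}

#' Construct a validated dose-response dataset
#'
#' Long-format viability records: one row per (group, dose, replicate).
#'
#' @param group group labels (week or mixture identifier).
#' @param dose_uM doses in µM.
#' @param replicate replicate identifiers.
#' @param viability viability fractions in [0, 1].
#' @return A data.frame of class \code{drmix_data} with those four columns.
#' @export
dose_response_data <- function(group, dose_uM, replicate, viability) {
  d <- data.frame(group = as.character(group), dose_uM = as.numeric(dose_uM),
                  replicate = replicate, viability = as.numeric(viability),
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty dataset", call. = FALSE)
  if (any(!is.finite(d$dose_uM)) || any(d$dose_uM < 0))
    stop("doses must be finite and >= 0", call. = FALSE)
  bad <- which(!is.finite(d$viability) | d$viability < 0 | d$viability > 1)
  if (length(bad))
    stop("viability outside [0, 1] at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  class(d) <- c("drmix_data", "data.frame")
  d
}

# Mean viability of one design group at given doses.
group_viability <- function(gen, dose) {
  if (inherits(gen, "drmix_single_params")) predict_viability(gen, dose)
  else if (inherits(gen, "drmix_two_pop_params")) {
    if (length(gen$f_sens) != 1)
      stop("design group generator must carry exactly one f_sens", call. = FALSE)
    predict_viability(gen, dose, group = names(gen$f_sens))
  } else stop("unsupported generating parameter object", call. = FALSE)
}

#' Simulate a dose-response assay
#'
#' Draws each record as the generating model's viability at its (group, dose)
#' plus zero-mean Gaussian noise with the dose's standard deviation, truncated
#' to [0, 1]. Each (group, dose) cell uses an RNG stream derived
#' deterministically from the root seed, so the same seed always reproduces
#' the same dataset regardless of iteration order, and the caller's RNG state
#' is left untouched.
#'
#' @param design an \code{\link{assay_design}}.
#' @param noise a \code{\link{noise_model}}.
#' @return A \code{drmix_data} data.frame.
#' @examples
#' des <- make_time_course_design(
#'   f_sens = seq(0.9, 0.5, length.out = 4),
#'   params = two_pop_params(22.4, 0.06, 79.7, 0.028, f_sens = 1, v_max = 0.9))
#' sim <- simulate_assay(des, noise_model(sd = 0.05, seed = 7))
#' head(sim)
#' @export
simulate_assay <- function(design, noise) {
  if (!inherits(design, "drmix_design")) stop("'design' must be an assay_design")
  if (!inherits(noise, "drmix_noise")) stop("'noise' must be a noise_model")
  labs <- names(design$groups)
  doses <- design$dose_panel
  reps <- design$replicates
  out <- vector("list", length(labs) * length(doses))
  k <- 0L
  for (i in seq_along(labs)) {
    gen <- design$groups[[i]]
    for (j in seq_along(doses)) {
      mu <- group_viability(gen, doses[j])
      s <- noise_sd_at(noise, doses[j])
      eps <- if (s > 0)
        with_local_seed(derive_seed(noise$seed, i, j), stats::rnorm(reps, 0, s))
      else numeric(reps)
      v <- pmin(pmax(mu + eps, 0), 1)
      k <- k + 1L
      out[[k]] <- data.frame(group = labs[i], dose_uM = doses[j],
                             replicate = seq_len(reps), viability = v,
                             stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  class(d) <- c("drmix_data", "data.frame")
  d
}

#' Estimate the dose-dependent noise profile from replicate spread
#'
#' Pools the within-(group, dose) sample variance across groups, dose by dose,
#' and returns the pooled standard deviation as a noise model. Doses where no
#' cell has two or more replicates contribute no degrees of freedom; their sd
#' is interpolated from neighbouring doses and flagged.
#'
#' @param data a \code{drmix_data} dataset.
#' @param seed seed carried into the returned noise model.
#' @return A \code{\link{noise_model}} with attribute \code{interpolated}
#'   naming any doses whose sd was filled in by interpolation.
#' @export
estimate_noise_from_data <- function(data, seed = 1L) {
  doses <- sort(unique(data$dose_uM))
  pooled <- vapply(doses, function(d) {
    sub <- data[data$dose_uM == d, ]
    vs <- tapply(sub$viability, sub$group, function(v) {
      n <- length(v)
      if (n < 2) c(0, 0) else c((n - 1) * stats::var(v), n - 1)
    })
    ss <- sum(vapply(vs, `[`, numeric(1), 1))
    df <- sum(vapply(vs, `[`, numeric(1), 2))
    if (df == 0) NA_real_ else sqrt(ss / df)
  }, numeric(1))
  flagged <- doses[is.na(pooled)]
  if (length(flagged)) {
    if (all(is.na(pooled)))
      stop("no dose has >= 2 replicates; cannot estimate noise", call. = FALSE)
    ok <- !is.na(pooled)
    pooled[!ok] <- stats::approx(doses[ok], pooled[ok], xout = doses[!ok],
                                 rule = 2)$y
    warning("sd interpolated at singleton dose(s): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  nm <- noise_model(sd = pooled, doses = doses, seed = seed)
  attr(nm, "interpolated") <- flagged
  nm
}

#' Mixture-validation assay design
#'
#' One assay group per known resistant fraction, each generated from the
#' two-state mixture with sensitive fraction \code{1 - fraction_res}. The
#' design mirrors reference standards made by mixing a sensitive and a
#' resistant line at ratios 1:0, 3:1, 1:1, 1:3, 0:1 (resistant fractions
#' 0, 0.25, 0.5, 0.75, 1).
#'
#' @param fractions_res resistant fractions in [0, 1], one per mixture group.
#' @param params a \code{\link{two_pop_params}} supplying the two states'
#'   LD50s, slopes and \code{v_max} (its \code{f_sens} entries are ignored).
#' @param dose_panel,replicates see \code{\link{assay_design}}.
#' @return An \code{\link{assay_design}} with group labels like
#'   \code{"res25"} for 25\% resistant.
#' @export
make_mixture_design <- function(fractions_res, params,
                                dose_panel = dox_dose_panel, replicates = 4) {
  if (length(fractions_res) == 0)
    stop("at least one mixture fraction required", call. = FALSE)
  stopifnot_finite(fractions_res, "fractions_res")
  if (any(fractions_res < 0 | fractions_res > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (!inherits(params, "drmix_two_pop_params"))
    stop("'params' must be a two_pop_params object", call. = FALSE)
  # zero-padded labels keep lexicographic group order == fraction order
  pct <- 100 * fractions_res
  labs <- if (all(abs(pct - round(pct)) < 1e-9))
    sprintf("res%03d", as.integer(round(pct)))
  else sprintf("res%07.3f", pct)
  groups <- stats::setNames(lapply(seq_along(fractions_res), function(i) {
    two_pop_params(params$c_sens, params$m_sens, params$c_res, params$m_res,
                   f_sens = stats::setNames(1 - fractions_res[i], labs[i]),
                   v_max = params$v_max)
  }), labs)
  assay_design(groups, dose_panel, replicates)
}

#' Time-course assay design
#'
#' One assay group per week with a prescribed sensitive fraction, emulating a
#' pulse-treat-then-recover experiment assayed weekly.
#'
#' @param f_sens per-week sensitive fractions in [0, 1]; names (or weeks
#'   1..n) become group labels.
#' @param params a \code{\link{two_pop_params}} supplying shared state
#'   parameters (its own \code{f_sens} is ignored).
#' @param dose_panel,replicates see \code{\link{assay_design}}.
#' @return An \code{\link{assay_design}}.
#' @export
make_time_course_design <- function(f_sens, params,
                                    dose_panel = dox_dose_panel,
                                    replicates = 4) {
  stopifnot_finite(f_sens, "f_sens")
  if (any(f_sens < 0 | f_sens > 1))
    stop("f_sens values must lie in [0, 1]", call. = FALSE)
  labs <- if (!is.null(names(f_sens))) names(f_sens)
          else sprintf("week%d", seq_along(f_sens))
  groups <- stats::setNames(lapply(seq_along(f_sens), function(i) {
    two_pop_params(params$c_sens, params$m_sens, params$c_res, params$m_res,
                   f_sens = stats::setNames(f_sens[i], labs[i]),
                   v_max = params$v_max)
  }), labs)
  assay_design(groups, dose_panel, replicates)
}
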