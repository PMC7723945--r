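#' Cartilage strain from pre/post-activity thickness
#'
#' Percent thickness change relative to the pre-activity baseline,
#' `((h_post - h_pre) / h_pre) * 100`. Negative values indicate
#' compression; swelling gives positive values and is not clamped.
#'
#' @param h_pre pre-activity thickness (mm), > 0.
#' @param h_post post-activity thickness (mm). Vectorised; `h_pre` and
#'   `h_post` are recycled against each other.
#' @return Strain in percent.
#' @examples
#' compute_strain(2.0, 1.9) # -5
#' @export
compute_strain <- function(h_pre, h_post) {
  if (any(!is.finite(h_pre)) || any(h_pre <= 0))
    stop("h_pre must be positive", call. = FALSE)
  (h_post - h_pre) / h_pre * 100
}

#' Repeat-baseline thickness difference
#'
#' Percent difference between a repeated pre-activity thickness measure
#' and the first, `((h_pre_n - h_pre_1) / h_pre_1) * 100`. With repeated
#' baselines of the same (unloaded) tissue the expected value is 0%, so
#' its mean magnitude measures the technique's strain error.
#'
#' @param h_pre_1 first pre-activity thickness (mm), > 0.
#' @param h_pre_n subsequent pre-activity thickness (mm). Vectorised.
#' @return Percent difference.
#' @export
thickness_difference <- function(h_pre_1, h_pre_n) {
  if (any(!is.finite(h_pre_1)) || any(h_pre_1 <= 0))
    stop("h_pre_1 must be positive", call. = FALSE)
  (h_pre_n - h_pre_1) / h_pre_1 * 100
}

#' Strain trajectory
#'
#' Strain versus time after activity for one subject or for a cohort
#' mean.
#'
#' @param times minutes post-activity; strictly increasing, all > 0.
#' @param strains percent strain (negative = compression), same length.
#' @param level `"subject"` or `"cohort_mean"`.
#' @param n optional per-point subject counts (for cohort means).
#' @return An object of class `strain_trajectory`.
#' @export
strain_trajectory <- function(times, strains,
                              level = c("subject", "cohort_mean"),
                              n = NULL) {
  level <- match.arg(level)
  times <- as.numeric(times); strains <- as.numeric(strains)
  if (length(times) != length(strains))
    stop("times and strains must have the same length", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be finite and > 0 (minutes post-activity)",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(strains)))
    stop("strains must be finite", call. = FALSE)
  if (is.null(n)) n <- rep(1L, length(times))
  structure(list(times = times, strains = strains, level = level,
                 n = as.integer(n)), class = "strain_trajectory")
}

#' @export
print.strain_trajectory <- function(x, ...) {
  cat(sprintf("<strain_trajectory> (%s) %d time points, %g..%g min\n",
              x$level, length(x$times), min(x$times), max(x$times)))
  print(data.frame(time_min = x$times, strain_pct = x$strains, n = x$n))
  invisible(x)
}

#' Mean strain trajectory across subjects
#'
#' Per-time-point mean over the subjects observed at that point. Subjects
#' may miss individual points (e.g. a scan dropped for motion artifact);
#' the per-point `n` records how many contributed. Points observed by no
#' subject are dropped with a warning.
#'
#' @param subject_trajs list of subject-level [strain_trajectory()]
#'   objects sharing a nominal time grid.
#' @return A cohort-mean [strain_trajectory()].
#' @export
cohort_mean_trajectory <- function(subject_trajs) {
  if (!length(subject_trajs))
    stop("need at least one subject trajectory", call. = FALSE)
  lapply(subject_trajs, function(tr) {
    if (!inherits(tr, "strain_trajectory"))
      stop("all elements must be strain_trajectory objects", call. = FALSE)
  })
  times <- sort(unique(unlist(lapply(subject_trajs, `[[`, "times"))))
  vals <- lapply(times, function(t0) {
    s <- unlist(lapply(subject_trajs, function(tr) {
      i <- match(t0, tr$times)
      if (is.na(i)) NULL else tr$strains[i]
    }))
    list(mean = if (length(s)) mean(s) else NA_real_, n = length(s))
  })
  n <- vapply(vals, `[[`, integer(1), "n")
  if (any(n == 0L)) {
    warning(sprintf("dropping time point(s) with no subjects: %s",
                    paste(times[n == 0], collapse = ", ")))
    keep <- n > 0L
    times <- times[keep]; vals <- vals[keep]; n <- n[keep]
  }
  strain_trajectory(times, vapply(vals, `[[`, numeric(1), "mean"),
                    level = "cohort_mean", n = n)
}

#' Fit the Kelvin-Voigt recovery model
#'
#' Nonlinear least squares of the two-parameter exponential
#' `strain(t) = A * exp(-B * t)` to a strain trajectory. `1/B` is
#' reported as the characteristic recovery time (minutes): with only a
#' handful of post-activity time points this first-order approximation of
#' the biphasic series is the estimable model. There is no offset term by
#' default (strain is assumed to return to 0 at full recovery); set
#' `offset = TRUE` for a diagnostic three-parameter variant
#' `A * exp(-B * t) + C`.
#'
#' @param traj a [strain_trajectory()] with at least 3 points.
#' @param offset include an additive offset term (non-default diagnostic).
#' @param B_bounds lower/upper bounds for the rate constant (1/min).
#' @return An object of class `kelvin_voigt_fit`: list with `A` (percent
#'   strain), `B` (1/min), `characteristic_recovery_time` (min, `= 1/B`),
#'   `rmse` (percent-strain points), `converged`, `n_points`, and
#'   `offset` (0 unless `offset = TRUE`).
#' @examples
#' t <- c(10, 20, 30, 40, 50)
#' fit <- fit_kelvin_voigt(strain_trajectory(t, -5 * exp(-0.04 * t)))
#' fit$characteristic_recovery_time # 25
#' @export
fit_kelvin_voigt <- function(traj, offset = FALSE,
                             B_bounds = c(1e-6, 10)) {
  if (!inherits(traj, "strain_trajectory"))
    stop("`traj` must be a strain_trajectory", call. = FALSE)
  t <- traj$times; eps <- traj$strains
  if (length(t) < 3)
    stop("need at least 3 time points to fit the recovery model",
         call. = FALSE)
  if (all(eps == 0))
    stop("all strains are zero; nothing to fit", call. = FALSE)

  A0 <- eps[1]
  B0 <- 1 / median(t)
  dat <- data.frame(t = t, eps = eps)
  fit <- NULL
  converged <- FALSE
  if (offset) {
    fit <- tryCatch(minpack.lm::nlsLM(
      eps ~ A * exp(-B * t) + C, data = dat,
      start = list(A = A0, B = B0, C = 0),
      lower = c(-Inf, B_bounds[1], -Inf),
      upper = c(Inf, B_bounds[2], Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(minpack.lm::nlsLM(
      eps ~ A * exp(-B * t), data = dat,
      start = list(A = A0, B = B0),
      lower = c(-Inf, B_bounds[1]), upper = c(Inf, B_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }

  if (is.null(fit)) {
    out <- list(A = NA_real_, B = NA_real_,
                characteristic_recovery_time = NA_real_,
                rmse = NA_real_, offset = 0, converged = FALSE,
                n_points = length(t))
    class(out) <- "kelvin_voigt_fit"
    return(out)
  }
  cf <- coef(fit)
  B <- unname(cf["B"])
  converged <- fit$convInfo$isConv %||% TRUE
  # rate pinned at a bound is a degenerate (non-recovering) fit
  at_bound <- B <= B_bounds[1] * (1 + 1e-8) || B >= B_bounds[2] * (1 - 1e-8)
  if (at_bound) {
    warning("Kelvin-Voigt rate constant hit its bound; fit flagged as not converged")
    converged <- FALSE
  }
  rmse <- sqrt(mean(resid(fit)^2))
  out <- list(A = unname(cf["A"]), B = B,
              characteristic_recovery_time = 1 / B,
              rmse = rmse,
              offset = if (offset) unname(cf["C"]) else 0,
              converged = converged, n_points = length(t))
  class(out) <- "kelvin_voigt_fit"
  out
}

#' @export
print.kelvin_voigt_fit <- function(x, ...) {
  cat("<kelvin_voigt_fit>\n")
  cat(sprintf("  A = %.4f %%, B = %.6f /min\n", x$A, x$B))
  cat(sprintf("  characteristic recovery time 1/B = %.2f min\n",
              x$characteristic_recovery_time))
  cat(sprintf("  RMSE = %.4f (%% strain), n = %d, converged = %s\n",
              x$rmse, x$n_points, x$converged))
  invisible(x)
}

#' Walking speed from the Froude number
#'
#' Dimensionless normalisation of walking speed to lower limb length:
#' `v = sqrt(Fr * L * g)`. Used to prescribe a comparable treadmill speed
#' across subjects of different stature.
#'
#' @param Fr Froude number (> 0); 0.25 is a comfortable walk.
#' @param L lower limb length in metres (> 0).
#' @param g gravitational acceleration, m/s^2.
#' @return Walking speed in m/s.
#' @examples
#' froude_walk_speed(0.25, 0.9) # about 1.49 m/s
#' @export
froude_walk_speed <- function(Fr, L, g = 9.81) {
  if (any(!is.finite(Fr)) || any(Fr <= 0))
    stop("Fr must be positive", call. = FALSE)
  if (any(!is.finite(L)) || any(L <= 0))
    stop("L must be positive (metres)", call. = FALSE)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("g must be positive", call. = FALSE)
  sqrt(Fr * L * g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
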