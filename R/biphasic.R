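#' Biphasic tissue parameters
#'
#' Material and loading parameters of the confined-compression biphasic
#' (solid matrix + interstitial fluid) description of cartilage, in SI
#' units. A convenience constructor accepting the units creep studies
#' tabulate (mm, MPa) is available via `units = "mm_MPa"`.
#'
#' @param h tissue thickness; metres, or mm with `units = "mm_MPa"`.
#' @param H_A aggregate modulus; Pa, or MPa with `units = "mm_MPa"`.
#' @param k hydraulic permeability, m^4/(N s) in both conventions.
#' @param sigma0 applied compressive stress; Pa (or MPa), >= 0.
#' @param units `"SI"` (m, Pa) or `"mm_MPa"`.
#' @return An object of class `biphasic_parameters` with fields in SI.
#' @examples
#' biphasic_parameters(2.27, 0.65, 2.00e-15, units = "mm_MPa")
#' @export
biphasic_parameters <- function(h, H_A, k, sigma0 = 0,
                                units = c("SI", "mm_MPa")) {
  units <- match.arg(units)
  if (units == "mm_MPa") {
    h <- h * 1e-3
    H_A <- H_A * 1e6
    sigma0 <- sigma0 * 1e6
  }
  vals <- c(h = h, H_A = H_A, k = k)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("h, H_A and k must be positive", call. = FALSE)
  if (!is.finite(sigma0) || sigma0 < 0)
    stop("sigma0 must be >= 0", call. = FALSE)
  structure(list(h = h, H_A = H_A, k = k, sigma0 = sigma0),
            class = "biphasic_parameters")
}

#' @export
print.biphasic_parameters <- function(x, ...) {
  cat(sprintf(paste0("<biphasic_parameters> h = %.3f mm, H_A = %.3f MPa, ",
                     "k = %.3g m^4/Ns, sigma0 = %.3g MPa\n"),
              x$h * 1e3, x$H_A / 1e6, x$k, x$sigma0 / 1e6))
  cat(sprintf("  time constant %.1f s, characteristic time %.1f min\n",
              time_constant(x), characteristic_time(x)))
  invisible(x)
}

#' Biphasic gel diffusion time constant
#'
#' `tau = h^2 / (H_A * k)`: the time scale on which interstitial fluid
#' redistributes through the solid matrix under confined compression.
#'
#' @param p a [biphasic_parameters()] object.
#' @return Time constant in seconds.
#' @export
time_constant <- function(p) {
  if (!inherits(p, "biphasic_parameters"))
    stop("`p` must be biphasic_parameters", call. = FALSE)
  p$h^2 / (p$H_A * p$k)
}

#' Characteristic time of biphasic creep/recovery
#'
#' `tau0 = (4 / pi^2) * h^2 / (H_A * k)`: the decay time of the slowest
#' (first, n = 0) mode of the biphasic creep series, i.e. the time scale
#' that dominates the approach to equilibrium. Reported in minutes, the
#' unit used when comparing with in vivo recovery fits.
#'
#' @param p a [biphasic_parameters()] object.
#' @return Characteristic time in minutes.
#' @examples
#' characteristic_time(
#'   biphasic_parameters(2.27, 0.65, 2.00e-15, units = "mm_MPa")) # 26.8
#' @export
characteristic_time <- function(p) {
  (4 / pi^2) * time_constant(p) / 60
}

#' Biphasic confined-compression creep strain
#'
#' Series solution for the creep strain under a constant applied stress:
#' `strain(t) = -(sigma0 / H_A) * (1 - 2 * sum_n (1/M_n) exp(-(M_n/tau) t))`
#' with `M_n = pi^2 (n + 1/2)^2` and `tau = h^2/(H_A k)`. The strain is 0
#' at `t = 0` (the mode weights sum to 1/2 exactly) and tends to the
#' equilibrium `-sigma0/H_A` as `t -> Inf`.
#'
#' `t = 0` is evaluated through that closed-form normalisation rather than
#' by summation (term magnitudes decay only as `1/n^2` there); for
#' `t > 0` the series is truncated adaptively when the next term falls
#' below `1e-12`, with a hard cap of `n_terms` terms.
#'
#' @param p a [biphasic_parameters()] object.
#' @param t time(s) in seconds, >= 0; vectorised.
#' @param n_terms maximum number of series terms.
#' @return Strain as a dimensionless fraction (negative = compression).
#' @export
biphasic_strain <- function(p, t, n_terms = 10000L) {
  if (!inherits(p, "biphasic_parameters"))
    stop("`p` must be biphasic_parameters", call. = FALSE)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0 (seconds)", call. = FALSE)
  tau <- time_constant(p)
  amp <- p$sigma0 / p$H_A
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    s <- 0
    for (n in seq_len(n_terms) - 1L) {
      M <- pi^2 * (n + 0.5)^2
      term <- (1 / M) * exp(-(M / tau) * ti)
      s <- s + term
      if (term < 1e-12) break
    }
    -amp * (1 - 2 * s)
  }, numeric(1))
}
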