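#' Phantom specification
#'
#' Parameters of a synthetic phantom with known ground truth. The same
#' spec with the same seed always reproduces the identical phantom.
#'
#' @param kind `"parallel_plate"`, `"paraboloid_cartilage"`,
#'   `"recovery_sequence"` or `"relaxation_stack"`.
#' @param params named list of kind-specific parameters (see the
#'   generator functions for each kind's defaults).
#' @param noise `"none"`, `"gaussian"` or `"rician"`.
#' @param sigma noise scale (mm for mesh perturbation, intensity units
#'   for image stacks).
#' @param seed RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("parallel_plate", "paraboloid_cartilage",
                                  "recovery_sequence", "relaxation_stack"),
                         params = list(),
                         noise = c("none", "gaussian", "rician"),
                         sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  noise <- match.arg(noise)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(kind = kind, params = params, noise = noise,
                 sigma = sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

default_params <- function(spec, defaults) {
  p <- utils::modifyList(defaults, spec$params)
  p
}

# Rectangular lattice of xy sampling columns. Interior nodes are
# jittered (deterministically, from `seed`) so the point set is generic:
# a perfectly regular lattice is symmetric under a 180-degree flip and
# aliases ICP correspondences, neither of which real anatomy does.
# Boundary nodes stay on the exact footprint so the bounding box is
# spacing-independent. Bone and cartilage share these columns, which
# keeps the node-to-node thickness equal to the analytic field exactly.
lattice_columns <- function(extent, spacing, jitter, seed) {
  xs <- seq(0, extent[1], by = spacing)
  ys <- seq(0, extent[2], by = spacing)
  g <- expand.grid(x = xs, y = ys)
  if (jitter > 0) {
    amp <- jitter * spacing
    j <- with_seed(seed, matrix(runif(2 * nrow(g), -amp, amp), ncol = 2))
    interior_x <- g$x > 0 & g$x < extent[1]
    interior_y <- g$y > 0 & g$y < extent[2]
    g$x <- g$x + j[, 1] * interior_x
    g$y <- g$y + j[, 2] * interior_y
  }
  list(xy = cbind(g$x, g$y), faces = grid_faces(length(xs), length(ys)))
}

#' Generate a cartilage-on-bone mesh phantom
#'
#' Builds a bone mesh (flat plate at z = 0) and a cartilage mesh whose
#' height above the bone follows an analytic thickness field, so the true
#' node-to-node thickness is known in closed form at every vertex:
#'
#' * `parallel_plate`: uniform thickness `gap` over a rectangular
#'   footprint — thickness is `gap` everywhere.
#' * `paraboloid_cartilage`: a paraboloid cap,
#'   `t(r) = apex * (1 - r^2 / R^2)` about the footprint centre, floored
#'   at `floor_mm` so the sheet never touches the bone.
#'
#' Bone and cartilage share the same lattice in x/y, so the nearest bone
#' node of each cartilage vertex is the node directly beneath it and the
#' analytic field is exact for the node-to-node definition. Gaussian
#' noise (if requested) perturbs cartilage heights after the ground truth
#' is recorded.
#'
#' @param spec a [phantom_spec()] of kind `parallel_plate` or
#'   `paraboloid_cartilage`. Common params: `extent` (mm, default
#'   `c(40, 20)`), `spacing` (mm, default 0.5); `gap` (default 3) for the
#'   plate; `apex` (default 4), `R` (default 20), `floor_mm` (default
#'   0.2) for the paraboloid.
#' @return list(`bone`, `cartilage`, `thickness_field` (function of x,
#'   y), `truth` (data.frame of per-vertex true thickness), `spec`).
#' @export
make_cartilage_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  if (!spec$kind %in% c("parallel_plate", "paraboloid_cartilage"))
    stop(sprintf("unknown mesh phantom kind '%s'", spec$kind),
         call. = FALSE)

  if (spec$kind == "parallel_plate") {
    p <- default_params(spec, list(extent = c(40, 20), spacing = 0.5,
                                   gap = 3, jitter = 0.2))
    tfield <- function(x, y) rep(p$gap, length(x))
  } else {
    p <- default_params(spec, list(extent = c(40, 40), spacing = 0.5,
                                   apex = 4, R = 20, floor_mm = 0.2,
                                   jitter = 0.2))
    cx <- p$extent[1] / 2; cy <- p$extent[2] / 2
    tfield <- function(x, y) {
      r2 <- (x - cx)^2 + (y - cy)^2
      pmax(p$apex * (1 - r2 / p$R^2), p$floor_mm)
    }
  }
  cols <- lattice_columns(p$extent, p$spacing, p$jitter, spec$seed)
  bone <- surface_mesh(cbind(cols$xy, 0), cols$faces, "bone")
  cart <- surface_mesh(cbind(cols$xy, tfield(cols$xy[, 1], cols$xy[, 2])),
                       cols$faces, "cartilage")
  truth <- data.frame(vertex = seq_len(nrow(cart$vertices)),
                      thickness_mm = tfield(cart$vertices[, 1],
                                            cart$vertices[, 2]))
  if (spec$noise == "gaussian" && spec$sigma > 0) {
    cart$vertices[, 3] <- cart$vertices[, 3] +
      with_seed(spec$seed, rnorm(nrow(cart$vertices), 0, spec$sigma))
  }
  list(bone = bone, cartilage = cart, thickness_field = tfield,
       truth = truth, spec = spec)
}

#' Generate a post-activity recovery scan sequence
#'
#' Emulates a baseline scan followed by serial post-activity scans whose
#' true site strain follows the Kelvin-Voigt recovery law
#' `A * exp(-B * t)` percent: cartilage heights are scaled by
#' `1 + strain/100` at each time point. Each post-activity "scan" may be
#' rigidly perturbed (rotation + translation of bone and cartilage
#' together) so the registration step has real work to do.
#'
#' @param spec a [phantom_spec()]; the underlying geometry is the mesh
#'   phantom of `spec$params$geometry` (default `"parallel_plate"`) with
#'   the same params.
#' @param A strain amplitude, percent (negative = compression).
#' @param B recovery rate constant, 1/min; must be > 0. The true
#'   characteristic recovery time is `1/B` minutes.
#' @param times post-activity scan times, minutes.
#' @param perturb logical: rigidly perturb each post scan (rotations up
#'   to `max_angle_deg`, translations up to `max_shift_mm`, drawn from
#'   `spec$seed`).
#' @param max_angle_deg,max_shift_mm perturbation magnitudes.
#' @return list with `baseline` (the unperturbed phantom), `scans` (one
#'   element per time: `time_min`, `bone`, `cartilage`, `true_strain_pct`,
#'   `applied_transform`), and `truth` (`A`, `B`,
#'   `characteristic_recovery_time`, per-time strain).
#' @export
make_recovery_sequence <- function(spec, A = -5, B = 0.04,
                                   times = c(10, 20, 30, 40, 50),
                                   perturb = TRUE, max_angle_deg = 5,
                                   max_shift_mm = 3) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  if (!is.finite(B) || B <= 0) stop("B must be > 0", call. = FALSE)
  geom <- spec$params$geometry %||% "parallel_plate"
  base_spec <- phantom_spec(geom, spec$params[setdiff(names(spec$params),
                                                      "geometry")],
                            noise = spec$noise, sigma = spec$sigma,
                            seed = spec$seed)
  base <- make_cartilage_phantom(base_spec)

  strains <- A * exp(-B * times)
  draws <- with_seed(spec$seed, list(
    ang = runif(length(times) * 3, -max_angle_deg, max_angle_deg),
    sft = runif(length(times) * 3, -max_shift_mm, max_shift_mm)))
  scans <- lapply(seq_along(times), function(i) {
    cart <- base$cartilage
    cart$vertices[, 3] <- cart$vertices[, 3] * (1 + strains[i] / 100)
    tf <- rigid_transform()
    if (perturb) {
      k <- (i - 1) * 3
      Rm <- rotation_about("z", draws$ang[k + 1]) %*%
        rotation_about("y", draws$ang[k + 2]) %*%
        rotation_about("x", draws$ang[k + 3])
      tf <- rigid_transform(Rm, draws$sft[k + 1:3])
    }
    list(time_min = times[i],
         bone = apply_transform(tf, base$bone),
         cartilage = apply_transform(tf, cart),
         true_strain_pct = strains[i],
         applied_transform = tf)
  })
  list(baseline = base, scans = scans,
       truth = list(A = A, B = B, characteristic_recovery_time = 1 / B,
                    times = times, strains = strains))
}

#' Generate a synthetic relaxation image stack
#'
#' Per-pixel intensities `S0 * exp(-t / T)` from a ground-truth
#' relaxation-time field, with optional Gaussian or Rician noise applied
#' after the truth is recorded (Rician being the natural model for MR
#' magnitude images).
#'
#' @param spec a [phantom_spec()] (kind `relaxation_stack`); its `noise`,
#'   `sigma` and `seed` control the noise.
#' @param T_field matrix/array of true relaxation times (ms), positive on
#'   the mask.
#' @param S0 equilibrium signal intensity (scalar or array like
#'   `T_field`).
#' @param times acquisition times (ms).
#' @param mask binary mask (default: all pixels).
#' @param modality `"T1rho"` or `"T2"`.
#' @return list(`stack` (a [relaxation_stack()]), `truth` (list with
#'   `T_field`, `S0`, `times`), `spec`).
#' @export
make_relaxation_stack <- function(spec, T_field, S0 = 100,
                                  times = c(13.8, 27.6, 41.4, 55.2,
                                            69.0, 82.8, 96.6),
                                  mask = NULL,
                                  modality = c("T2", "T1rho")) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  modality <- match.arg(modality)
  T_field <- as.array(T_field)
  if (is.null(mask)) mask <- array(TRUE, dim(T_field))
  mask <- array(as.logical(as.array(mask) != 0), dim(T_field))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (any(T_field[mask] <= 0))
    stop("T_field must be positive on the mask", call. = FALSE)
  S0a <- if (length(S0) == 1) array(S0, dim(T_field)) else as.array(S0)

  frames <- lapply(times, function(t0) S0a * exp(-t0 / T_field))
  img <- array(unlist(frames), dim = c(dim(T_field), length(times)))
  truth <- list(T_field = T_field, S0 = S0a, times = times)
  if (spec$noise != "none" && spec$sigma > 0) {
    img <- with_seed(spec$seed, {
      if (spec$noise == "gaussian") {
        img + array(rnorm(length(img), 0, spec$sigma), dim(img))
      } else { # rician: magnitude of complex signal + iid gaussian noise
        n1 <- array(rnorm(length(img), 0, spec$sigma), dim(img))
        n2 <- array(rnorm(length(img), 0, spec$sigma), dim(img))
        sqrt((img + n1)^2 + n2^2)
      }
    })
  }
  stack <- relaxation_stack(img, times, mask, modality = modality)
  list(stack = stack, truth = truth, spec = spec)
}
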