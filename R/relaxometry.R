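#' Multi-spin-lock / multi-echo relaxation stack
#'
#' K co-registered intensity images acquired at increasing spin-lock
#' times (T1rho) or echo times (T2), with one binary cartilage mask
#' shared by all frames: the mask drawn on the first-acquired frame is
#' applied unchanged to the later frames.
#'
#' @param images numeric array whose last dimension indexes the K
#'   acquisition times (e.g. `x.y.K` for single-slice, `x.y.z.K` for a
#'   volume), or a list of K equally shaped arrays.
#' @param times K acquisition times in ms, strictly increasing, > 0;
#'   K >= 3.
#' @param mask logical/0-1 array matching the spatial dimensions.
#' @param modality `"T1rho"` or `"T2"`.
#' @return An object of class `relaxation_stack`.
#' @export
relaxation_stack <- function(images, times, mask,
                             modality = c("T1rho", "T2")) {
  modality <- match.arg(modality)
  times <- as.numeric(times)
  if (is.list(images)) {
    dims <- dim(as.array(images[[1]]))
    if (is.null(dims)) dims <- length(images[[1]])
    images <- array(unlist(images), dim = c(dims, length(images)))
  }
  images <- as.array(images)
  nd <- length(dim(images))
  K <- dim(images)[nd]
  if (length(times) != K)
    stop("length(times) must equal the number of frames", call. = FALSE)
  if (K < 3)
    stop("need at least 3 acquisition times", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0) || any(diff(times) <= 0))
    stop("times must be positive and strictly increasing (ms)",
         call. = FALSE)
  spatial <- dim(images)[-nd]
  mask <- as.array(mask)
  if (!isTRUE(all.equal(dim(mask) %||% length(mask), spatial,
                        check.attributes = FALSE)))
    stop("mask shape must equal the image spatial shape", call. = FALSE)
  mask <- array(as.logical(mask != 0), dim = spatial)
  structure(list(images = images, times = times, mask = mask,
                 modality = modality), class = "relaxation_stack")
}

#' @export
print.relaxation_stack <- function(x, ...) {
  cat(sprintf("<relaxation_stack> %s, %s px, %d frames (%s ms), %d masked\n",
              x$modality,
              paste(dim(x$mask), collapse = "x"),
              length(x$times), paste(x$times, collapse = ", "),
              sum(x$mask)))
  invisible(x)
}

#' Fit a mono-exponential decay to one pixel
#'
#' Nonlinear least squares of `S(t) = S0 * exp(-t / T)` to the K signal
#' intensities of a pixel, T being the relaxation time (T1rho or T2). The
#' closed-form log-linear fit initialises the nonlinear solve (pure
#' log-linearisation is biased under additive noise, so it is only the
#' initialiser). The fit is flagged invalid when any intensity is <= 0,
#' when the solver fails, or when T exceeds `cap_factor` times the last
#' acquisition time (such pixels are excluded from summary means).
#'
#' @param intensities K signal intensities.
#' @param times K acquisition times (ms).
#' @param cap_factor validity cap on T as a multiple of `max(times)`.
#' @return list(`S0`, `T_ms`, `rmse`, `valid`).
#' @examples
#' te <- c(13.8, 27.6, 41.4, 55.2, 69.0, 82.8, 96.6)
#' fit_pixel_decay(100 * exp(-te / 40), te)$T_ms # 40
#' @export
fit_pixel_decay <- function(intensities, times, cap_factor = 10) {
  intensities <- as.numeric(intensities); times <- as.numeric(times)
  if (length(intensities) != length(times))
    stop("intensities and times must have the same length", call. = FALSE)
  if (length(times) < 3)
    stop("need at least 3 acquisition times", call. = FALSE)
  cap <- cap_factor * max(times)
  bad <- list(S0 = NA_real_, T_ms = NA_real_, rmse = NA_real_,
              valid = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0)) return(bad)

  ll <- lm(log(intensities) ~ times)
  slope <- unname(coef(ll)[2])
  T0 <- if (is.finite(slope) && slope < 0) min(-1 / slope, cap) else cap
  S00 <- exp(unname(coef(ll)[1]))
  dat <- data.frame(t = times, s = intensities)
  fit <- tryCatch(minpack.lm::nlsLM(
    s ~ S0 * exp(-t / Tc), data = dat,
    start = list(S0 = S00, Tc = T0),
    lower = c(0, 1e-6), upper = c(Inf, cap),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- coef(fit)
  T_ms <- unname(cf["Tc"])
  valid <- T_ms < cap * (1 - 1e-8) && T_ms > 1e-6 * (1 + 1e-8)
  list(S0 = unname(cf["S0"]), T_ms = T_ms,
       rmse = sqrt(mean(resid(fit)^2)), valid = valid)
}

#' Per-pixel relaxation map and masked summary
#'
#' Applies [fit_pixel_decay()] to every masked pixel of a
#' [relaxation_stack()] and summarises the subject as the arithmetic mean
#' relaxation time over all valid masked pixels from all slices.
#'
#' @param stack a [relaxation_stack()].
#' @param cap_factor forwarded to [fit_pixel_decay()].
#' @return An object of class `relaxation_map`: arrays `T_ms`, `S0`,
#'   `rmse`, `valid` (spatial shape; `NA` outside the mask) and a
#'   `summary` list with `modality`, `n_masked`, `n_valid` and `mean_ms`.
#' @export
compute_map <- function(stack, cap_factor = 10) {
  if (!inherits(stack, "relaxation_stack"))
    stop("`stack` must be a relaxation_stack", call. = FALSE)
  mask <- stack$mask
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  spatial <- dim(mask)
  npx <- prod(spatial)
  K <- length(stack$times)
  flat <- matrix(stack$images, nrow = npx, ncol = K)
  idx <- which(as.vector(mask))

  T_ms <- S0 <- rmse <- rep(NA_real_, npx)
  valid <- rep(FALSE, npx)
  for (i in idx) {
    f <- fit_pixel_decay(flat[i, ], stack$times, cap_factor = cap_factor)
    T_ms[i] <- f$T_ms; S0[i] <- f$S0; rmse[i] <- f$rmse
    valid[i] <- f$valid
  }
  ok <- valid
  structure(list(
    T_ms = array(T_ms, spatial), S0 = array(S0, spatial),
    rmse = array(rmse, spatial), valid = array(valid, spatial),
    summary = list(modality = stack$modality,
                   n_masked = length(idx), n_valid = sum(ok),
                   mean_ms = if (any(ok)) mean(T_ms[ok]) else NA_real_,
                   excluded_invalid = length(idx) - sum(ok))),
    class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<relaxation_map> %s: mean %.2f ms over %d/%d valid masked pixels\n",
              s$modality, s$mean_ms, s$n_valid, s$n_masked))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Image I/O: NIfTI volumes (one per frame or a single 4D file) and
# multi-page TIFF for phantoms.

#' Read a relaxation stack from NIfTI or TIFF files
#'
#' @param paths character vector of per-frame image files (NIfTI or
#'   TIFF), or a single 4D NIfTI / multi-page TIFF.
#' @param times acquisition times in ms, one per frame.
#' @param mask_path binary mask image (NIfTI or TIFF) matching the
#'   spatial shape.
#' @param modality `"T1rho"` or `"T2"`.
#' @return A [relaxation_stack()].
#' @export
read_relaxation_stack <- function(paths, times, mask_path,
                                  modality = c("T1rho", "T2")) {
  imgs <- lapply(paths, read_image)
  if (length(imgs) == 1L) {
    a <- imgs[[1]]
    nd <- length(dim(a))
    frames <- lapply(seq_len(dim(a)[nd]), function(k)
      slice_last(a, k))
  } else frames <- imgs
  relaxation_stack(frames, times, read_image(mask_path),
                   modality = match.arg(modality))
}

#' Write a relaxation map image
#'
#' Writes the per-pixel relaxation times as a float NIfTI or TIFF image
#' (`NA`/invalid pixels as 0) and, optionally, the JSON summary.
#'
#' @param map a [relaxation_map()][compute_map].
#' @param path output image path (`.nii`, `.nii.gz` or `.tif`).
#' @param summary_path optional JSON path for the masked summary.
#' @return `path`, invisibly.
#' @export
write_relaxation_map <- function(map, path, summary_path = NULL) {
  if (!inherits(map, "relaxation_map"))
    stop("`map` must be a relaxation_map", call. = FALSE)
  img <- map$T_ms
  img[!map$valid | is.na(img)] <- 0
  write_image(img, path)
  if (!is.null(summary_path))
    jsonlite::write_json(map$summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii", "hdr", "img")) {
    as.array(RNifti::readNifti(path))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 1L) as.array(pages[[1]])
    else array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  } else stop(sprintf("unsupported image format '.%s'", ext),
              call. = FALSE)
}

# TIFF float samples must lie in [0,1]; `scale` divides the data before
# writing. Per-pixel decay fits are scale-equivariant, so writing a whole
# stack with one shared scale leaves relaxation times untouched (S0 is
# then in scaled units). NIfTI stores values verbatim.
write_image <- function(img, path, scale = 1) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(img), path)
  } else if (ext %in% c("tif", "tiff")) {
    scaled <- img / scale
    if (min(scaled) < 0 || max(scaled) > 1)
      stop("TIFF data must lie in [0,1] after `scale`; pass a shared scale",
           call. = FALSE)
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  } else stop(sprintf("unsupported image format '.%s'", ext),
              call. = FALSE)
  invisible(path)
}

slice_last <- function(a, k) {
  nd <- length(dim(a))
  idx <- c(rep(list(quote(expr = )), nd - 1), list(k))
  do.call(`[`, c(list(a), idx, list(drop = TRUE)))
}
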