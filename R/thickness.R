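#' Node-to-node cartilage thickness
#'
#' Thickness at every cartilage vertex, defined as the Euclidean distance
#' from that vertex to the nearest vertex of the bone mesh (node-to-node;
#' an optional point-to-triangle variant is deliberately not the default,
#' the node-to-node definition being the one used with segmented surface
#' models).
#'
#' @param cartilage cartilage [surface_mesh()] (or n x 3 point matrix).
#' @param bone bone [surface_mesh()] (or n x 3 point matrix).
#' @return Numeric vector of per-vertex thickness (mm), one value per
#'   cartilage vertex.
#' @export
nodewise_thickness <- function(cartilage, bone) {
  cv <- if (is_surface_mesh(cartilage)) cartilage$vertices
        else as_points3(cartilage)
  bv <- if (is_surface_mesh(bone)) bone$vertices else as_points3(bone)
  if (nrow(cv) == 0) stop("cartilage mesh is empty", call. = FALSE)
  if (nrow(bv) == 0) stop("bone mesh is empty", call. = FALSE)
  nearest_nodes(cv, bv)$distance
}

#' Sampling grid of thickness sites
#'
#' Eighteen labelled 3D sampling points, nine per tibial plateau arranged
#' as a 3 x 3 array in the axial projection, plus the averaging radius.
#'
#' @param sites data.frame with columns `site_id`, `plateau`
#'   (`"medial"`/`"lateral"`), `x`, `y`, `z` (mm).
#' @param radius averaging radius in mm (default 2.5).
#' @return An object of class `sampling_grid`.
#' @export
sampling_grid <- function(sites, radius = 2.5) {
  need <- c("site_id", "plateau", "x", "y", "z")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop("`sites` needs columns site_id, plateau, x, y, z", call. = FALSE)
  if (!all(sites$plateau %in% c("medial", "lateral")))
    stop("plateau must be 'medial' or 'lateral'", call. = FALSE)
  counts <- table(factor(sites$plateau, c("medial", "lateral")))
  if (!all(counts == 9L))
    stop("a sampling grid has exactly 9 sites per plateau", call. = FALSE)
  if (anyDuplicated(sites$site_id))
    stop("site ids must be unique", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a single positive number (mm)", call. = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, radius = radius), class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("<sampling_grid> %d sites, radius %.2f mm\n",
              nrow(x$sites), x$radius))
  invisible(x)
}

#' Build the 3 x 3 per-plateau sampling grid from a cartilage mesh
#'
#' Splits the cartilage footprint into medial and lateral halves along a
#' mediolateral axis, takes each half's axial bounding box, and places
#' nine sites per half at the 25/50/75% fractions of the box edges. The
#' grid is deterministic for a given mesh and is built once on the
#' pre-activity model, then reused verbatim for all aligned post-activity
#' scans.
#'
#' @param cartilage pre-activity cartilage [surface_mesh()].
#' @param split_axis mediolateral axis of the axial projection, `"x"` or
#'   `"y"`; the footprint is split at the midpoint of this axis unless
#'   `split_at` is given.
#' @param split_at optional coordinate (mm) on `split_axis` separating the
#'   medial (lower) from the lateral (upper) half.
#' @param radius averaging radius (mm).
#' @return A [sampling_grid()]. Each site's `z` is taken from the
#'   cartilage vertex nearest to the site in the axial projection, so the
#'   averaging ball is centred on the surface.
#' @export
build_sampling_grid <- function(cartilage, split_axis = c("x", "y"),
                                split_at = NULL, radius = 2.5) {
  stopifnot_mesh(cartilage)
  split_axis <- match.arg(split_axis)
  v <- cartilage$vertices
  ax <- if (split_axis == "x") 1L else 2L
  other <- if (split_axis == "x") 2L else 1L
  rng_ax <- range(v[, ax]); rng_ot <- range(v[, other])
  if (diff(rng_ax) <= 0 || diff(rng_ot) <= 0)
    stop("degenerate (zero-area) cartilage footprint", call. = FALSE)
  if (is.null(split_at)) split_at <- mean(rng_ax)

  half_sites <- function(sel, plateau, prefix) {
    w <- v[sel, , drop = FALSE]
    if (nrow(w) == 0)
      stop(sprintf("no cartilage vertices on the %s side of the split",
                   plateau), call. = FALSE)
    ra <- range(w[, ax]); ro <- range(w[, other])
    fa <- ra[1] + c(0.25, 0.5, 0.75) * diff(ra)
    fo <- ro[1] + c(0.25, 0.5, 0.75) * diff(ro)
    g <- expand.grid(a = fa, o = fo)
    xy <- matrix(0, nrow(g), 2)
    xy[, ax] <- g$a; xy[, other] <- g$o
    # z from the axially nearest cartilage vertex (ties: lowest index)
    zz <- vapply(seq_len(nrow(xy)), function(i) {
      d2 <- (v[, 1] - xy[i, 1])^2 + (v[, 2] - xy[i, 2])^2
      v[which.min(d2), 3]
    }, numeric(1))
    data.frame(site_id = sprintf("%s%d%d", prefix,
                                 rep(1:3, times = 3), rep(1:3, each = 3)),
               plateau = plateau, x = xy[, 1], y = xy[, 2], z = zz,
               stringsAsFactors = FALSE)
  }
  med <- half_sites(v[, ax] <= split_at, "medial", "M")
  lat <- half_sites(v[, ax] >= split_at, "lateral", "L")
  sampling_grid(rbind(med, lat), radius = radius)
}

#' Average per-vertex thickness at each sampling site
#'
#' For each grid site, averages the thickness of all cartilage vertices
#' whose Euclidean distance to the site point is at most the grid radius.
#' Sites capturing no vertex are flagged `missing` (never imputed, never
#' reported as zero) and are excluded from per-scan means downstream.
#'
#' @param per_vertex numeric vector of per-vertex thickness (mm), aligned
#'   with `cartilage` vertices (from [nodewise_thickness()]).
#' @param cartilage cartilage [surface_mesh()].
#' @param grid a [sampling_grid()].
#' @return data.frame with one row per site: `site_id`, `plateau`,
#'   `thickness_mm`, `n_nodes`, `missing`.
#' @export
site_thickness <- function(per_vertex, cartilage, grid) {
  stopifnot_mesh(cartilage)
  if (!inherits(grid, "sampling_grid"))
    stop("`grid` must be a sampling_grid", call. = FALSE)
  v <- cartilage$vertices
  if (length(per_vertex) != nrow(v))
    stop("per_vertex must have one value per cartilage vertex",
         call. = FALSE)
  s <- grid$sites
  r2 <- grid$radius^2
  res <- lapply(seq_len(nrow(s)), function(i) {
    d2 <- (v[, 1] - s$x[i])^2 + (v[, 2] - s$y[i])^2 + (v[, 3] - s$z[i])^2
    sel <- d2 <= r2
    n <- sum(sel)
    data.frame(site_id = s$site_id[i], plateau = s$plateau[i],
               thickness_mm = if (n > 0) mean(per_vertex[sel]) else NA_real_,
               n_nodes = n, missing = n == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Measure site thickness for one scan
#'
#' Convenience wrapper chaining [nodewise_thickness()] and
#' [site_thickness()] for a registered bone/cartilage pair.
#'
#' @inheritParams nodewise_thickness
#' @inheritParams site_thickness
#' @param scan_id identifier recorded in the output.
#' @return data.frame as [site_thickness()] plus a `scan_id` column.
#' @export
scan_site_thickness <- function(cartilage, bone, grid, scan_id = "scan") {
  st <- site_thickness(nodewise_thickness(cartilage, bone), cartilage, grid)
  cbind(scan_id = scan_id, st, stringsAsFactors = FALSE)
}

#' Mean thickness of a scan over non-missing sites
#'
#' @param sites data.frame from [site_thickness()].
#' @return Mean of `thickness_mm` over sites not flagged missing.
#' @export
mean_site_thickness <- function(sites) {
  ok <- !sites$missing
  if (!any(ok)) return(NA_real_)
  mean(sites$thickness_mm[ok])
}
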