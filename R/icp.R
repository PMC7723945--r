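#' Rigid transform
#'
#' A proper rigid-body motion `p -> R p + t` in millimetres. The rotation
#' must be orthonormal with determinant +1 (tolerance 1e-9).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%s) mm\n",
              ang, paste(sprintf("%.4f", x$translation), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
    y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
    z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)))
}

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Apply a rigid transform to points or a mesh
#'
#' @param transform a [rigid_transform()].
#' @param x an n x 3 point matrix or a [surface_mesh()].
#' @return Object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(transform, x) {
  if (!inherits(transform, "rigid_transform"))
    stop("`transform` must be a rigid_transform", call. = FALSE)
  if (is_surface_mesh(x)) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  p <- as_points3(x)
  sweep(p %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then
#' `a` (function composition `a o b`).
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}

# Least-squares rigid motion taking `from` onto `to` (row-paired points):
# SVD of the cross-covariance with a determinant correction so the result
# is a proper rotation (Kabsch).
kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- crossprod(sweep(from, 2, cf), sweep(to, 2, ct))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, ct - as.numeric(R %*% cf))
}

#' Iterative closest point rigid registration
#'
#' Aligns `moving` to `fixed` with a point-to-point ICP: at each iteration
#' every moving vertex is paired with its nearest fixed vertex and the
#' rigid motion minimising the RMS of those pairs is re-estimated from the
#' original vertices (Kabsch). Iteration stops when the RMS improvement
#' falls below `tol` or after `max_iter` iterations. Used to align each
#' post-activity bone model with the pre-activity bone model so cartilage
#' is sampled at the same anatomical sites over time.
#'
#' @param moving,fixed [surface_mesh()] objects of the same rigid anatomy.
#' @param max_iter maximum number of iterations.
#' @param tol convergence tolerance on the RMS improvement (mm).
#' @param subsample optionally, number of moving vertices to use for
#'   correspondence search (uniform, deterministic given `seed`);
#'   `NULL` uses all vertices.
#' @param seed RNG seed for subsampling.
#' @param init `"pca"` (default) seeds the iteration with a coarse
#'   principal-axes alignment (centroids matched, covariance eigenvectors
#'   aligned, best of the proper-rotation sign choices by residual);
#'   `"identity"` starts from the untransformed pose. Coarse seeding
#'   widens the basin of attraction well beyond the mesh spacing.
#' @return A [rigid_transform()] with attributes `rms` (final RMS
#'   nearest-point distance, mm), `iterations`, and `converged` (FALSE if
#'   `max_iter` was exhausted before the improvement dropped below `tol`).
#' @examples
#' ph <- make_cartilage_phantom(phantom_spec("parallel_plate",
#'   list(extent = c(10, 10), gap = 3, spacing = 1)))
#' tf <- rigid_transform(diag(3), c(1, -0.5, 2))
#' moved <- apply_transform(tf, ph$bone)
#' est <- icp_register(moved, ph$bone)
#' max(abs(est$translation + c(1, -0.5, 2))) < 1e-6
#' @export
icp_register <- function(moving, fixed, max_iter = 100L, tol = 1e-6,
                         subsample = NULL, seed = 1L,
                         init = c("pca", "identity")) {
  stopifnot_mesh(moving); stopifnot_mesh(fixed)
  init <- match.arg(init)
  if (nrow(moving$vertices) == 0 || nrow(fixed$vertices) == 0)
    stop("cannot register an empty mesh", call. = FALSE)
  src <- moving$vertices
  if (!is.null(subsample) && subsample < nrow(src)) {
    idx <- with_seed(seed, sample.int(nrow(src), subsample))
    src <- src[idx, , drop = FALSE]
  }
  tgt <- fixed$vertices

  rms_of <- function(tf) sqrt(mean(nearest_nodes(apply_transform(tf, src),
                                                 tgt)$distance^2))
  tf <- rigid_transform()
  rms0 <- rms_of(tf)
  best <- list(tf = tf, rms = rms0)
  if (init == "pca") {
    for (cand in pca_align_candidates(src, tgt)) {
      r <- rms_of(cand)
      if (r < best$rms) best <- list(tf = cand, rms = r)
    }
    tf <- best$tf
  }
  rms_prev <- best$rms
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- apply_transform(tf, src)
    nn <- nearest_nodes(cur, tgt)
    tf <- kabsch(src, tgt[nn$index, , drop = FALSE])
    rms <- rms_of(tf)
    if (rms < best$rms) best <- list(tf = tf, rms = rms)
    if (rms_prev - rms < tol) { converged <- TRUE; break }
    rms_prev <- rms
  }
  # never worse than leaving the meshes untouched
  out <- if (best$rms <= rms0) best$tf else rigid_transform()
  attr(out, "rms") <- min(best$rms, rms0)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

# Coarse principal-axes alignments: match centroids and covariance
# eigenvectors; enumerate the eigenvector sign choices that give a proper
# rotation (the caller keeps the one with the lowest residual).
pca_align_candidates <- function(src, tgt) {
  cm <- colMeans(src); ct <- colMeans(tgt)
  Vm <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  Vf <- eigen(stats::cov(tgt), symmetric = TRUE)$vectors
  out <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    R <- Vf %*% diag(c(s1, s2, s3)) %*% t(Vm)
    if (det(R) < 0) next
    out[[length(out) + 1]] <-
      rigid_transform(R, ct - as.numeric(R %*% cm))
  }
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
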