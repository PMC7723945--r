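#' Triangulated surface mesh
#'
#' Container for a triangulated anatomical surface (bone or cartilage).
#' Vertices are 3D points in millimetres; faces index vertices (1-based).
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of vertex indices, one triangle per
#'   row. May have zero rows for point-cloud style meshes.
#' @param label mesh label, `"bone"` or `"cartilage"`.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, `label`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' surface_mesh(v, rbind(c(1, 2, 3)), "bone")
#' @export
surface_mesh <- function(vertices, faces = matrix(integer(), 0, 3),
                         label = c("bone", "cartilage")) {
  label <- match.arg(label)
  vertices <- as_points3(vertices)
  if (nrow(vertices) < 3)
    stop("a surface mesh needs at least 3 vertices", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("vertex coordinates must be finite", call. = FALSE)
  faces <- as.matrix(faces)
  if (length(faces) == 0L) faces <- matrix(integer(), 0, 3)
  if (ncol(faces) != 3)
    stop("faces must be an m x 3 index matrix", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices must refer to existing vertices", call. = FALSE)
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen))
      stop("degenerate faces (repeated vertex index) are not allowed",
           call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s: %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_surface_mesh <- function(x) inherits(x, "surface_mesh")

stopifnot_mesh <- function(x, arg = deparse(substitute(x))) {
  if (!is_surface_mesh(x))
    stop(sprintf("`%s` must be a surface_mesh", arg), call. = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mesh I/O: ASCII PLY, OBJ and STL. These cover the interchange formats
# segmentation tools export; binary variants are not handled.

#' Read a surface mesh from PLY, OBJ or STL (ASCII)
#'
#' Format is chosen from the file extension. STL files carry no shared
#' vertex list, so identical vertices are merged on read.
#'
#' @param path file path ending in `.ply`, `.obj` or `.stl`.
#' @param label mesh label to attach, `"bone"` or `"cartilage"`.
#' @return A [surface_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, label = c("bone", "cartilage")) {
  label <- match.arg(label)
  if (!file.exists(path))
    stop(sprintf("mesh file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = read_ply(path, label),
    obj = read_obj(path, label),
    stl = read_stl(path, label),
    stop(sprintf("unsupported mesh format '.%s'", ext), call. = FALSE)
  )
}

#' Write a surface mesh to PLY, OBJ or STL (ASCII)
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path),
    stop(sprintf("unsupported mesh format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

read_ply <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("not a PLY file", call. = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header has no end_header", call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format", header, value = TRUE)
  if (length(fmt) && !grepl("ascii", fmt[1]))
    stop("only ASCII PLY is supported", call. = FALSE)
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)[1]))
  nf_line <- grep("^element face ", header, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("^element face ", "", nf_line[1])) else 0L
  if (is.na(nv)) stop("PLY header lacks a vertex element", call. = FALSE)
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- do.call(rbind, lapply(body[seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  faces <- matrix(integer(), 0, 3)
  if (nf > 0) {
    faces <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(l) {
      f <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (f[1] != 3L) stop("only triangular PLY faces are supported",
                           call. = FALSE)
      f[2:4] + 1L
    }))
  }
  surface_mesh(vtx, faces, label)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment label %s", mesh$label),
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(v, 1, function(p) paste(format(p, digits = 17),
                                           collapse = " ")), con)
  if (nrow(f) > 0)
    writeLines(apply(f, 1, function(p) paste(c(3L, p - 1L), collapse = " ")),
               con)
}

read_obj <- function(path, label) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0) stop("OBJ file has no vertices", call. = FALSE)
  vtx <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4])))
  faces <- matrix(integer(), 0, 3)
  if (length(fl)) {
    faces <- do.call(rbind, lapply(fl, function(l) {
      toks <- strsplit(l, "\\s+")[[1]][-1]
      if (length(toks) != 3) stop("only triangular OBJ faces are supported",
                                  call. = FALSE)
      as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1L))
    }))
  }
  surface_mesh(vtx, faces, label)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label %s", mesh$label), con)
  writeLines(apply(mesh$vertices, 1, function(p)
    paste(c("v", format(p, digits = 17)), collapse = " ")), con)
  if (nrow(mesh$faces) > 0)
    writeLines(apply(mesh$faces, 1, function(p)
      paste(c("f", p), collapse = " ")), con)
}

read_stl <- function(path, label) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!length(lines) || !grepl("^solid", lines[1]))
    stop("only ASCII STL is supported", call. = FALSE)
  vl <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed STL: vertex count not a multiple of 3", call. = FALSE)
  pts <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4])))
  key <- apply(pts, 1, function(p) paste(format(p, digits = 17),
                                         collapse = ","))
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  vtx <- pts[uniq, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(vtx, faces, label)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) stop("STL requires faces", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$label), con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %s", paste(format(n, digits = 17),
                                                  collapse = " ")),
                 "outer loop",
                 apply(tri, 1, function(p)
                   paste(c("vertex", format(p, digits = 17)),
                         collapse = " ")),
                 "endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$label), con)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Regular-grid triangulation helper shared by the phantom generators:
# vertices on an nx x ny lattice (column-major over x then y), split each
# lattice cell into two triangles.
grid_faces <- function(nx, ny) {
  if (nx < 2 || ny < 2) return(matrix(integer(), 0, 3))
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  unname(rbind(cbind(v00, v10, v11), cbind(v00, v11, v01)))
}
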