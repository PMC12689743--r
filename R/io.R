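# File interfaces: triangle meshes (ASCII OBJ/PLY/STL), depth maps (16-bit
# PNG or NPY, both in mm), binary masks (PNG) and intrinsics (JSON).

#' Construct a triangle mesh
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @return a `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3 || !all(is.finite(vertices)))
    stop("vertices must be a finite N x 3 matrix")
  if (nrow(faces) < 1 || min(faces) < 1 || max(faces) > nrow(vertices))
    stop("faces must index existing vertices (1-based)")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle surface mesh (ASCII OBJ, PLY or STL)
#'
#' Vertex coordinates are taken to be millimetres. Only triangular faces are
#' supported (OBJ polygon faces are fan-triangulated).
#'
#' @param path mesh file; format chosen by extension.
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl_ascii(path),
         stop("unsupported mesh format: .", ext, " (use OBJ, PLY or STL)"))
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- list()
  for (f in strsplit(trimws(sub("^f", "", fl)), "\\s+")) {
    idx <- as.integer(vapply(strsplit(f, "/"), `[[`, "", 1))
    for (k in seq_len(length(idx) - 2))       # fan triangulation
      faces[[length(faces) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  triangle_mesh(V, do.call(rbind, faces))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file")
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
  endh <- grep("^end_header", lines)[1]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  V <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  Fl <- strsplit(trimws(body[(nv + 1):(nv + nf)]), "\\s+")
  faces <- lapply(Fl, function(x) {
    n <- as.integer(x[1])
    if (n != 3) stop("only triangular PLY faces are supported")
    as.integer(x[2:4]) + 1L                   # PLY indices are 0-based
  })
  triangle_mesh(V, do.call(rbind, faces))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1])) stop("only ASCII STL is supported")
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^\\s*vertex", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  if (nrow(V) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3")
  # merge duplicate vertices so the mesh is usable for topology checks
  key <- apply(round(V, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  triangle_mesh(V[uk, , drop = FALSE], matrix(map, ncol = 3, byrow = TRUE))
}

#' Write a triangle mesh (ASCII OBJ or PLY)
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path; format chosen by extension (.obj or .ply).
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; Fc <- mesh$faces
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", Fc[, 1], Fc[, 2], Fc[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(Fc)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", Fc[, 1] - 1L, Fc[, 2] - 1L, Fc[, 3] - 1L), con)
  } else stop("unsupported mesh output format: .", ext)
  invisible(path)
}

#' Write a point cloud as ASCII PLY
#'
#' @param points N x 3 point matrix (mm).
#' @param path output .ply path.
#' @export
write_pointcloud_ply <- function(points, path) {
  points <- as.matrix(points)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(points)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  if (nrow(points))
    writeLines(sprintf("%.9g %.9g %.9g", points[, 1], points[, 2], points[, 3]), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Depth maps. Disk formats: 16-bit grayscale PNG with pixel value = mm
# (read/write via the png package; writes are emitted as NPY because
# png::writePNG is 8-bit only) or NPY float32/float64 in mm.

#' Read a depth map (16-bit PNG or NPY, mm)
#'
#' @param path `.png` (16-bit grayscale, pixel value = depth in mm) or
#'   `.npy` (float32/float64 matrix, mm).
#' @return numeric H x W matrix of depths in mm (0 = invalid).
#' @export
read_depth <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 65535)
  } else if (ext == "npy") {
    read_npy(path)
  } else stop("unsupported depth format: .", ext)
}

#' Write a depth map as NPY (float32, mm)
#' @param depth numeric H x W matrix (mm).
#' @param path output `.npy` path.
#' @export
write_depth <- function(depth, path) write_npy(as.matrix(depth), path, dtype = "<f4")

#' Read / write a binary mask PNG (nonzero = organ)
#' @param path PNG path.
#' @return `read_mask_png`: logical H x W matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' @param mask logical H x W matrix.
#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write pinhole intrinsics JSON
#'
#' JSON object with fields `fx, fy, cx, cy, width, height`.
#'
#' @param path JSON path.
#' @return `read_intrinsics_json`: a [camera_intrinsics()].
#' @export
read_intrinsics_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(x$fx, x$fy, x$cx, x$cy, x$width, x$height)
}

#' @param intrinsics a [camera_intrinsics()].
#' @rdname read_intrinsics_json
#' @export
write_intrinsics_json <- function(intrinsics, path) {
  jsonlite::write_json(unclass(intrinsics), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal NPY v1.0 support (C-order or Fortran-order float32/float64 2-D
# arrays), enough for depth maps.

write_npy <- function(mat, path, dtype = c("<f4", "<f8")) {
  dtype <- match.arg(dtype)
  header <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': (%d, %d), }",
                    dtype, nrow(mat), ncol(mat))
  # total header block (magic 6 + version 2 + len 2 + header) padded to 64
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  if (pad == 64) pad <- 0
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(mat), con, size = if (dtype == "<f4") 4 else 8,
           endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file")
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape), ",")[[1]])
  n <- prod(dims)
  size <- switch(descr, "<f4" = 4L, "<f8" = 8L,
                 stop("unsupported NPY dtype: ", descr))
  x <- readBin(con, "numeric", n, size = size, endian = "little")
  if (length(dims) == 1) return(x)
  if (length(dims) != 2) stop("only 1-D and 2-D NPY arrays are supported")
  if (fortran) matrix(x, dims[1], dims[2])
  else t(matrix(x, dims[2], dims[1]))
}
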