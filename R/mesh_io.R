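# ---- mesh file I/O: OFF, PLY (ascii), VTK legacy polydata -----------------
# All formats store 0-based vertex indices; conversion to the package's
# 1-based convention happens here at the boundary. Only triangular faces
# are accepted. Vertex labels are not part of these formats and are lost
# on write.

fmt_num <- function(x) sprintf("%.10g", x)

parse_error <- function(path, line, msg) {
  stop(sprintf("%s: parse error at line %d: %s", path, line, msg), call. = FALSE)
}

split_tokens <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]

#' Write a mesh to OFF, PLY (ascii) or VTK legacy polydata
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file.
#' @param format `"off"`, `"ply"` or `"vtk"`; default inferred from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- resolve_mesh_format(path, format)
  v <- mesh$vertices
  f0 <- mesh$triangles - 1L
  vl <- paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]))
  fl <- paste(3L, f0[, 1], f0[, 2], f0[, 3])
  lines <- switch(format,
    off = c("OFF", paste(nrow(v), nrow(f0), 0L), vl, fl),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(v)),
            "property double x", "property double y", "property double z",
            paste("element face", nrow(f0)),
            "property list uchar int vertex_indices",
            "end_header", vl, fl),
    vtk = c("# vtk DataFile Version 3.0", "ectoloc surface", "ASCII",
            "DATASET POLYDATA",
            paste("POINTS", nrow(v), "double"), vl,
            paste("POLYGONS", nrow(f0), 4L * nrow(f0)), fl))
  writeLines(lines, path)
  invisible(path)
}

#' Read a triangulated mesh from OFF, PLY (ascii) or VTK legacy polydata
#'
#' Malformed files raise an error naming the offending line; faces with
#' other than three vertices are rejected.
#'
#' @param path input file.
#' @param format `"off"`, `"ply"` or `"vtk"`; default inferred from the
#'   file extension.
#' @return a [triangle_mesh()] (all vertices unlabeled).
#' @export
read_mesh <- function(path, format = NULL) {
  format <- resolve_mesh_format(path, format)
  lines <- readLines(path, warn = FALSE)
  switch(format,
         off = read_off(lines, path),
         ply = read_ply(lines, path),
         vtk = read_vtk(lines, path))
}

resolve_mesh_format <- function(path, format) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (!format %in% c("off", "ply", "vtk"))
    stop("unsupported mesh format '", format, "' (use off, ply or vtk)")
  format
}

# iterator over non-empty, non-comment lines keeping 1-based line numbers
content_lines <- function(lines, comment = "#") {
  keep <- which(!grepl(paste0("^[[:space:]]*(", comment, "|$)"), lines))
  list(idx = keep, text = lines[keep])
}

read_faces <- function(toks_list, line_nos, path) {
  faces <- matrix(0L, length(toks_list), 3)
  for (k in seq_along(toks_list)) {
    t <- suppressWarnings(as.integer(toks_list[[k]]))
    if (length(t) < 1L || anyNA(t))
      parse_error(path, line_nos[k], "malformed face record")
    if (t[1] != 3L)
      parse_error(path, line_nos[k],
                  sprintf("non-triangular face with %d vertices", t[1]))
    if (length(t) != 4L)
      parse_error(path, line_nos[k], "face record length mismatch")
    faces[k, ] <- t[2:4] + 1L
  }
  faces
}

read_vertex_block <- function(cl, start, nv, path) {
  if (start + nv - 1L > length(cl$text))
    parse_error(path, length(cl$idx) + 1L, "unexpected end of file in vertex block")
  v <- matrix(0, nv, 3)
  for (k in seq_len(nv)) {
    t <- suppressWarnings(as.numeric(split_tokens(cl$text[start + k - 1L])))
    if (length(t) < 3L || anyNA(t[1:3]))
      parse_error(path, cl$idx[start + k - 1L], "malformed vertex coordinates")
    v[k, ] <- t[1:3]
  }
  v
}

read_off <- function(lines, path) {
  cl <- content_lines(lines)
  if (length(cl$text) == 0L) parse_error(path, 1L, "empty file")
  pos <- 1L
  if (toupper(trimws(cl$text[1])) == "OFF") pos <- 2L
  if (pos > length(cl$text)) parse_error(path, cl$idx[1], "missing count line")
  counts <- suppressWarnings(as.integer(split_tokens(cl$text[pos])))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    parse_error(path, cl$idx[pos], "malformed vertex/face counts")
  nv <- counts[1]; nf <- counts[2]
  v <- read_vertex_block(cl, pos + 1L, nv, path)
  fstart <- pos + nv + 1L
  if (fstart + nf - 1L > length(cl$text))
    parse_error(path, length(lines) + 1L, "unexpected end of file in face block")
  faces <- read_faces(lapply(cl$text[fstart:(fstart + nf - 1L)], split_tokens),
                      cl$idx[fstart:(fstart + nf - 1L)], path)
  triangle_mesh(v, faces)
}

read_ply <- function(lines, path) {
  if (length(lines) == 0L) parse_error(path, 1L, "empty file")
  if (tolower(trimws(lines[1])) != "ply") parse_error(path, 1L, "missing 'ply' magic")
  nv <- nf <- NA_integer_
  hdr_end <- NA_integer_
  for (k in seq_along(lines)) {
    t <- split_tokens(lines[k])
    if (length(t) >= 2 && t[1] == "format" && t[2] != "ascii")
      parse_error(path, k, "only ascii PLY is supported")
    if (length(t) >= 3 && t[1] == "element" && t[2] == "vertex")
      nv <- as.integer(t[3])
    if (length(t) >= 3 && t[1] == "element" && t[2] == "face")
      nf <- as.integer(t[3])
    if (length(t) >= 1 && t[1] == "end_header") { hdr_end <- k; break }
  }
  if (is.na(hdr_end)) parse_error(path, length(lines), "missing end_header")
  if (is.na(nv) || is.na(nf)) parse_error(path, hdr_end, "missing element counts")
  body <- content_lines(lines)
  body_start <- which(body$idx > hdr_end)[1]
  if (is.na(body_start) && nv > 0)
    parse_error(path, hdr_end + 1L, "missing vertex data")
  v <- read_vertex_block(body, body_start, nv, path)
  fstart <- body_start + nv
  if (fstart + nf - 1L > length(body$text))
    parse_error(path, length(lines) + 1L, "unexpected end of file in face block")
  faces <- read_faces(lapply(body$text[fstart:(fstart + nf - 1L)], split_tokens),
                      body$idx[fstart:(fstart + nf - 1L)], path)
  triangle_mesh(v, faces)
}

read_vtk <- function(lines, path) {
  if (length(lines) == 0L) parse_error(path, 1L, "empty file")
  pts_line <- grep("^[[:space:]]*POINTS[[:space:]]", lines)
  if (length(pts_line) != 1L) parse_error(path, 1L, "missing POINTS section")
  nv <- suppressWarnings(as.integer(split_tokens(lines[pts_line])[2]))
  if (is.na(nv)) parse_error(path, pts_line, "malformed POINTS count")
  poly_line <- grep("^[[:space:]]*POLYGONS[[:space:]]", lines)
  if (length(poly_line) != 1L) parse_error(path, length(lines), "missing POLYGONS section")
  nf <- suppressWarnings(as.integer(split_tokens(lines[poly_line])[2]))
  if (is.na(nf)) parse_error(path, poly_line, "malformed POLYGONS count")
  coords <- suppressWarnings(as.numeric(unlist(
    lapply(lines[(pts_line + 1L):(poly_line - 1L)], split_tokens))))
  coords <- coords[!is.na(coords)]
  if (length(coords) < 3L * nv)
    parse_error(path, poly_line - 1L, "too few point coordinates")
  v <- matrix(coords[seq_len(3L * nv)], ncol = 3, byrow = TRUE)
  fl <- (poly_line + 1L):length(lines)
  fl <- fl[!grepl("^[[:space:]]*$", lines[fl])]
  if (length(fl) < nf)
    parse_error(path, length(lines) + 1L, "unexpected end of file in face block")
  faces <- read_faces(lapply(lines[fl[seq_len(nf)]], split_tokens),
                      fl[seq_len(nf)], path)
  triangle_mesh(v, faces)
}

#' Read / write electrode positions as 3-column delimited text
#'
#' @param path file path; columns are x, y, z in mm.
#' @return for `read_electrodes`, a P x 3 numeric matrix.
#' @export
read_electrodes <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) != 3L) stop(path, ": expected 3 columns (x y z in mm)")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' @rdname read_electrodes
#' @param electrodes P x 3 numeric matrix of positions (mm).
#' @export
write_electrodes <- function(electrodes, path) {
  write.table(format(electrodes, digits = 10), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
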