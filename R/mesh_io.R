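# STL (ASCII + binary) and PLY (ASCII) mesh I/O.
#
# STL files carry no units; meshes are assumed millimetres and `units_scale`
# rescales on read when a file is known to be in other units.

# weld duplicated vertices produced by formats that store one vertex per
# corner (STL)
.weld_vertices <- function(v, f, digits = 9) {
  key <- paste(round(v[, 1], digits), round(v[, 2], digits),
               round(v[, 3], digits))
  first <- !duplicated(key)
  map <- match(key, key[first])
  triangle_mesh(v[first, , drop = FALSE],
                matrix(map[f], ncol = 3L))
}

.report_watertight <- function(mesh, path, quiet) {
  if (!quiet) {
    wt <- is_watertight(mesh)
    message(sprintf("%s: %d vertices, %d faces, %s",
                    basename(path), nrow(mesh$vertices), nrow(mesh$faces),
                    if (wt$watertight) "watertight" else
                      sprintf("NOT watertight (%d open edges)",
                              wt$open_edges)))
  }
  mesh
}

#' Read a mesh from STL (ASCII or binary)
#'
#' The format variant is auto-detected. Per-corner vertices are welded into a
#' shared-vertex mesh, and a watertightness report is emitted.
#'
#' @param path STL file path.
#' @param units_scale Multiplied into all coordinates on read (default 1,
#'   i.e. the file is already in mm).
#' @param quiet Suppress the watertightness report message.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, units_scale = 1, quiet = FALSE) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  ntri_bin <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.size(path)
  close(con)
  is_binary <- length(ntri_bin) == 1L && !is.na(ntri_bin) &&
    sz == 84 + 50 * as.double(ntri_bin)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    rec <- readBin(con, "raw", 50L * ntri_bin)
    m <- matrix(rec, nrow = 50L)
    tri <- matrix(readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                          n = 12L * ntri_bin, endian = "little"),
                  nrow = 12L)
    v <- matrix(as.vector(tri[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    parts <- strsplit(trimws(vl), "\\s+")
    v <- do.call(rbind, lapply(parts, function(p) as.numeric(p[2:4])))
    if (is.null(v) || nrow(v) %% 3L != 0L) {
      stop("malformed ASCII STL: vertex count not a multiple of 3",
           call. = FALSE)
    }
  }
  v <- v * units_scale
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  .report_watertight(.weld_vertices(v, f), path, quiet)
}

#' Write a mesh to STL
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param binary Write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "tmj_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  nrm <- cbind((p2[,2]-p1[,2])*(p3[,3]-p1[,3]) - (p2[,3]-p1[,3])*(p3[,2]-p1[,2]),
               (p2[,3]-p1[,3])*(p3[,1]-p1[,1]) - (p2[,1]-p1[,1])*(p3[,3]-p1[,3]),
               (p2[,1]-p1[,1])*(p3[,2]-p1[,2]) - (p2[,2]-p1[,2])*(p3[,1]-p1[,1]))
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    dat <- t(cbind(nrm, p1, p2, p3))   # 12 floats per triangle
    for (i in seq_len(nrow(f))) {
      writeBin(dat[, i], con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    lines <- c("solid tmjvol")
    tri_lines <- vapply(seq_len(nrow(f)), function(i) {
      paste0("facet normal ", paste(sprintf("%.9g", nrm[i, ]), collapse = " "),
             "\n outer loop",
             "\n  vertex ", paste(sprintf("%.9g", p1[i, ]), collapse = " "),
             "\n  vertex ", paste(sprintf("%.9g", p2[i, ]), collapse = " "),
             "\n  vertex ", paste(sprintf("%.9g", p3[i, ]), collapse = " "),
             "\n endloop\nendfacet")
    }, character(1))
    writeLines(c(lines, tri_lines, "endsolid tmjvol"), path)
  }
  invisible(path)
}

#' Read a mesh from ASCII PLY
#'
#' Minimal PLY reader: ASCII format, `vertex` element with leading x/y/z
#' properties and a `face` element with vertex index lists (triangles).
#'
#' @inheritParams read_stl
#' @return A [triangle_mesh()].
#' @export
read_ply <- function(path, units_scale = 1, quiet = FALSE) {
  txt <- readLines(path, warn = FALSE)
  if (!startsWith(txt[1], "ply")) stop("not a PLY file", call. = FALSE)
  hend <- match("end_header", trimws(txt))
  if (is.na(hend)) stop("PLY header missing end_header", call. = FALSE)
  head <- trimws(txt[1:hend])
  if (!any(grepl("^format ascii", head))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", head, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", head, value = TRUE)[1]))
  body <- txt[(hend + 1L):length(txt)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(fparts, function(p) {
    k <- as.integer(p[1])
    if (k != 3L) stop("only triangle faces are supported", call. = FALSE)
    as.integer(p[2:4]) + 1L
  }))
  .report_watertight(triangle_mesh(v * units_scale, f), path, quiet)
}

#' Write a mesh to ASCII PLY
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "tmj_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  head <- c("ply", "format ascii 1.0", "comment tmjvol",
            sprintf("element vertex %d", nrow(v)),
            "property float x", "property float y", "property float z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(head, vl, fl), path)
  invisible(path)
}
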