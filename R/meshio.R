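# Mesh file I/O: PLY (ascii and binary little-endian) and OFF.

#' Write a mesh as PLY
#'
#' @param mesh A `surface_mesh`.
#' @param file Output path.
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#' @export
write_ply <- function(mesh, file, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    "comment pocketsphere surface",
    paste("element vertex", nv),
    "property float x", "property float y", "property float z",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (format == "ascii") {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(format(mesh$vertices, scientific = FALSE), con,
      col.names = FALSE, row.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, mesh$faces - 1L), con,
      col.names = FALSE, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(file, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
      eos = NULL)
    writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
    fb <- t(cbind(mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fb[, i]), con, size = 4, endian = "little")
    }
  }
  invisible(file)
}

#' Read a PLY mesh written by [write_ply()]
#'
#' Supports ascii and binary little-endian files with xyz float vertices
#' and triangular faces.
#'
#' @param file Path to the PLY file.
#' @return A `surface_mesh`.
#' @export
read_ply <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readBin(con, "raw", n = 1)
    buf <- raw(0)
    while (length(line) && line != as.raw(10L)) {
      buf <- c(buf, line)
      line <- readBin(con, "raw", n = 1)
    }
    header <- c(header, rawToChar(buf))
    if (header[length(header)] == "end_header") break
    if (length(header) > 100) stop("malformed PLY header")
  }
  fmt <- strsplit(grep("^format", header, value = TRUE), "\\s+")[[1]][2]
  nv <- as.integer(strsplit(grep("^element vertex", header, value = TRUE),
    "\\s+")[[1]][3])
  nf <- as.integer(strsplit(grep("^element face", header, value = TRUE),
    "\\s+")[[1]][3])
  if (fmt == "ascii") {
    txt <- readLines(con)
    vl <- txt[seq_len(nv)]
    verts <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
      ncol = 3, byrow = TRUE)
    fl <- txt[nv + seq_len(nf)]
    fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
      ncol = 4, byrow = TRUE)
    faces <- fm[, 2:4, drop = FALSE] + 1L
  } else {
    verts <- matrix(readBin(con, "numeric", n = 3 * nv, size = 4,
      endian = "little"), ncol = 3, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      k <- as.integer(readBin(con, "raw", n = 1))
      idx <- readBin(con, "integer", n = k, size = 4, endian = "little")
      faces[i, ] <- idx[1:3] + 1L
    }
  }
  surface_mesh(verts, faces)
}

#' Write a mesh as OFF
#' @param mesh A `surface_mesh`.
#' @param file Output path.
#' @export
write_off <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0), con)
  utils::write.table(format(mesh$vertices, scientific = FALSE), con,
    col.names = FALSE, row.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
    col.names = FALSE, row.names = FALSE, quote = FALSE)
  invisible(file)
}
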