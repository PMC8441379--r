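#' Read a point cloud from disk
#'
#' Supported formats: ASCII XYZ(L) (whitespace-separated columns
#' `x y z [label [plant]]`, `#` comments), binary little-endian PLY with
#' optional integer `label`/`plant` vertex properties, and LAS 1.x
#' (read-only; XYZ with scale/offset applied, point record formats 0-3).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"xyz"`, `"ply"`, `"las"`. `"auto"` picks
#'   by file extension.
#' @return A [point_cloud].
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "xyz", "ply", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", las = "las", laz = "las", "xyz")
  }
  switch(format,
         xyz = read_xyz(path),
         ply = read_ply(path),
         las = read_las(path))
}

#' Write a point cloud to disk
#'
#' ASCII XYZ is written at 1e-6 m precision; PLY is binary little-endian and
#' lossless (doubles). Labels and plant ids are written when present.
#'
#' @param cloud a [point_cloud].
#' @param path output file path.
#' @param format `"xyz"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("xyz", "ply")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "xyz") write_xyz(cloud, path) else write_ply(cloud, path)
  invisible(path)
}

write_xyz <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("x", "y", "z",
            if (!is.null(cloud$label)) "label",
            if (!is.null(cloud$plant)) "plant")
  writeLines(paste("#", paste(cols, collapse = " ")), con)
  if (n_points(cloud) == 0) return(invisible(path))
  txt <- sprintf("%.6f %.6f %.6f",
                 cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  if (!is.null(cloud$label)) txt <- paste(txt, cloud$label)
  if (!is.null(cloud$plant)) txt <- paste(txt, cloud$plant)
  writeLines(txt, con)
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  if (length(body) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  parts <- strsplit(trimws(body), "\\s+")
  ncol <- length(parts[[1]])
  if (ncol < 3) stop("malformed XYZ record at data row 1: fewer than 3 fields")
  bad_len <- which(vapply(parts, length, 0L) != ncol)
  if (length(bad_len))
    stop("malformed XYZ record at data row ", bad_len[1],
         ": inconsistent field count")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = ncol, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("non-numeric value in XYZ file at data row ", bad)
  }
  point_cloud(m[, 1:3, drop = FALSE],
              label = if (ncol >= 4) as.integer(m[, 4]),
              plant = if (ncol >= 5) as.integer(m[, 5]))
}

write_ply <- function(cloud, path) {
  n <- n_points(cloud)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (!is.null(cloud$label)) "property int label",
           if (!is.null(cloud$plant)) "property int plant",
           "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (n == 0) return(invisible(path))
  rec <- matrix(writeBin(as.vector(t(cloud$coords)), raw(), size = 8,
                         endian = "little"), nrow = 24)
  if (!is.null(cloud$label))
    rec <- rbind(rec, matrix(writeBin(cloud$label, raw(), size = 4,
                                      endian = "little"), nrow = 4))
  if (!is.null(cloud$plant))
    rec <- rbind(rec, matrix(writeBin(cloud$plant, raw(), size = 4,
                                      endian = "little"), nrow = 4))
  writeBin(as.vector(rec), con)
  invisible(path)
}

ply_type_size <- function(type) {
  switch(type,
         char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L,
         float32 = 4L, double = 8L, float64 = 8L,
         stop("unsupported PLY property type: ", type))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII lines terminated by \n
  read_hline <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("truncated PLY header")
      if (b == as.raw(10)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  if (read_hline() != "ply") stop("not a PLY file: ", path)
  fmt <- read_hline()
  if (!grepl("binary_little_endian", fmt))
    stop("only binary little-endian PLY is supported")
  nvert <- NA_integer_
  props <- list()
  in_vertex <- FALSE
  repeat {
    ln <- read_hline()
    if (ln == "end_header") break
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop("PLY list properties are not supported")
      props[[tok[3]]] <- tok[2]
    }
  }
  if (is.na(nvert)) stop("PLY file has no vertex element")
  sizes <- vapply(unlist(props), ply_type_size, 0L)
  rec_size <- sum(sizes)
  payload <- readBin(con, "raw", n = rec_size * nvert)
  if (length(payload) < rec_size * nvert) stop("truncated PLY payload")
  cols <- list()
  off <- 0L
  if (nvert > 0) {
    recs <- matrix(payload, nrow = rec_size)
    for (j in seq_along(props)) {
      nm <- names(props)[j]
      sz <- sizes[j]
      bytes <- as.vector(recs[(off + 1):(off + sz), , drop = FALSE])
      type <- props[[j]]
      what <- if (type %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
      cols[[nm]] <- readBin(bytes, what, n = nvert, size = sz,
                            signed = if (sz < 4) signed else TRUE,
                            endian = "little")
      off <- off + sz
    }
  }
  need <- c("x", "y", "z")
  if (nvert > 0 && !all(need %in% names(cols)))
    stop("PLY vertex element lacks x/y/z properties")
  coords <- if (nvert > 0) cbind(cols$x, cols$y, cols$z)
            else matrix(numeric(0), ncol = 3)
  point_cloud(coords, label = cols$label, plant = cols$plant)
}

# Minimal LAS reader: header fields needed for XYZ plus scale/offset.
read_las <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 227)
  if (length(hdr) < 227 || rawToChar(hdr[1:4]) != "LASF")
    stop("not a LAS file: ", path)
  u32 <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  u16 <- function(off) readBin(hdr[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = "little")
  dbl <- function(off) readBin(hdr[(off + 1):(off + 8)], "double", size = 8,
                               endian = "little")
  offset_to_points <- u32(96)
  rec_len <- u16(105)
  npts <- u32(107)
  scale <- c(dbl(131), dbl(139), dbl(147))
  offs <- c(dbl(155), dbl(163), dbl(171))
  if (npts < 0 || offset_to_points + as.double(rec_len) * npts > sz)
    stop("corrupt LAS header (point count exceeds file size)")
  seek(con, offset_to_points)
  payload <- readBin(con, "raw", n = rec_len * npts)
  if (npts == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  recs <- matrix(payload, nrow = rec_len)
  int_at <- function(off)
    readBin(as.vector(recs[(off + 1):(off + 4), , drop = FALSE]), "integer",
            n = npts, size = 4, endian = "little")
  coords <- cbind(int_at(0) * scale[1] + offs[1],
                  int_at(4) * scale[2] + offs[2],
                  int_at(8) * scale[3] + offs[3])
  point_cloud(coords)
}
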