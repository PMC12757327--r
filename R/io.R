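#' Read and write point clouds
#'
#' Two on-disk dialects are supported:
#'
#' * **XYZ** text: one point per line, three whitespace-separated floats;
#'   blank lines and `#` comments are ignored. Written at 9 significant
#'   digits, so write-then-read reproduces coordinates that carry at most 9
#'   significant digits bit-exactly.
#' * **PLY**: the `vertex` element with float/double properties `x`, `y`, `z`
#'   (other vertex properties are skipped). Both `ascii` and
#'   `binary_little_endian` files are read; ascii is written.
#'
#' @param path File to read or write.
#' @param format `"auto"` (by extension), `"xyz"` or `"ply"`.
#' @param label,source Optional metadata attached to the returned cloud;
#'   `source` defaults to `path`.
#' @return `read_point_cloud()` returns a [point_cloud] with points in file
#'   order (no reordering, no deduplication). `write_point_cloud()` invisibly
#'   returns `path`.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' write_point_cloud(point_cloud(diag(3)), f)
#' read_point_cloud(f)
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply"), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  }
  m <- if (format == "ply") read_ply_vertices(path) else read_xyz_matrix(path)
  point_cloud(m, label = label, source = path)
}

#' @rdname read_point_cloud
#' @param cloud The point cloud to write.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "xyz", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  }
  m <- as_xyz_matrix(cloud)
  if (format == "xyz") {
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "ply",
      "format ascii 1.0",
      "comment written by mrcnet",
      sprintf("element vertex %d", nrow(m)),
      "property float x",
      "property float y",
      "property float z",
      "end_header",
      sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    ), con)
  }
  invisible(path)
}

read_xyz_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) abort(paste0("empty XYZ file: ", path))
  parse_line <- function(i) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 3L || anyNA(vals)) {
      abort(sprintf("malformed XYZ line %d in %s: '%s'", i, path, lines[[i]]))
    }
    vals
  }
  do.call(rbind, lapply(keep, parse_line))
}

ply_type_size <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
  double = 8L, float64 = 8L
)

read_ply_vertices <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii line-by-line
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) abort(paste0("PLY header has no end_header: ", path))
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 1000L) abort(paste0("PLY header too long: ", path))
  }
  if (!identical(trimws(header[[1]]), "ply")) {
    abort(paste0("not a PLY file (line 1 must be 'ply'): ", path))
  }
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) abort(paste0("PLY header line missing 'format': ", path))
  fmt <- strsplit(trimws(fmt_line[[1]]), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    abort(paste0("unsupported PLY format '", fmt, "' in ", path))
  }

  # locate the vertex element and its property list
  el_idx <- grep("^element ", header)
  if (!length(el_idx)) abort(paste0("PLY header has no elements: ", path))
  elements <- lapply(seq_along(el_idx), function(k) {
    i <- el_idx[k]
    toks <- strsplit(trimws(header[[i]]), "\\s+")[[1]]
    stop_i <- if (k < length(el_idx)) el_idx[k + 1] - 1L else length(header) - 1L
    props <- header[seq.int(i + 1L, stop_i)][grepl("^property ", header[seq.int(i + 1L, stop_i)])]
    list(name = toks[2], count = as.integer(toks[3]), props = props)
  })
  vi <- which(vapply(elements, function(e) e$name == "vertex", logical(1)))
  if (!length(vi)) abort(paste0("PLY file has no vertex element: ", path))
  if (vi[1] != 1L) abort(paste0("vertex must be the first PLY element for this reader: ", path))
  vertex <- elements[[vi[1]]]
  if (vertex$count < 1L) abort(paste0("PLY vertex element is empty: ", path))
  ptoks <- lapply(vertex$props, function(p) strsplit(trimws(p), "\\s+")[[1]])
  if (any(vapply(ptoks, function(t) t[2] == "list", logical(1)))) {
    abort(paste0("list properties on the vertex element are unsupported: ", path))
  }
  ptypes <- vapply(ptoks, function(t) t[2], character(1))
  pnames <- vapply(ptoks, function(t) t[3], character(1))
  cols <- match(c("x", "y", "z"), pnames)
  if (anyNA(cols)) abort(paste0("PLY vertex element lacks x/y/z properties: ", path))

  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = vertex$count * length(pnames), quiet = TRUE)
    if (length(vals) != vertex$count * length(pnames)) {
      abort(paste0("truncated PLY vertex data in ", path))
    }
    m <- matrix(vals, ncol = length(pnames), byrow = TRUE)
    return(m[, cols, drop = FALSE])
  }

  sizes <- ply_type_size[ptypes]
  if (anyNA(sizes)) abort(paste0("unknown PLY property type in ", path))
  rec <- sum(sizes)
  raw <- readBin(con, "raw", n = rec * vertex$count)
  if (length(raw) < rec * vertex$count) abort(paste0("truncated PLY binary data in ", path))
  offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
  read_col <- function(j) {
    at <- outer(offs[j] + seq_len(sizes[j]), rec * (seq_len(vertex$count) - 1L), "+")
    bytes <- raw[as.vector(at)]
    typ <- ptypes[j]
    if (typ %in% c("float", "float32")) {
      readBin(bytes, "double", n = vertex$count, size = 4L, endian = "little")
    } else if (typ %in% c("double", "float64")) {
      readBin(bytes, "double", n = vertex$count, size = 8L, endian = "little")
    } else {
      abort(paste0("x/y/z PLY properties must be float or double in ", path))
    }
  }
  cbind(read_col(cols[1]), read_col(cols[2]), read_col(cols[3]))
}
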