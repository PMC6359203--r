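# PLY reader/writer, scoped to point clouds: a vertex element with scalar
# properties (positions, 8-bit colors, float attributes, integer leaf
# labels). ascii and binary_little_endian; list properties of non-vertex
# elements (e.g. faces) are skipped.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_col <- function(raw_data, type, n, rec_size, offset) {
  size <- .ply_type_size[[type]]
  idx <- rep((seq_len(n) - 1L) * rec_size + offset, each = size) +
    seq_len(size)
  bytes <- raw_data[idx]
  switch(type,
    char = , int8 = readBin(bytes, "integer", n, 1, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = as.integer(bytes),
    short = , int16 = readBin(bytes, "integer", n, 2, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", n, 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", n, 4, endian = "little"),
    float = , float32 = readBin(bytes, "numeric", n, 4, endian = "little"),
    double = , float64 = readBin(bytes, "numeric", n, 8, endian = "little"),
    stop_phyto("unsupported PLY property type '%s'", type,
               class = "ply_parse_error"))
}

.ply_parse_header <- function(lines) {
  if (length(lines) < 2 || trimws(lines[1]) != "ply") {
    stop_phyto("not a PLY file: missing 'ply' magic line",
               class = "ply_parse_error")
  }
  fmt <- NULL
  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(),
                  list_types = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) {
        stop_phyto("malformed PLY header: property before any element",
                   class = "ply_parse_error")
      }
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, "list")
        cur$list_types[[tok[5]]] <- c(count = tok[3], item = tok[4])
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
      }
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop_phyto("malformed PLY header line: '%s'", ln,
                 class = "ply_parse_error")
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop_phyto("unsupported or missing PLY format '%s'",
               if (is.null(fmt)) "<none>" else fmt,
               class = "ply_parse_error")
  }
  list(format = fmt, elements = elements)
}

#' Read a colored point cloud from a PLY file
#'
#' Reads the `vertex` element of an ascii or binary little-endian PLY file.
#' `x`, `y`, `z` and `red`, `green`, `blue` properties are required (the
#' chlorophyll pipeline needs RGB); any additional scalar vertex property is
#' carried along as a per-point attribute, and an integer property named
#' `leaf` becomes the leaf labels. Non-vertex elements (faces etc.) are
#' ignored.
#'
#' @param path path to a `.ply` file.
#' @param frame frame tag to assign; point clouds coming straight out of a
#'   photogrammetric reconstruction are `"raw"` (the default) until
#'   [apply_calibration()] establishes cm units and the z-up frame.
#' @return a [point_cloud()].
#' @seealso [write_ply()]
#' @export
read_ply <- function(path, frame = c("raw", "calibrated")) {
  frame <- match.arg(frame)
  if (!file.exists(path)) {
    stop_phyto("PLY file not found: %s", path, class = "ply_parse_error")
  }
  raw_all <- readBin(path, "raw", file.info(path)$size)
  # header ends at the first "end_header" line; search raw bytes (the body
  # may be binary)
  m <- grepRaw("end_header", raw_all, fixed = TRUE)
  if (length(m) == 0 || m == -1L) {
    stop_phyto("malformed PLY: no end_header", class = "ply_parse_error")
  }
  m <- m[1]
  nl <- m + 9L
  while (nl <= length(raw_all) && raw_all[nl] != as.raw(10L)) nl <- nl + 1L
  body_start <- nl + 1L
  header_lines <- strsplit(rawToChar(raw_all[seq_len(m - 1L)]),
                           "\r?\n")[[1]]
  hdr <- .ply_parse_header(header_lines)
  if (!"vertex" %in% names(hdr$elements)) {
    stop_phyto("malformed PLY: no vertex element", class = "ply_parse_error")
  }
  cols <- list()
  if (hdr$format == "ascii") {
    body <- if (body_start > length(raw_all)) character() else
      strsplit(rawToChar(raw_all[body_start:length(raw_all)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    pos <- 1L
    for (el in hdr$elements) {
      if (el$count > length(body) - pos + 1L) {
        stop_phyto("malformed PLY: element '%s' declares %d rows but fewer remain",
                   el$name, el$count, class = "ply_parse_error")
      }
      if (el$name != "vertex") { pos <- pos + el$count; next }
      if (any(el$types == "list")) {
        stop_phyto("malformed PLY: list property in vertex element",
                   class = "ply_parse_error")
      }
      rows <- body[seq(pos, length.out = el$count)]
      vals <- scan(text = rows, quiet = TRUE)
      if (length(vals) != el$count * length(el$props)) {
        stop_phyto("malformed PLY: vertex rows do not match the declared %d properties",
                   length(el$props), class = "ply_parse_error")
      }
      m <- matrix(vals, ncol = length(el$props), byrow = TRUE)
      for (j in seq_along(el$props)) cols[[el$props[j]]] <- m[, j]
      pos <- pos + el$count
      vertex <- el
    }
  } else {
    off <- body_start - 1L
    for (el in hdr$elements) {
      if (any(el$types == "list")) {
        if (el$name == "vertex") {
          stop_phyto("malformed PLY: list property in vertex element",
                     class = "ply_parse_error")
        }
        # variable-length records: walk them one by one
        for (i in seq_len(el$count)) {
          for (j in seq_along(el$props)) {
            if (el$types[j] == "list") {
              lt <- el$list_types[[el$props[j]]]
              csz <- .ply_type_size[[lt[["count"]]]]
              cnt <- .ply_read_col(raw_all[(off + 1):(off + csz)],
                                   lt[["count"]], 1L, csz, 0L)
              off <- off + csz + cnt * .ply_type_size[[lt[["item"]]]]
            } else {
              off <- off + .ply_type_size[[el$types[j]]]
            }
          }
        }
        next
      }
      sizes <- .ply_type_size[el$types]
      rec <- sum(sizes)
      need <- el$count * rec
      if (off + need > length(raw_all)) {
        stop_phyto("malformed PLY: element '%s' truncated", el$name,
                   class = "ply_parse_error")
      }
      if (el$name == "vertex") {
        chunk <- raw_all[(off + 1):(off + need)]
        offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
        for (j in seq_along(el$props)) {
          cols[[el$props[j]]] <- .ply_read_col(chunk, el$types[j], el$count,
                                               rec, offs[j])
        }
        vertex <- el
      }
      off <- off + need
    }
  }
  need_xyz <- c("x", "y", "z")
  if (!all(need_xyz %in% names(cols))) {
    stop_phyto("malformed PLY: vertex element lacks x,y,z",
               class = "ply_parse_error")
  }
  if (!all(c("red", "green", "blue") %in% names(cols))) {
    stop_phyto("colorless cloud: PLY vertex element has no red,green,blue properties (required for the chlorophyll pipeline)",
               class = "colorless_cloud_error")
  }
  n <- vertex$count
  pts <- cbind(x = cols$x, y = cols$y, z = cols$z)
  if (n == 0) pts <- matrix(numeric(0), 0, 3)
  rgb <- cbind(cols$red, cols$green, cols$blue)
  if (n == 0) rgb <- matrix(integer(0), 0, 3)
  extra <- setdiff(names(cols), c("x", "y", "z", "red", "green", "blue",
                                  "leaf"))
  attrs <- cols[extra]
  attrs <- lapply(attrs, function(v) { v[is.nan(v)] <- NA_real_; v })
  labs <- if ("leaf" %in% names(cols)) as.integer(cols$leaf) else NULL
  point_cloud(pts, rgb, attrs, labs, frame = frame)
}

.ply_write_col <- function(values, type) {
  switch(type,
    uchar = as.raw(as.integer(values)),
    int = writeBin(as.integer(values), raw(), size = 4, endian = "little"),
    float = writeBin(as.double(values), raw(), size = 4, endian = "little"),
    double = writeBin(as.double(values), raw(), size = 8, endian = "little"),
    stop("unsupported write type ", type))
}

#' Write a colored point cloud to a PLY file
#'
#' Emits a single `vertex` element: positions, RGB as `uchar`, every cloud
#' attribute as a per-vertex floating-point property (`NA` stored as NaN),
#' and leaf labels as an `int` property named `leaf`. Positions default to
#' `double` precision so a write/read round trip preserves coordinates;
#' pass `position_type = "float"` for single-precision output compatible
#' with tools that expect 32-bit positions.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @param position_type PLY type for x,y,z: `"double"` (default) or
#'   `"float"`.
#' @return invisibly, `path`.
#' @seealso [read_ply()]
#' @export
write_ply <- function(cloud, path, format = c("ascii", "binary_little_endian"),
                      position_type = c("double", "float")) {
  format <- match.arg(format)
  position_type <- match.arg(position_type)
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  anames <- names(cloud$attributes)
  props <- c(rep(position_type, 3), rep("uchar", 3),
             rep("float", length(anames)),
             if (!is.null(cloud$leaf_labels)) "int")
  pnames <- c("x", "y", "z", "red", "green", "blue", anames,
              if (!is.null(cloud$leaf_labels)) "leaf")
  header <- c("ply",
              paste("format", format, "1.0"),
              "comment phytocloud point cloud",
              paste("element vertex", n),
              paste("property", props, pnames),
              "end_header")
  columns <- c(lapply(1:3, function(j) cloud$points[, j]),
               lapply(1:3, function(j) cloud$colors[, j]),
               lapply(anames, function(nm) {
                 v <- cloud$attributes[[nm]]
                 v[is.na(v)] <- NaN
                 v
               }),
               if (!is.null(cloud$leaf_labels)) list(cloud$leaf_labels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0) return(invisible(path))
  if (format == "ascii") {
    txt <- do.call(paste, lapply(seq_along(columns), function(j) {
      if (props[j] %in% c("uchar", "int")) format(columns[[j]], scientific = FALSE)
      else sprintf("%.17g", columns[[j]])
    }))
    writeLines(txt, con, sep = "\n")
  } else {
    sizes <- c(uchar = 1L, int = 4L, float = 4L, double = 8L)[props]
    rec <- sum(sizes)
    offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
    out <- raw(n * rec)
    for (j in seq_along(columns)) {
      bytes <- .ply_write_col(columns[[j]], props[j])
      idx <- rep((seq_len(n) - 1L) * rec + offs[j], each = sizes[j]) +
        seq_len(sizes[j])
      out[idx] <- bytes
    }
    writeBin(out, con)
  }
  invisible(path)
}
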