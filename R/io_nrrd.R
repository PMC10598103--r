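# Voxel-mask volume I/O.
#
# The package's native exchange format for masks is a minimal NRRD
# single-volume container (detached text header + data in one file):
# 3-D, type uint8, axis-aligned space directions, voxel-centre origin.
# Axis order in the file matches the package convention -- the first
# (fastest) NRRD axis is the slice axis. Supported encodings: "ascii"
# (fully text, used for fixtures) and "raw" (uint8 bytes, compact, used
# by the simulator for large cohorts).

#' Read a voxel-mask volume (NRRD)
#'
#' Populates the grid from the header (sizes, axis-aligned space
#' directions as spacing, space origin as the centre of the first voxel)
#' and sets every nonzero voxel. Fails with a format error naming the
#' path on unreadable headers, non-3-D volumes, non-positive or
#' non-axis-aligned spacings.
#'
#' @param path an NRRD file written by [write_mask_volume()] or any
#'   axis-aligned uint8/int NRRD with `ascii` or `raw` encoding.
#' @return A [binary_mask()].
#' @export
read_mask_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p - prev == 1L) { hdr_end <- p; break }
    # tolerate CRLF
    if (p - prev == 2L && bytes[p - 1L] == as.raw(13L)) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed volume header (no blank line): ", path)
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (length(hdr) == 0 || !grepl("^NRRD", hdr[1]))
    stop("not an NRRD volume: ", path)
  fields <- list()
  for (ln in hdr[-1]) {
    if (ln == "" || grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("volume header missing field(s) ", paste(miss, collapse = ", "),
         ": ", path)
  if (fields$dimension != "3")
    stop("not a 3-D volume (dimension ", fields$dimension, "): ", path)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3 || anyNA(sizes) || any(sizes < 1))
    stop("bad sizes in volume header: ", path)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3) stop("bad space directions: ", path)
    m <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    if (any(abs(m[col(m) != row(m)]) > 1e-9))
      stop("non-axis-aligned space directions are not supported: ", path)
    spacing <- diag(m)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in volume header: ", path)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  n <- prod(sizes)
  enc <- tolower(fields$encoding)
  payload <- bytes[seq.int(hdr_end + 1L, length(bytes))]
  if (enc == "raw") {
    if (!(tolower(fields$type) %in% c("uint8", "uchar", "unsigned char")))
      stop("raw encoding supported for uint8 only: ", path)
    if (length(payload) < n) stop("truncated volume data: ", path)
    vals <- as.integer(payload[seq_len(n)])
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(text = rawToChar(payload), what = numeric(), quiet = TRUE)
    if (length(vals) != n)
      stop(sprintf("expected %d values, found %d: %s", n, length(vals), path))
  } else {
    stop("unsupported encoding '", fields$encoding, "': ", path)
  }
  grid <- image_grid(sizes, spacing, origin)
  binary_mask(array(vals != 0, sizes), grid)
}

#' Write a voxel-mask volume (NRRD)
#'
#' Round-trips through [read_mask_volume()]: grid spacing to 1e-6 mm,
#' origin to 1e-3 mm, voxels exactly.
#'
#' @param mask a [binary_mask()].
#' @param path output file.
#' @param encoding `"raw"` (uint8 bytes, compact) or `"ascii"` (fully
#'   text; use for small fixtures).
#' @return `path`, invisibly.
#' @export
write_mask_volume <- function(mask, path, encoding = c("raw", "ascii")) {
  stopifnot(inherits(mask, "binary_mask"))
  encoding <- match.arg(encoding)
  g <- mask$grid
  fmt <- function(x) sprintf("%.17g", x)
  hdr <- c(
    "NRRD0004",
    "type: uint8",
    "dimension: 3",
    paste("sizes:", paste(g$shape, collapse = " ")),
    "space dimension: 3",
    sprintf("space directions: (%s,0,0) (0,%s,0) (0,0,%s)",
            fmt(g$spacing_mm[1]), fmt(g$spacing_mm[2]), fmt(g$spacing_mm[3])),
    sprintf("space origin: (%s,%s,%s)",
            fmt(g$origin_mm[1]), fmt(g$origin_mm[2]), fmt(g$origin_mm[3])),
    paste("encoding:", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  v <- as.integer(mask$voxels)
  if (encoding == "raw") {
    writeBin(as.raw(v), con)
  } else {
    # 20 values per line keeps files diffable without being enormous
    idx <- ceiling(seq_along(v) / 20)
    lines <- vapply(split(v, idx), paste, character(1), collapse = " ")
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}
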