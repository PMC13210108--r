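#' Read a 3D NRRD volume
#'
#' Minimal NRRD reader covering the files this pipeline exchanges: 3D volumes,
#' attached header, encodings `raw`, `ascii`/`text`/`txt` and `gzip`, scalar
#' types `uchar`/`short`/`ushort`/`int`/`uint`/`float`/`double`, little- or
#' big-endian. Spacing is taken from `space directions` (diagonal) or
#' `spacings`; origin from `space origin`.
#'
#' @param path file path.
#' @param binary if `TRUE` return a [binary_volume()] (non-zero = foreground),
#'   otherwise a [scalar_volume()].
#' @return a [binary_volume()] or [scalar_volume()].
#' @export
read_nrrd <- function(path, binary = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)

  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (!identical(ndim, 3L)) stop("only 3-dimensional NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- tolower(fields[["type"]])
  enc <- tolower(fields[["encoding"]])
  n <- prod(sizes)

  spec <- switch(type,
    "uchar" = , "unsigned char" = , "uint8" = list(what = "integer", size = 1, signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2, signed = TRUE),
    "ushort" = , "uint16" = list(what = "integer", size = 2, signed = FALSE),
    "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
    "uint" = , "uint32" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported NRRD type: ", type))
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"

  values <- switch(enc,
    "raw" = readBin(con, spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian),
    "ascii" = , "text" = , "txt" = {
      txt <- readLines(con)
      as.numeric(scan(text = paste(txt, collapse = " "), quiet = TRUE))
    },
    "gzip" = , "gz" = {
      comp <- readBin(con, "raw", n = file.size(path))
      readBin(memDecompress(comp, type = "gzip"), spec$what, n = n,
              size = spec$size, signed = spec$signed, endian = endian)
    },
    stop("unsupported NRRD encoding: ", enc))
  if (length(values) != n) stop("NRRD payload has ", length(values),
                                " values, expected ", n)

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    spacing <- sqrt(colSums(mat^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  }

  arr <- array(values, dim = sizes)  # NRRD axis order is fastest-first, as in R
  if (binary) binary_volume(arr != 0, spacing, origin)
  else scalar_volume(arr, spacing, origin)
}

#' Write a 3D volume as NRRD
#'
#' @param vol a [binary_volume()] or [scalar_volume()].
#' @param path output file path.
#' @param encoding `"raw"`, `"ascii"` or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(vol, path, encoding = c("raw", "ascii", "gzip")) {
  encoding <- match.arg(encoding)
  is_bin <- inherits(vol, "binary_volume")
  stopifnot(is_bin || inherits(vol, "scalar_volume"))
  type <- if (is_bin) "uchar" else "double"
  dims <- dim(vol$data)
  dirs <- sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                  vol$spacing[1], vol$spacing[2], vol$spacing[3])
  header <- c(
    "NRRD0004",
    "# produced by wallpulse",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dims, collapse = " ")),
    paste("space directions:", dirs),
    "kinds: domain domain domain",
    if (encoding == "raw" && !is_bin) "endian: little",
    if (encoding == "raw" && is_bin) NULL,
    paste0("encoding: ", encoding),
    sprintf("space origin: (%g,%g,%g)", vol$origin[1], vol$origin[2], vol$origin[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  values <- if (is_bin) as.integer(vol$data) else as.numeric(vol$data)
  if (encoding == "ascii") {
    writeLines(paste(format(values, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  } else {
    payload <- if (is_bin) as.raw(values) else
      writeBin(values, raw(), size = 8, endian = "little")
    if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
    writeBin(payload, con)
  }
  invisible(path)
}
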