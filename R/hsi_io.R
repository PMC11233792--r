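#' Hyperspectral cube
#'
#' Container for a hyperspectral raster: a 3-D array of reflectance or
#' intensity values with dimensions (rows M, cols N, bands B), optional band
#' center wavelengths, and a free-text identifier.
#'
#' @param data numeric 3-D array, dims (M, N, B). Promoted to double.
#' @param band_centers optional numeric vector of B wavelengths (nm),
#'   strictly increasing.
#' @param name free-text identifier for the scene.
#' @return An object of class `hyper_cube` with elements `data`,
#'   `band_centers`, `name`.
#' @examples
#' cube <- hyper_cube(array(runif(5 * 4 * 3), c(5, 4, 3)), name = "toy")
#' dim(cube$data)
#' @export
hyper_cube <- function(data, band_centers = NULL, name = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows, cols, bands)", call. = FALSE)
  d <- dim(data)
  if (any(d < 1L)) stop("all cube dimensions must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  bad <- which(!is.finite(data))
  if (length(bad)) {
    band <- ((bad[1L] - 1L) %/% (d[1L] * d[2L])) + 1L
    stop(sprintf("cube contains %d non-finite value(s); first in band %d",
                 length(bad), band), call. = FALSE)
  }
  if (!is.null(band_centers)) {
    if (length(band_centers) != d[3L])
      stop("`band_centers` length must equal the number of bands",
           call. = FALSE)
    if (any(diff(band_centers) <= 0))
      stop("`band_centers` must be strictly increasing", call. = FALSE)
    band_centers <- as.numeric(band_centers)
  }
  structure(list(data = data, band_centers = band_centers,
                 name = as.character(name)[1L]),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube '%s'> %d x %d pixels, %d bands\n",
              x$name, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' Label mask
#'
#' Per-pixel integer class labels over an M x N grid. Codes are 1..C for the
#' C named classes; `unlabeled_value` (default 0) marks pixels without ground
#' truth.
#'
#' @param labels integer matrix (M, N).
#' @param class_names character vector of C class names, in code order
#'   (code c is `class_names[c]`).
#' @param unlabeled_value reserved integer not among 1..C.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, class_names, unlabeled_value = 0L) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stop("`labels` must contain finite integer codes", call. = FALSE)
  storage.mode(labels) <- "integer"
  unlabeled_value <- as.integer(unlabeled_value)
  C <- length(class_names)
  if (C < 1L) stop("at least one class name is required", call. = FALSE)
  if (unlabeled_value %in% seq_len(C))
    stop("`unlabeled_value` collides with a class code", call. = FALSE)
  codes <- setdiff(unique(as.vector(labels)), unlabeled_value)
  stray <- setdiff(codes, seq_len(C))
  if (length(stray)) {
    idx <- which(matrix(labels %in% stray, nrow(labels)), arr.ind = TRUE)
    shown <- utils::head(idx, 5L)
    stop(sprintf(
      "labels contain code(s) %s outside declared classes; e.g. at (row,col) %s",
      paste(stray, collapse = ", "),
      paste(sprintf("(%d,%d)", shown[, 1L] - 1L, shown[, 2L] - 1L),
            collapse = " ")), call. = FALSE)
  }
  structure(list(labels = labels, class_names = as.character(class_names),
                 unlabeled_value = unlabeled_value),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d, %d classes (%s), unlabeled = %d\n",
              nrow(x$labels), ncol(x$labels), length(x$class_names),
              paste(x$class_names, collapse = ", "), x$unlabeled_value))
  invisible(x)
}

#' Check that a cube and a mask cover the same grid
#'
#' @param cube a [hyper_cube].
#' @param mask a [label_mask].
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_pair <- function(cube, mask) {
  d <- dim(cube$data)
  if (nrow(mask$labels) != d[1L] || ncol(mask$labels) != d[2L])
    stop(sprintf("cube grid %d x %d does not match mask grid %d x %d",
                 d[1L], d[2L], nrow(mask$labels), ncol(mask$labels)),
         call. = FALSE)
  invisible(TRUE)
}

# ---- ENVI dialect ----------------------------------------------------------
# Flat binary + ASCII .hdr sidecar; BSQ/BIL/BIP interleaves, little or big
# endian, float32/float64 payloads. ENVI "lines" are rows, "samples" columns.

envi_dtype <- function(code) {
  switch(as.character(code),
         "4" = list(what = "double", size = 4L),
         "5" = list(what = "double", size = 8L),
         stop(sprintf("unsupported ENVI data type %s (only 4/5 = float32/64)",
                      code), call. = FALSE))
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[1L]))
    stop("not an ENVI header: missing ENVI magic line", call. = FALSE)
  fields <- list()
  # simple key = value parser; { ... } blocks may span lines
  buf <- ""
  for (ln in lines[-1L]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    if (grepl("\\{", buf) && !grepl("\\}", buf)) next
    m <- regmatches(buf, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", buf))[[1L]]
    if (length(m) == 3L) fields[[tolower(m[2L])]] <- trimws(m[3L])
    buf <- ""
  }
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop(sprintf("ENVI header missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  fields
}

envi_header_text <- function(M, N, B, data_type, interleave, byte_order,
                             band_centers = NULL, name = "") {
  out <- c("ENVI",
           sprintf("description = {%s}", name),
           sprintf("samples = %d", N),
           sprintf("lines = %d", M),
           sprintf("bands = %d", B),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           sprintf("byte order = %d", byte_order))
  if (!is.null(band_centers))
    out <- c(out, sprintf("wavelength = {%s}",
                          paste(format(band_centers, trim = TRUE),
                                collapse = ", ")))
  out
}

# permutation taking (M, N, B) array dims to on-disk fastest-to-slowest order
interleave_perm <- function(interleave) {
  switch(interleave,
         bsq = c(2L, 1L, 3L),   # col fastest, then row, then band
         bil = c(2L, 3L, 1L),   # col, band, row
         bip = c(3L, 2L, 1L),   # band, col, row
         stop(sprintf("unknown interleave '%s'", interleave), call. = FALSE))
}

write_envi_cube <- function(cube, path, interleave = "bsq",
                            data_type = 5L, byte_order = 0L) {
  interleave <- match.arg(interleave, c("bsq", "bil", "bip"))
  d <- dim(cube$data)
  dt <- envi_dtype(data_type)
  perm <- interleave_perm(interleave)
  vals <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = dt$size,
           endian = if (byte_order == 0L) "little" else "big")
  writeLines(envi_header_text(d[1L], d[2L], d[3L], data_type, interleave,
                              byte_order, cube$band_centers, cube$name),
             paste0(path, ".hdr"))
  invisible(path)
}

read_envi_cube <- function(path) {
  candidates <- unique(c(paste0(path, ".hdr"),
                         sub("\\.[^.]+$", ".hdr", path)))
  candidates <- setdiff(candidates[file.exists(candidates)], path)
  if (!length(candidates))
    stop(sprintf("missing ENVI header for '%s' (looked for '%s')",
                 path, paste0(path, ".hdr")), call. = FALSE)
  hdr_path <- candidates[1L]
  h <- parse_envi_header(hdr_path)
  M <- as.integer(h$lines); N <- as.integer(h$samples)
  B <- as.integer(h$bands)
  dt <- envi_dtype(h[["data type"]])
  byte_order <- as.integer(h[["byte order"]] %||% "0")
  interleave <- tolower(h$interleave)
  offset <- as.integer(h[["header offset"]] %||% "0")
  n_expect <- as.double(M) * N * B
  payload <- file.size(path) - offset
  if (payload != n_expect * dt$size)
    stop(sprintf(
      "ENVI payload holds %.0f values but header declares %d x %d x %d = %.0f",
      payload / dt$size, M, N, B, n_expect), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", offset)
  vals <- readBin(con, dt$what, n = n_expect, size = dt$size,
                  endian = if (byte_order == 0L) "little" else "big")
  perm <- interleave_perm(interleave)
  arr <- array(vals, dim = c(M, N, B)[perm])
  arr <- aperm(arr, order(perm))
  wl <- NULL
  if (!is.null(h$wavelength)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1L]])
  }
  name <- if (!is.null(h$description)) gsub("[{}]", "", h$description) else ""
  hyper_cube(arr, band_centers = wl, name = trimws(name))
}

# ---- portable array container ----------------------------------------------
# Single file: magic "SCSARR01", uint32 little-endian header length, JSON
# header, float64 little-endian payload in column-major (M, N, B) order.

ARRAY_MAGIC <- charToRaw("SCSARR01")

write_array_cube <- function(cube, path) {
  d <- dim(cube$data)
  hdr <- jsonlite::toJSON(list(dims = d, order = "column_major_MNB",
                               dtype = "float64", name = cube$name,
                               band_centers = cube$band_centers),
                          auto_unbox = TRUE, null = "null", digits = NA)
  hraw <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(ARRAY_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(cube$data), con, size = 8L, endian = "little")
  invisible(path)
}

read_array_cube <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, ARRAY_MAGIC))
    stop(sprintf("'%s' is not an array-container cube (bad magic)", path),
         call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  d <- as.integer(hdr$dims)
  n_expect <- prod(as.double(d))
  vals <- readBin(con, "double", n = n_expect + 1L, size = 8L,
                  endian = "little")
  if (length(vals) != n_expect)
    stop(sprintf("array container holds %d values, header declares %.0f",
                 length(vals), n_expect), call. = FALSE)
  bc <- hdr$band_centers
  if (is.null(bc) || !length(bc)) bc <- NULL
  hyper_cube(array(vals, dim = d), band_centers = bc,
             name = hdr$name %||% "")
}

#' Write a hyperspectral cube
#'
#' Two dialects are supported: `envi` (flat binary plus ASCII `.hdr` sidecar,
#' BSQ/BIL/BIP interleaves, the de-facto standard for hyperspectral imagery)
#' and `array` (a single portable container with an embedded JSON header and
#' a float64 payload).
#'
#' @param cube a [hyper_cube].
#' @param path output file path (ENVI writes `path` and `path.hdr`).
#' @param format `"envi"` or `"array"`.
#' @param interleave ENVI interleave, one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "array"),
                       interleave = "bsq", data_type = 5L) {
  format <- match.arg(format)
  if (!inherits(cube, "hyper_cube"))
    stop("`cube` must be a hyper_cube", call. = FALSE)
  switch(format,
         envi  = write_envi_cube(cube, path, interleave, data_type),
         array = write_array_cube(cube, path))
}

#' Read a hyperspectral cube
#'
#' @param path file path. ENVI expects an accompanying `.hdr`.
#' @param format `"envi"`, `"array"`, or `NULL` to sniff the container magic.
#' @return A [hyper_cube]; all values promoted to double. Fails (rather than
#'   truncating) when the header and payload disagree, and rejects non-finite
#'   values naming the offending band.
#' @export
read_cube <- function(path, format = NULL) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  if (is.null(format)) {
    con <- file(path, "rb")
    magic <- readBin(con, "raw", 8L)
    close(con)
    format <- if (identical(magic, ARRAY_MAGIC)) "array" else "envi"
  }
  format <- match.arg(format, c("envi", "array"))
  switch(format, envi = read_envi_cube(path), array = read_array_cube(path))
}

# ---- label masks ------------------------------------------------------------
# Grayscale PNG (integer codes, so <= 255 classes) + JSON sidecar carrying
# class names and the unlabeled code.

#' Write a label mask
#'
#' Stores the integer codes as a grayscale PNG (lossless for codes up to 255)
#' with a JSON sidecar `path.json` declaring class names and the unlabeled
#' code.
#'
#' @param mask a [label_mask].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask"))
    stop("`mask` must be a label_mask", call. = FALSE)
  if (max(mask$labels) > 255L || min(mask$labels) < 0L)
    stop("PNG mask storage supports codes in 0..255", call. = FALSE)
  png::writePNG(mask$labels / 255, path)
  jsonlite::write_json(list(class_names = mask$class_names,
                            unlabeled_value = mask$unlabeled_value),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label mask
#'
#' @param path PNG path written by [write_label_mask()], or any integer-coded
#'   grayscale PNG if `class_names` is given explicitly.
#' @param class_names optional override of the sidecar class names.
#' @param unlabeled_value optional override of the sidecar unlabeled code.
#' @param remap_unknown if `TRUE`, codes outside the declared set are mapped
#'   to the unlabeled value; the default strict mode errors, listing the
#'   offending coordinates.
#' @return A [label_mask].
#' @export
read_label_mask <- function(path, class_names = NULL, unlabeled_value = NULL,
                            remap_unknown = FALSE) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  codes <- img * 255
  if (max(abs(codes - round(codes))) > 1e-6)
    stop("mask PNG does not hold integer codes", call. = FALSE)
  codes <- round(codes)
  storage.mode(codes) <- "integer"
  side <- paste0(path, ".json")
  if (is.null(class_names) || is.null(unlabeled_value)) {
    if (!file.exists(side))
      stop(sprintf("no sidecar '%s' and no explicit class declaration", side),
           call. = FALSE)
    meta <- jsonlite::fromJSON(side)
    if (is.null(class_names)) class_names <- meta$class_names
    if (is.null(unlabeled_value)) unlabeled_value <- meta$unlabeled_value
  }
  if (remap_unknown) {
    known <- c(seq_along(class_names), as.integer(unlabeled_value))
    codes[!(codes %in% known)] <- as.integer(unlabeled_value)
  }
  label_mask(codes, class_names, unlabeled_value)
}

# ---- classification map rendering -------------------------------------------

#' Default class palette
#'
#' @param class_names character vector of class names.
#' @return Named character vector of hex colors, one per class.
#' @export
default_palette <- function(class_names) {
  base <- c("#3CB44B", "#E6194B", "#4363D8", "#A9A9A9", "#F58231", "#911EB4",
            "#46F0F0", "#F032E6", "#BCF60C", "#FABEBE")
  if (length(class_names) > length(base))
    base <- grDevices::rainbow(length(class_names))
  stats::setNames(base[seq_along(class_names)], class_names)
}

hex_to_rgb <- function(hex) t(grDevices::col2rgb(hex)) / 255

#' Render a classification map to a PNG image
#'
#' One pixel per grid cell, colored by the class palette; unlabeled pixels
#' get the background color. Lossless, so the class of every pixel can be
#' recovered by [read_classification_map()].
#'
#' @param mask a [label_mask] of predicted (or true) classes.
#' @param path output PNG path.
#' @param palette named vector/list mapping every class name to a color;
#'   defaults to [default_palette()].
#' @param background color for unlabeled pixels.
#' @return `path`, invisibly.
#' @export
write_classification_map <- function(mask, path,
                                     palette = default_palette(mask$class_names),
                                     background = "#000000") {
  miss <- setdiff(mask$class_names[sort(unique(mask$labels[mask$labels != mask$unlabeled_value]))],
                  names(palette))
  if (length(miss))
    stop(sprintf("palette is missing class(es): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  cols <- rbind(hex_to_rgb(background),
                hex_to_rgb(unlist(palette[mask$class_names])))
  idx <- mask$labels
  idx[idx == mask$unlabeled_value] <- 0L
  img <- array(0, dim = c(nrow(idx), ncol(idx), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(cols[idx + 1L, ch], nrow(idx))
  png::writePNG(img, path)
  jsonlite::write_json(list(class_names = mask$class_names,
                            unlabeled_value = mask$unlabeled_value,
                            palette = as.list(palette[mask$class_names]),
                            background = background),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Decode a rendered classification map back to a label mask
#'
#' Inverts [write_classification_map()] by matching each pixel's RGB value
#' against the palette recorded in the sidecar (or given explicitly).
#'
#' @param path PNG path.
#' @param palette,background,class_names,unlabeled_value optional overrides
#'   of the sidecar metadata.
#' @return A [label_mask].
#' @export
read_classification_map <- function(path, palette = NULL, background = NULL,
                                    class_names = NULL,
                                    unlabeled_value = NULL) {
  meta_path <- paste0(path, ".json")
  if ((is.null(palette) || is.null(class_names)) && !file.exists(meta_path))
    stop(sprintf("no sidecar '%s' and no explicit palette", meta_path),
         call. = FALSE)
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    if (is.null(palette)) palette <- unlist(meta$palette)
    if (is.null(background)) background <- meta$background
    if (is.null(class_names)) class_names <- meta$class_names
    if (is.null(unlabeled_value)) unlabeled_value <- meta$unlabeled_value
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]
  cols <- rbind(hex_to_rgb(background), hex_to_rgb(unlist(palette[class_names])))
  M <- dim(img)[1L]; N <- dim(img)[2L]
  flat <- matrix(img, M * N, 3L)
  # nearest palette entry; exact for losslessly rendered maps
  d2 <- outer(rowSums(flat^2), rowSums(cols^2), "+") - 2 * flat %*% t(cols)
  idx <- max.col(-d2, ties.method = "first") - 1L
  labels <- matrix(idx, M, N)
  labels[labels == 0L] <- as.integer(unlabeled_value)
  label_mask(labels, class_names, unlabeled_value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
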