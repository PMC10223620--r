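#' Read a micrograph from PNG or TIFF
#'
#' Loads an 8- or 16-bit raster image and returns pixel intensities normalized
#' to `[0, 1]`. Grayscale images become a numeric matrix (rows = image rows,
#' origin top-left); color images become a `height x width x 3` array. Alpha
#' channels are dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (grayscale) or 3-channel array with values in
#'   `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG or TIFF expected): ", path)
  )
  if (length(dim(px)) == 3L) {
    nc <- dim(px)[3L]
    if (nc == 2L) px <- px[, , 1L]                 # gray + alpha
    else if (nc >= 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha if RGBA
    else if (nc == 1L) px <- px[, , 1L]
  }
  # readPNG/readTIFF already rescale integer depths to [0,1]
  px
}

#' Normalize raw integer intensities to \[0, 1\]
#'
#' Divides 8-bit or 16-bit pixel values by the type maximum (255 or 65535).
#' Values already in `[0, 1]` are returned unchanged under `"auto"`.
#'
#' @param pixels Numeric matrix or array of raw intensities.
#' @param bit_depth `"auto"` (inferred from the value range), `"8"` or `"16"`.
#' @return Pixels rescaled to `[0, 1]`.
#' @export
normalize_intensity <- function(pixels, bit_depth = c("auto", "8", "16")) {
  bit_depth <- match.arg(bit_depth)
  mx <- max(pixels, na.rm = TRUE)
  div <- switch(bit_depth,
    "8" = 255,
    "16" = 65535,
    auto = if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
  )
  out <- pixels / div
  if (min(out, na.rm = TRUE) < 0 || max(out, na.rm = TRUE) > 1) {
    stop("intensities outside [0, 1] after normalization; check bit_depth")
  }
  out
}

#' Convert a color micrograph to grayscale
#'
#' Uses the standard luma weights (0.299, 0.587, 0.114). A single-channel
#' image is returned unchanged.
#'
#' @param image Numeric matrix, or `h x w x 1` / `h x w x 3` array, values in
#'   `[0, 1]`.
#' @return Numeric matrix of grayscale intensities in `[0, 1]`.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) != 3L) stop("expected a matrix or a 3-dimensional array")
  if (d[3L] == 1L) return(image[, , 1L])
  if (d[3L] == 3L) {
    return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
  }
  stop("unsupported channel count: ", d[3L], " (1 or 3 expected)")
}

#' Write a binary mask as an 8-bit PNG (0 = background, 255 = foreground)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask written by [save_mask()]
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  px <- load_image(path)
  px <- to_grayscale(px)
  px > 0.5
}

#' Write a three-label partition (metal / hole / bone) as one PNG
#'
#' Encodes metal as 0, holes as 128/255 and bone as 255/255, the layout also
#' accepted for manually annotated masks.
#'
#' @param metal,hole,bone Disjoint logical matrices of equal size.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_labels <- function(metal, hole, bone, path) {
  check_same_shape(metal, hole)
  check_same_shape(metal, bone)
  if (any(metal & hole) || any(metal & bone) || any(hole & bone)) {
    stop("label masks overlap")
  }
  lab <- matrix(0, nrow(metal), ncol(metal))
  lab[hole] <- 128 / 255
  lab[bone] <- 1
  png::writePNG(lab, path)
  invisible(path)
}

#' Read a three-label PNG into hole and bone masks
#'
#' @param path PNG path with levels 0 (metal), 128 (hole), 255 (bone).
#' @return List with logical matrices `metal`, `hole`, `bone`.
#' @export
load_labels <- function(path) {
  px <- to_grayscale(load_image(path))
  list(
    metal = px < 0.25,
    hole  = px >= 0.25 & px < 0.75,
    bone  = px >= 0.75
  )
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("masks/images have mismatched shapes: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

check_grayscale01 <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("expected a numeric grayscale matrix")
  }
  r <- range(image)
  if (r[1] < -1e-9 || r[2] > 1 + 1e-9) {
    stop("grayscale intensities must lie in [0, 1]; got range [",
         signif(r[1], 4), ", ", signif(r[2], 4), "]")
  }
  invisible(TRUE)
}
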