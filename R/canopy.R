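#' Construct a canopy image
#'
#' Wraps a matrix of grayscale pixel intensities in \[0, 255\] together
#' with the photo-station and plot identifiers of the hemispherical
#' photograph (sixteen fixed stations per plot, on a 20-m grid).
#'
#' @param pixels numeric matrix of intensities in \[0, 255\]; must be
#'   non-empty.
#' @param station_id station number (1-16) or `NA`.
#' @param plot_id plot identifier or `NA`.
#' @return Object of class `canopy_image`.
#' @export
canopy_image <- function(pixels, station_id = NA_integer_,
                         plot_id = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop("'pixels' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(is.na(pixels)) || any(pixels < 0) || any(pixels > 255)) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, station_id = as.integer(station_id),
                 plot_id = as.character(plot_id)),
            class = "canopy_image")
}

#' @export
print.canopy_image <- function(x, ...) {
  cat(sprintf("Canopy image %dx%d (plot %s, station %s)\n",
              nrow(x$pixels), ncol(x$pixels), x$plot_id, x$station_id))
  invisible(x)
}

#' Read a hemispherical photograph from PNG or TIFF
#'
#' Loads a grayscale or colour image and reduces it to a single intensity
#' channel scaled to \[0, 255\]. For colour images the blue channel is
#' used by default — standard practice for sky/canopy contrast in
#' hemispherical photography — with red, green or a Rec. 709 luminance
#' combination as alternatives.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param channel channel selector for colour images: `"blue"`
#'   (default), `"red"`, `"green"` or `"luminance"`.
#' @param station_id,plot_id identifiers to attach; see [canopy_image()].
#' @return A [canopy_image()].
#' @export
read_canopy_image <- function(path, channel = c("blue", "red", "green",
                                                "luminance"),
                              station_id = NA_integer_,
                              plot_id = NA_character_) {
  channel <- match.arg(channel)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    gray <- switch(channel,
      red = arr[, , 1],
      green = arr[, , 2],
      blue = arr[, , min(3L, dim(arr)[3])],
      luminance = 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] +
        0.0722 * arr[, , min(3L, dim(arr)[3])]
    )
  } else {
    gray <- arr
  }
  canopy_image(gray * 255, station_id = station_id, plot_id = plot_id)
}

#' Canopy fraction of one photograph
#'
#' Percentage of pixels classified as canopy by intensity thresholding:
#' pixels strictly below the threshold are canopy (dark foliage), pixels
#' at or above it are sky. The default cut-off of 125 on the \[0, 255\]
#' scale delineates canopy from sky.
#'
#' An optional circular mask restricts the calculation to pixels within
#' `mask_radius` (in pixels) of the image centre, for fisheye frames
#' whose corners are not part of the hemisphere.
#'
#' @param image a [canopy_image()] or bare intensity matrix in
#'   \[0, 255\].
#' @param threshold intensity cut-off (default 125).
#' @param mask_radius optional circular mask radius in pixels; `NULL`
#'   (default) uses the full frame.
#' @return Canopy cover percent in \[0, 100\].
#' @export
#' @examples
#' canopy_fraction(matrix(c(0, 255), 2, 2))  # 50
canopy_fraction <- function(image, threshold = 125, mask_radius = NULL) {
  if (inherits(image, "canopy_image")) image <- image$pixels
  if (!is.matrix(image) || length(image) == 0L) {
    stop("'image' must be a non-empty canopy image or matrix", call. = FALSE)
  }
  px <- image
  if (!is.null(mask_radius)) {
    ctr <- (dim(px) + 1) / 2
    rr <- outer((seq_len(nrow(px)) - ctr[1])^2,
                (seq_len(ncol(px)) - ctr[2])^2, "+")
    px <- px[rr <= mask_radius^2]
    if (length(px) == 0L) {
      stop("circular mask excludes every pixel", call. = FALSE)
    }
  }
  100 * mean(px < threshold)
}

#' Plot-level canopy cover over photo stations
#'
#' Averages the canopy fraction of the hemispherical photographs taken at
#' a plot's fixed stations (unweighted mean) and reports the per-station
#' fractions individually. All images must belong to the same plot.
#'
#' @param images list of [canopy_image()]s from one plot.
#' @param threshold intensity cut-off passed to [canopy_fraction()].
#' @param mask_radius optional circular mask, see [canopy_fraction()].
#' @return List with `plot_id`, `mean_cover_pct` and `stations` (data
#'   frame of `station_id`, `cover_pct`).
#' @export
plot_canopy_cover <- function(images, threshold = 125, mask_radius = NULL) {
  if (!is.list(images) || length(images) == 0L ||
      !all(vapply(images, inherits, logical(1), "canopy_image"))) {
    stop("'images' must be a non-empty list of canopy_image objects",
         call. = FALSE)
  }
  ids <- unique(vapply(images, `[[`, "", "plot_id"))
  if (length(ids) > 1L) {
    stop(sprintf("images belong to different plots: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  cover <- vapply(images, canopy_fraction, numeric(1),
                  threshold = threshold, mask_radius = mask_radius)
  list(
    plot_id = ids,
    mean_cover_pct = mean(cover),
    stations = data.frame(
      station_id = vapply(images, `[[`, integer(1), "station_id"),
      cover_pct = cover
    )
  )
}
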