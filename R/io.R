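# Image, label and manifest I/O.

#' Read a raster image scaled to [0, 1]
#'
#' Reads PNG/TIFF (anything EBImage reads) and returns an H x W x C array
#' (or a matrix for single-channel images) with intensities in `[0, 1]`.
#' Integer inputs are rescaled by the dtype maximum; float inputs are
#' assumed already scaled and are clipped with a warning otherwise.  An
#' alpha channel, if present, is dropped with a warning.
#'
#' @param path file path.
#' @return numeric matrix (grayscale) or H x W x C array.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_invalid(paste("cannot read image:", path), "nbracm_io_error")
  img <- EBImage::readImage(path)   # readImage already scales ints to [0,1]
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    out <- t(a)
  } else {
    if (dim(a)[3L] == 4L) {
      warning("dropping alpha channel")
      a <- a[, , 1:3, drop = FALSE]
    }
    if (dim(a)[3L] == 2L) {
      warning("dropping alpha channel")
      a <- a[, , 1L, drop = FALSE]
    }
    out <- aperm(a, c(2L, 1L, 3L))
    if (dim(out)[3L] == 1L) out <- out[, , 1L]
  }
  if (min(out) < 0 || max(out) > 1) {
    warning("intensities outside [0, 1]; clipping")
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Write an image array to PNG/TIFF
#'
#' @param image matrix or H x W x C array in `[0, 1]`.
#' @param path output path; format from the extension.
#' @export
write_image <- function(image, path) {
  a <- if (is.matrix(image)) t(image) else aperm(image, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(a, colormode = if (is.matrix(image)) 0L else 2L),
                      path)
  invisible(path)
}

#' Write a region labeling as an 8-bit label PNG
#'
#' Label values are stored directly as 8-bit gray levels (0..255), so a
#' re-read with [read_label_png()] reproduces the labeling exactly.
#'
#' @param labels integer matrix of labels in `[0, 255]`.
#' @param path output path.
#' @export
write_label_png <- function(labels, path) {
  if (max(labels) > 255L || min(labels) < 0L)
    stop_invalid("labels must lie in [0, 255] for 8-bit output", "nbracm_invalid_input")
  EBImage::writeImage(EBImage::Image(t(labels / 255)), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  matrix(as.integer(round(t(a) * 255)), ncol(a), nrow(a))
}

#' Run manifest
#'
#' A YAML record of everything needed to reproduce a run bit-identically:
#' inputs, model, resolved configuration, seed and output paths.
#'
#' @param path output YAML path.
#' @param inputs character vector of input paths.
#' @param model model name.
#' @param config the resolved configuration list.
#' @param seed integer seed.
#' @param outputs character vector of output paths.
#' @param extra optional named list of additional fields (iteration counts,
#'   wall summary).
#' @export
write_manifest <- function(path, inputs, model, config, seed, outputs,
                           extra = list()) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  m <- c(list(inputs = as.list(inputs), model = model, config = cfg,
              seed = seed, outputs = as.list(outputs)), extra)
  yaml::write_yaml(m, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)

#' Display helpers
#'
#' Base-graphics previews of images, level sets and labelings.
#'
#' @param x matrix, H x W x 3 array, or `region_labeling`.
#' @param ... passed to [graphics::image()] where applicable.
#' @name plotting
NULL

#' @rdname plotting
#' @export
plot_field <- function(x, ...) {
  graphics::image(t(x[nrow(x):1, , drop = FALSE]), axes = FALSE, asp = nrow(x) / ncol(x), ...)
}

#' @rdname plotting
#' @export
plot_labels <- function(x, ...) {
  lab <- if (inherits(x, "region_labeling")) x$labels else x
  k <- max(lab) + 1L
  plot_field(lab, col = label_palette(max(1L, ceiling(log2(max(2L, k))))), ...)
}
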