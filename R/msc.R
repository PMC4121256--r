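#' Multichannel segmentation combination
#'
#' Maps N per-channel level-set fields to a per-pixel sign sequence and an
#' integer region label.  Each channel contributes one sign
#' `s_i = 1 if phi_i > 0 else 0` (so `s_i = 0` marks the pixel as interior to
#' channel i's contour, the region containing that channel's component); the
#' label is the base-2 encoding `sum(s_i * 2^(N - i))`, giving up to `2^N`
#' distinct regions.  Channel order is fixed (R, G, B for N = 3) so labels
#' are stable across runs.
#'
#' @param phis list of N numeric matrices (per-channel level-set fields),
#'   all of the same shape.
#' @return an object of class `region_labeling` with fields `labels`
#'   (integer matrix in `[0, 2^N)`), `signs` (H x W x N array of 0/1), and
#'   `n_channels`.
#' @export
msc_combine <- function(phis) {
  if (!is.list(phis) || length(phis) < 1L)
    stop_invalid("`phis` must be a nonempty list of matrices", "nbracm_invalid_input")
  N <- length(phis)
  ok <- vapply(phis, function(p) is.matrix(p) && is.numeric(p), logical(1))
  if (!all(ok))
    stop_invalid("`phis` must contain numeric matrices", "nbracm_invalid_input")
  dims <- vapply(phis, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_invalid("all level-set fields must have the same shape", "nbracm_invalid_input")
  H <- nrow(phis[[1L]]); W <- ncol(phis[[1L]])
  signs <- array(0L, c(H, W, N))
  labels <- matrix(0L, H, W)
  for (i in seq_len(N)) {
    s <- matrix(as.integer(phis[[i]] > 0), H, W)
    signs[, , i] <- s
    labels <- labels + s * as.integer(2^(N - i))
  }
  structure(list(labels = labels, signs = signs, n_channels = N),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<region_labeling> %d x %d | %d channels | %d of %d possible labels\n",
              nrow(x$labels), ncol(x$labels), x$n_channels,
              length(tab), 2L^x$n_channels))
  invisible(x)
}

#' Default label palette
#'
#' `2^N` visually distinct RGB colors for colorizing region labels.
#'
#' @param n_channels number of channels N.
#' @return character vector of `2^N` hex colors.
#' @export
label_palette <- function(n_channels) {
  base <- c("#000000", "#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231",
            "#911EB4", "#46F0F0", "#F032E6", "#BCF60C", "#FABEBE", "#008080",
            "#E6BEFF", "#9A6324", "#FFFAC8", "#800000")
  k <- 2L^n_channels
  if (k <= length(base)) base[seq_len(k)] else grDevices::rainbow(k)
}

#' Colorize a region labeling
#'
#' Deterministic label-to-color mapping: the same label always maps to the
#' same palette entry, and distinct labels stay distinguishable.
#'
#' @param labeling a `region_labeling` from [msc_combine()].
#' @param palette character vector of at least `max(label) + 1` colors
#'   (recycled never); defaults to [label_palette()].
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
label_to_color <- function(labeling, palette = label_palette(labeling$n_channels)) {
  if (!inherits(labeling, "region_labeling"))
    stop_invalid("`labeling` must come from msc_combine()", "nbracm_invalid_parameter")
  need <- max(labeling$labels) + 1L
  if (length(palette) < need)
    stop_invalid(sprintf("palette has %d colors but %d are required",
                         length(palette), need), "nbracm_invalid_parameter")
  rgb <- grDevices::col2rgb(palette) / 255
  H <- nrow(labeling$labels); W <- ncol(labeling$labels)
  out <- array(0, c(H, W, 3L))
  idx <- labeling$labels + 1L
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, idx], H, W)
  out
}
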