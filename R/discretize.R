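# Gray-level discretization of in-mask intensities -- the prerequisite of
# every texture matrix family.

#' Discretize in-mask intensities into gray levels
#'
#' Two schemes:
#' * `fixed_bin_width`: level = floor((x - min_in_mask) / width) + 1;
#' * `fixed_bin_count`: `bins` equal-width bins over the in-mask range.
#'
#' A constant region maps to the single level 1 in either scheme.
#'
#' @param image 3D volume.
#' @param mask logical 3D array (non-empty).
#' @param scheme `"fixed_bin_width"` or `"fixed_bin_count"`.
#' @param width bin width in map units (default 25).
#' @param bins bin count for `fixed_bin_count`.
#' @return a `DiscretizedImage` list: `levels` (integer volume, 0 outside the
#'   mask), `nLevels`, and the scheme settings.
#' @export
discretize <- function(image, mask, scheme = c("fixed_bin_width", "fixed_bin_count"),
                       width = 25, bins = 16) {
  scheme <- match.arg(scheme)
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  x <- image[mask]
  lev <- integer(length(x))
  if (scheme == "fixed_bin_width") {
    if (width <= 0) stop("width must be positive")
    lev <- as.integer(floor((x - min(x)) / width)) + 1L
  } else {
    if (bins < 1) stop("bins must be >= 1")
    rng <- range(x)
    if (diff(rng) == 0) {
      lev <- rep(1L, length(x))
    } else {
      w <- diff(rng) / bins
      lev <- pmin(as.integer(floor((x - rng[1]) / w)) + 1L, as.integer(bins))
    }
  }
  levels <- array(0L, dim(image))
  levels[mask] <- lev
  structure(list(levels = levels, nLevels = max(lev), scheme = scheme,
                 width = if (scheme == "fixed_bin_width") width else NULL,
                 bins = if (scheme == "fixed_bin_count") bins else NULL),
            class = "DiscretizedImage")
}
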