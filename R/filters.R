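# Image filter bank: Laplacian-of-Gaussian at physical scales, one-level
# undecimated separable wavelet decomposition (coif1), and range-normalized
# intensity remaps (square, square root, logarithm, exponential).

# coif1 decomposition filters (orthogonal, 6 taps)
coif1Lo <- function() c(-0.015655728135465, -0.072732619512854,
                        0.384864846864203, 0.852572020212255,
                        0.337897662457809, -0.072732619512854)
coif1Hi <- function() {
  lo <- coif1Lo()
  n <- seq_along(lo) - 1
  (-1)^(n + 1) * rev(lo)
}

# index a 3D array along one axis with an index vector (replicate padding
# already baked into idx)
sliceAxis <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# 1D convolution along `axis` with replicate (nearest) boundary padding
conv1dAxis <- function(a, kern, axis) {
  d <- dim(a); n <- d[axis]
  r <- (length(kern) - 1) %/% 2
  out <- array(0, d)
  base <- seq_len(n)
  for (t in seq_along(kern)) {
    if (kern[t] == 0) next
    idx <- pmin(pmax(base + (t - 1 - r), 1L), n)
    out <- out + kern[t] * sliceAxis(a, axis, idx)
  }
  out
}

logKernels <- function(sigmaVox) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigmaVox^2))
  nrm <- sum(g)
  d2 <- ((x^2 - sigmaVox^2) / sigmaVox^4) * g / nrm
  d2 <- d2 - mean(d2)  # exact zero DC response: ramps map to zero
  list(g = g / nrm, d2 = d2)
}

#' Specify an image filter
#'
#' @param family one of `"original"`, `"log_sigma"`, `"wavelet"`, `"square"`,
#'   `"square_root"`, `"logarithm"`, `"exponential"`.
#' @param sigma Laplacian-of-Gaussian scale in mm (required for `log_sigma`).
#' @param subband 3-letter wavelet subband label over axes x, y, z
#'   (e.g. `"LLH"`; required for `wavelet`).
#' @return a `FilterSpec` list with a printable `label`.
#' @export
filterSpec <- function(family = c("original", "log_sigma", "wavelet", "square",
                                  "square_root", "logarithm", "exponential"),
                       sigma = NULL, subband = NULL) {
  family <- match.arg(family)
  if (family == "log_sigma") {
    if (is.null(sigma) || sigma <= 0) stop("log_sigma requires sigma > 0")
  } else if (!is.null(sigma)) stop("sigma is only meaningful for log_sigma")
  if (family == "wavelet") {
    if (is.null(subband) || !grepl("^[LH]{3}$", subband))
      stop("wavelet requires a subband label such as 'LLH'")
  } else if (!is.null(subband)) stop("subband is only meaningful for wavelet")
  label <- switch(family,
                  original = "original",
                  log_sigma = paste0("log-sigma-", sigma),
                  wavelet = paste0("wavelet-", subband),
                  square = "square",
                  square_root = "square-root",
                  logarithm = "logarithm",
                  exponential = "exponential")
  structure(list(family = family, sigma = sigma, subband = subband,
                 label = label), class = "FilterSpec")
}

#' The default filter bank
#'
#' Original image, Laplacian-of-Gaussian at 1-5 mm, the eight wavelet
#' subbands, and the four intensity remaps: 18 filtered images per map.
#'
#' @param logSigmas LoG scales in mm.
#' @param waveletSubbands subband labels to emit.
#' @return list of `FilterSpec`s.
#' @export
defaultFilterBank <- function(logSigmas = 1:5,
                              waveletSubbands = c("LLL", "LLH", "LHL", "LHH",
                                                  "HLL", "HLH", "HHL", "HHH")) {
  c(list(filterSpec("original")),
    lapply(logSigmas, function(s) filterSpec("log_sigma", sigma = s)),
    lapply(waveletSubbands, function(b) filterSpec("wavelet", subband = b)),
    list(filterSpec("square"), filterSpec("square_root"),
         filterSpec("logarithm"), filterSpec("exponential")))
}

#' Apply a filter to a volume
#'
#' `log_sigma` convolves with the Laplacian-of-Gaussian at physical scale
#' `sigma` (mm, converted per-axis through `spacing`). `wavelet` performs a
#' one-level undecimated separable coif1 decomposition; the subband letter k
#' selects the low/high-pass filter along axis k, so eight subbands exist.
#' The intensity remaps use range-normalized forms (with M = max |x| over the
#' volume): square `x^2/M`, square root `sign(x) sqrt(M |x|)`, logarithm
#' `sign(x) * M/log(M+1) * log(|x|+1)`, exponential `exp(x log(M)/M)`, so
#' outputs stay on a scale comparable to the input.
#'
#' @param image 3D volume.
#' @param spec a `FilterSpec` from [filterSpec()].
#' @param spacing voxel spacing in mm (needed for `log_sigma`).
#' @return the filtered volume (same dimensions).
#' @export
applyFilter <- function(image, spec, spacing = c(1, 1, 1)) {
  ensure3d(image, "image")
  if (!inherits(spec, "FilterSpec")) stop("spec must come from filterSpec()")
  switch(spec$family,
    original = image,
    log_sigma = {
      ks <- lapply(1:3, function(ax) logKernels(spec$sigma / spacing[ax]))
      out <- array(0, dim(image))
      for (ax in 1:3) {
        tmp <- image
        for (ax2 in 1:3) {
          k <- if (ax2 == ax) ks[[ax2]]$d2 else ks[[ax2]]$g
          tmp <- conv1dAxis(tmp, k, ax2)
        }
        out <- out + tmp
      }
      out
    },
    wavelet = {
      letters3 <- strsplit(spec$subband, "")[[1]]
      out <- image
      for (ax in 1:3) {
        k <- if (letters3[ax] == "L") coif1Lo() else coif1Hi()
        out <- conv1dAxis(out, k, ax)
      }
      out
    },
    {
      M <- max(abs(image))
      if (M == 0) return(array(0, dim(image)))
      switch(spec$family,
        square = image^2 / M,
        square_root = sign(image) * sqrt(M * abs(image)),
        logarithm = sign(image) * (M / log(M + 1)) * log(abs(image) + 1),
        exponential = exp(image * log(M) / M))
    })
}
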