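# Feature definitions: first-order statistics on raw intensities plus the
# standard per-family texture feature sets computed from the gray-level
# matrices. Formulas follow the IBSI reference formulary (the formulary the
# mainstream radiomics toolkits implement); logarithms are base 2. Degenerate
# inputs (single gray level, single voxel) fall back to the documented
# constants noted inline instead of propagating NaN.

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' First-order features
#'
#' Eighteen intensity statistics. Moments are computed on the raw in-mask
#' intensities; entropy and uniformity on the discretized histogram.
#' Variance is the population (biased) form; a single-voxel region yields
#' variance 0 and skewness/kurtosis fall back to 0.
#'
#' @param values numeric vector of in-mask intensities.
#' @param levels integer vector of discretized levels for the same voxels.
#' @param voxelVolume physical voxel volume (mm^3) for TotalEnergy.
#' @return named numeric vector of 18 features.
#' @export
firstOrderFeatures <- function(values, levels, voxelVolume = 1) {
  n <- length(values)
  mu <- mean(values)
  v <- mean((values - mu)^2)
  s <- sqrt(v)
  p <- tabulate(levels) / n
  qs <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  core <- values[values >= qs[1] & values <= qs[4]]
  c(Mean = mu,
    Median = median(values),
    Minimum = min(values),
    Maximum = max(values),
    Range = max(values) - min(values),
    Variance = v,
    Skewness = if (s > 0) mean((values - mu)^3) / s^3 else 0,
    Kurtosis = if (s > 0) mean((values - mu)^4) / s^4 else 0,
    Energy = sum(values^2),
    TotalEnergy = voxelVolume * sum(values^2),
    Entropy = -sum(xlog2(p)),
    Uniformity = sum(p^2),
    RootMeanSquared = sqrt(mean(values^2)),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(core - mean(core))),
    Percentile10 = qs[1],
    Percentile90 = qs[4],
    InterquartileRange = qs[3] - qs[2])
}

glcmFeaturesOne <- function(cnt) {
  tot <- sum(cnt)
  if (tot == 0) return(NULL)
  P <- cnt / tot
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  # diagonal and cross-diagonal distributions
  kdiff <- 0:(Ng - 1)
  pxmy <- vapply(kdiff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * Ng)
  pxpy <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))
  HX <- -sum(xlog2(px)); HY <- -sum(xlog2(py))
  HXY <- -sum(xlog2(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(ifelse(pxy > 0, P * log2(pxy), 0))
  HXY2 <- -sum(xlog2(pxy))
  da <- sum(kdiff * pxmy)
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    # perfectly uniform region: correlation defaults to 1
    Correlation = if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(pxmy)),
    DifferenceVariance = sum((kdiff - da)^2 * pxmy),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    Imc2 = if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0,
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / Ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(P),
    SumAverage = sum(ksum * pxpy),
    SumEntropy = -sum(xlog2(pxpy)),
    SumSquares = sum((i - mux)^2 * P))
}

# shared run-length / size-zone style features; `what` names the j axis
rlmStyleFeatures <- function(cnt, nVoxels, prefixSmall, prefixLarge, what) {
  Ns <- sum(cnt)
  ri <- rowSums(cnt); rj <- colSums(cnt)
  p <- cnt / Ns
  i <- row(p); j <- col(p)
  mui <- sum(i * p); muj <- sum(j * p)
  f <- c(sum(cnt / col(cnt)^2) / Ns,
         sum(cnt * col(cnt)^2) / Ns,
         sum(ri^2) / Ns,
         sum(ri^2) / Ns^2,
         sum(rj^2) / Ns,
         sum(rj^2) / Ns^2,
         Ns / nVoxels,
         sum((i - mui)^2 * p),
         sum((j - muj)^2 * p),
         -sum(xlog2(p)),
         sum(cnt / row(cnt)^2) / Ns,
         sum(cnt * row(cnt)^2) / Ns,
         sum(cnt / (row(cnt)^2 * col(cnt)^2)) / Ns,
         sum(cnt * row(cnt)^2 / col(cnt)^2) / Ns,
         sum(cnt * col(cnt)^2 / row(cnt)^2) / Ns,
         sum(cnt * row(cnt)^2 * col(cnt)^2) / Ns)
  names(f) <- c(paste0(prefixSmall, "Emphasis"),
                paste0(prefixLarge, "Emphasis"),
                "GrayLevelNonUniformity",
                "GrayLevelNonUniformityNormalized",
                paste0(what, "NonUniformity"),
                paste0(what, "NonUniformityNormalized"),
                paste0(what, "Percentage"),
                "GrayLevelVariance",
                paste0(what, "Variance"),
                paste0(what, "Entropy"),
                "LowGrayLevelEmphasis",
                "HighGrayLevelEmphasis",
                paste0(prefixSmall, "LowGrayLevelEmphasis"),
                paste0(prefixSmall, "HighGrayLevelEmphasis"),
                paste0(prefixLarge, "LowGrayLevelEmphasis"),
                paste0(prefixLarge, "HighGrayLevelEmphasis"))
  f
}

glrlmFeaturesOne <- function(cnt, nVoxels) {
  rlmStyleFeatures(cnt, nVoxels, "ShortRun", "LongRun", "Run")
}

#' Texture features from a matrix family
#'
#' Computes the standard feature set of one family. For GLCM and GLRLM the
#' input is the list of 13 per-direction matrices; with
#' `aggregation = "average"` features are computed per direction and
#' averaged, with `"merge"` the matrices are summed first.
#'
#' @param matrices output of the corresponding builder
#'   ([glcmMatrices()], [glrlmMatrices()], [glszmMatrix()], [gldmMatrix()],
#'   [ngtdmTable()]).
#' @param family one of `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @param nVoxels in-mask voxel count (needed by the run/zone families).
#' @param aggregation direction handling for GLCM/GLRLM.
#' @return named numeric feature vector; every value finite.
#' @export
textureFeatures <- function(matrices, family = c("glcm", "glrlm", "glszm",
                                                 "gldm", "ngtdm"),
                            nVoxels = NULL,
                            aggregation = c("average", "merge")) {
  family <- match.arg(family)
  aggregation <- match.arg(aggregation)
  if (family %in% c("glcm", "glrlm")) {
    fOne <- if (family == "glcm") {
      glcmFeaturesOne
    } else {
      function(m) glrlmFeaturesOne(m, nVoxels)
    }
    if (aggregation == "merge") {
      maxc <- max(vapply(matrices, ncol, integer(1)))
      merged <- Reduce(`+`, lapply(matrices, function(m) {
        cbind(m, matrix(0, nrow(m), maxc - ncol(m)))
      }))
      return(fOne(merged))
    }
    per <- lapply(matrices, fOne)
    per <- per[!vapply(per, is.null, logical(1))]
    # single-voxel region: no co-occurring pairs in any direction; fall back
    # to the degenerate single-cell matrix
    if (!length(per)) per <- list(fOne(matrix(1, 1, 1)))
    return(rowMeans(do.call(cbind, per)))
  }
  if (family == "glszm")
    return(rlmStyleFeatures(matrices, nVoxels, "SmallArea", "LargeArea", "Zone"))
  if (family == "gldm") {
    f <- rlmStyleFeatures(matrices, nVoxels, "SmallDependence",
                          "LargeDependence", "Dependence")
    # dependence counts partition the voxels: percentage is always 1, drop it
    f[setdiff(names(f), "DependencePercentage")]
  } else {
    ngtdmFeatures(matrices)
  }
}

ngtdmFeatures <- function(tab) {
  Nvc <- sum(tab$n)
  # a region of mutually isolated voxels has no valid neighbourhoods
  if (Nvc == 0)
    return(c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  p <- tab$n / Nvc
  s <- tab$s
  act <- p > 0
  ia <- tab$level[act]; pa <- p[act]; sa <- s[act]
  Ngp <- sum(act)
  dP <- outer(pa, pa, function(a, b) a + b)
  dI <- abs(outer(ia, ia, "-"))
  coarsenessDen <- sum(pa * sa)
  contrast <- if (Ngp > 1) {
    (sum(outer(pa, pa) * dI^2) / (Ngp * (Ngp - 1))) * (sum(sa) / Nvc)
  } else 0
  busynessDen <- sum(abs(outer(ia * pa, ia * pa, "-")))
  complexity <- sum(dI * (outer(pa * sa, pa * sa, "+")) / dP) / Nvc
  strength <- if (sum(sa) > 0) sum(dP * dI^2) / sum(sa) else 0
  c(Coarseness = if (coarsenessDen > 0) 1 / coarsenessDen else 1e6,
    Contrast = contrast,
    Busyness = if (busynessDen > 0) coarsenessDen / busynessDen else 0,
    Complexity = complexity,
    Strength = strength)
}
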