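#' Optimisation direction of each validity index
#'
#' Which extremum over c marks the best partition: `"min"` for the
#' Rezaee-Lelieveldt-Reider and Kim-Park indices, `"max"` for the other six.
#'
#' @return named character vector over the eight index names.
#' @export
cvDirections <- function() {
  c(cv_rlr = "min", cv_zle = "max", cv_gv = "max", cv_kp = "min",
    cv_pbm = "max", cv_wy = "max", cv_bws = "max", cv_new = "max")
}

.degenerate <- function(...) any(!vapply(list(...), function(x)
  length(x) == 1 && is.finite(x), logical(1)))

# Redundant (coincident) centroids: surplus clusters beyond the structure the
# data supports collapse onto each other, leaving Vdmin at the level of the
# convergence residual. Any index that divides by Vdmin would then be pure
# numerical noise, so such partitions are flagged degenerate and can never be
# selected. The test is relative to the data's own length scale.
.redundantCentroids <- function(measures, redundancyTol) {
  !is.finite(measures@Vdmin) ||
    measures@Vdmin < redundancyTol * measures@dataScale
}

#' Rezaee-Lelieveldt-Reider index
#'
#' CV_RLR = sum_j sigma_{1,j} / (c ||sigma_X||) +
#' (1/alpha) (Vdmax * SS / Vdmin); minimised at the best partition. The
#' weighting constant alpha is fixed to the value of Vdmax * SS / Vdmin at
#' the largest swept c, so the second term equals 1 there.
#'
#' @param measures a [MeasureSet-class].
#' @param alpha numeric(1), the normalisation constant (> 0).
#' @param redundancyTol numeric(1); a partition whose smallest
#'   between-centroid distance falls below `redundancyTol` times the data's
#'   length scale has redundant (coincident) centroids and is flagged
#'   degenerate. Default 1e-3.
#' @return numeric(1); `NA` when degenerate (coincident centroids).
#' @export
cvRLR <- function(measures, alpha, redundancyTol = 1e-3) {
  if (.degenerate(measures@SS, measures@Vdmin) ||
      .redundantCentroids(measures, redundancyTol) ||
      !is.finite(alpha) || alpha <= 0)
    return(NA_real_)
  sum(measures@sigma1) / (measures@c * measures@sigmaXNorm) +
    (1 / alpha) * (measures@Vdmax * measures@SS / measures@Vdmin)
}

#' Zahid-Limouri-Essaid index
#'
#' CV_ZLE = alpha * (S / pi_m1) - FS / FC; maximised at the best partition.
#' The ratio S / pi_m1 is the Pal-Bezdek validity ratio; alpha is fixed to
#' the fuzzy overlap FS / FC at the largest swept c so the two subtracted
#' quantities live on the same scale.
#'
#' @inheritParams cvRLR
#' @return numeric(1); `NA` when degenerate.
#' @export
cvZLE <- function(measures, alpha) {
  if (.degenerate(measures@S, measures@piM1, measures@FS, measures@FC) ||
      measures@piM1 <= 0 || measures@FC <= 0 || !is.finite(alpha))
    return(NA_real_)
  alpha * (measures@S / measures@piM1) - measures@FS / measures@FC
}

#' Geva invariant index
#'
#' CV_GV = K_1 / (c^2 J_1), the ratio of between-cluster to within-cluster
#' scatter, normalised by c^2 to remove the monotone growth with c;
#' maximised at the best partition.
#'
#' @inheritParams cvRLR
#' @return numeric(1); `NA` when degenerate (zero within-cluster scatter).
#' @export
cvGV <- function(measures) {
  if (.degenerate(measures@K1, measures@J1) || measures@J1 <= 0)
    return(NA_real_)
  measures@K1 / (measures@c^2 * measures@J1)
}

#' Kim-Park index
#'
#' CV_KP = pi_11 / c + (1/alpha) (c / Vdmin); minimised at the best
#' partition. pi_11 here is the exponent-1 compactness sum_j sigma_{1,j} /
#' n_{1,j}. alpha is fixed to c / Vdmin at the largest swept c, mirroring
#' the normalisation the Rezaee-Lelieveldt-Reider index uses.
#'
#' @inheritParams cvRLR
#' @return numeric(1); `NA` when degenerate.
#' @export
cvKP <- function(measures, alpha, redundancyTol = 1e-3) {
  if (.degenerate(measures@Vdmin) ||
      .redundantCentroids(measures, redundancyTol) ||
      !is.finite(alpha) || alpha <= 0)
    return(NA_real_)
  pi11 <- sum(measures@sigma1 / measures@n1)
  pi11 / measures@c + (1 / alpha) * (measures@c / measures@Vdmin)
}

#' Pakhira-Bandyopadhyay-Maulik index
#'
#' CV_PBM = (alpha / c) (Vdmax / J_m) with alpha = n; maximised at the best
#' partition.
#'
#' @inheritParams cvRLR
#' @param n numeric(1), number of voxels (the constant alpha).
#' @return numeric(1); `NA` when degenerate.
#' @export
cvPBM <- function(measures, n = measures@n) {
  if (.degenerate(measures@Vdmax, measures@Jm) || measures@Jm <= 0)
    return(NA_real_)
  (n / measures@c) * (measures@Vdmax / measures@Jm)
}

#' Wu-Yang index
#'
#' CV_WY = sum_j (n_{1,j} / max_j n_{1,j} - exp(-Vdmin_j^2 / S)); maximised
#' at the best partition and bounded by (-c, c): each summand compares the
#' relative fuzzy cardinality of a cluster with its exponential separation
#' from the nearest other centroid.
#'
#' @inheritParams cvRLR
#' @return numeric(1); `NA` when degenerate (S = 0).
#' @export
cvWY <- function(measures) {
  if (.degenerate(measures@S) || measures@S <= 0)
    return(NA_real_)
  sum(measures@n1 / max(measures@n1) -
        exp(-measures@VdminPerCluster^2 / measures@S))
}

#' Bouguessa-Wang-Sun index
#'
#' CV_BWS = K_m / pi_mm, fuzzy separation over fuzzy compactness; maximised
#' at the best partition.
#'
#' @inheritParams cvRLR
#' @return numeric(1); `NA` when degenerate.
#' @export
cvBWS <- function(measures) {
  if (.degenerate(measures@Km, measures@piMM) || measures@piMM <= 0)
    return(NA_real_)
  measures@Km / measures@piMM
}

#' Compactness-separation product index
#'
#' CV_new = K_m * (ID_inter / ID_intra) * (FC / J_1); maximised at the best
#' partition. It combines the measures that behave differently on
#' structureless and single-cluster data (K_m, ID_intra, ID_inter, J_1) with
#' the fuzzy compactness FC, which makes it robust on noisy data with many
#' clusters.
#'
#' @inheritParams cvRLR
#' @return numeric(1); `NA` when degenerate.
#' @export
cvNew <- function(measures) {
  if (.degenerate(measures@Km, measures@IDintra, measures@IDinter,
                  measures@FC, measures@J1) ||
      measures@IDintra <= 0 || measures@J1 <= 0)
    return(NA_real_)
  measures@Km * (measures@IDinter / measures@IDintra) *
    (measures@FC / measures@J1)
}

#' Evaluate all eight validity indices on one MeasureSet
#'
#' @param measures a [MeasureSet-class].
#' @param alphas named numeric with `cv_rlr`, `cv_zle`, `cv_kp` (the
#'   constants fixed at the largest swept c) and `cv_pbm` (= n).
#' @param redundancyTol numeric(1); a partition with redundant (coincident)
#'   centroids is not a genuine c-cluster solution — it is a smaller
#'   partition in disguise — so the whole panel is flagged degenerate
#'   (`NA`, worst possible rank) when the smallest between-centroid
#'   distance falls below `redundancyTol` times the data scale.
#' @return named numeric(8); degenerate configurations yield `NA`.
#' @export
computeIndexPanel <- function(measures, alphas, redundancyTol = 1e-3) {
  if (.redundantCentroids(measures, redundancyTol)) {
    out <- rep(NA_real_, 8)
    names(out) <- names(cvDirections())
    return(out)
  }
  c(cv_rlr = cvRLR(measures, alphas[["cv_rlr"]], redundancyTol),
    cv_zle = cvZLE(measures, alphas[["cv_zle"]]),
    cv_gv = cvGV(measures),
    cv_kp = cvKP(measures, alphas[["cv_kp"]], redundancyTol),
    cv_pbm = cvPBM(measures, alphas[["cv_pbm"]]),
    cv_wy = cvWY(measures),
    cv_bws = cvBWS(measures),
    cv_new = cvNew(measures))
}

#' Alpha constants fixed at the top of the sweep
#'
#' The Rezaee-Lelieveldt-Reider, Zahid-Limouri-Essaid and Kim-Park indices
#' need a normalisation constant taken from the partition at the largest
#' swept c; the Pakhira-Bandyopadhyay-Maulik constant is simply n.
#'
#' @param measuresAtCmax the [MeasureSet-class] of the c = cMax partition.
#' @return named numeric(4).
#' @export
alphaAtCmax <- function(measuresAtCmax) {
  ms <- measuresAtCmax
  rlr <- if (is.finite(ms@SS) && is.finite(ms@Vdmin) && ms@Vdmin > 0)
    ms@Vdmax / ms@Vdmin * ms@SS else NA_real_
  kp <- if (is.finite(ms@Vdmin) && ms@Vdmin > 0)
    ms@c / ms@Vdmin else NA_real_
  c(cv_rlr = rlr, cv_zle = ms@FO, cv_kp = kp, cv_pbm = ms@n)
}

#' Select the optimal number of clusters for one index
#'
#' Applies the index's optimisation direction over the swept c values:
#' argmin for `cv_rlr` and `cv_kp`, argmax for the rest. Degenerate (`NA`)
#' values are excluded — a partition with redundant coincident centroids can
#' never win — and ties break toward the smaller c (parsimony).
#'
#' @param values numeric, index value per c.
#' @param cs integer, the c value each entry belongs to (same length,
#'   increasing).
#' @param index one of the eight index names (decides the direction).
#' @return integer(1), the selected number of clusters.
#' @export
selectCOpt <- function(values, cs, index) {
  dir <- cvDirections()[[match.arg(index, names(cvDirections()))]]
  ok <- is.finite(values)
  if (!any(ok)) stop("all index values are degenerate; no selection possible")
  v <- values[ok]; cc <- cs[ok]
  pick <- if (dir == "min") which.min(v) else which.max(v)
  as.integer(cc[pick])
}
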