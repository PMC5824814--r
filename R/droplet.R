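#' Fit a Poisson loading model to a droplet occupancy histogram
#'
#' The mean occupancy is estimated by its maximum-likelihood estimator
#' (the sample mean of the histogram) and the fit is assessed by a
#' chi-square goodness-of-fit test against Poisson(lambda_hat): bins are
#' pooled from the upper tail until every expected count is at least 5,
#' and one degree of freedom is subtracted for the estimated mean.
#'
#' @param hist numeric vector of droplet counts named by occupancy
#'   ("0", "1", ...). Total droplets must be >= 100.
#' @return An \code{\linkS4class{OccupancySummary}}. When all mass sits
#'   at occupancy 0 (or too few bins survive pooling) the fit is flagged
#'   degenerate and the GOF fields are NA.
#' @export
occupancyFit <- function(hist) {
  if (is.null(names(hist))) stop("histogram must be named by occupancy")
  k <- as.numeric(names(hist))
  if (anyNA(k) || any(k < 0) || any(k != round(k))) {
    stop("histogram names must be nonnegative integer occupancies")
  }
  if (any(hist < 0)) stop("histogram counts must be >= 0")
  n <- sum(hist)
  if (n < 100) stop("at least 100 droplets required; got ", n)
  lambda <- sum(k * hist) / n
  if (lambda == 0) {
    return(methods::new("OccupancySummary", histogram = hist, lambda_hat = 0,
                        gof_stat = NA_real_, gof_df = NA_real_, gof_p = NA_real_,
                        degenerate = TRUE))
  }
  # bins extend past the observed maximum while the fitted model still
  # expects appreciable mass there (zero observed counts are evidence too)
  kmax <- max(max(k), qpois(1 - 2.5 / n, lambda))
  obs <- stats::setNames(numeric(kmax + 1L), as.character(0:kmax))
  obs[names(hist)] <- hist
  expd <- n * dpois(0:kmax, lambda)
  expd[kmax + 1L] <- expd[kmax + 1L] + n * (1 - ppois(kmax, lambda))  # open tail
  # pool from the top until every expected count >= 5
  while (length(expd) > 2L && expd[length(expd)] < 5) {
    m <- length(expd)
    expd[m - 1L] <- expd[m - 1L] + expd[m]
    obs[m - 1L] <- obs[m - 1L] + obs[m]
    expd <- expd[-m]; obs <- obs[-m]
  }
  df <- length(expd) - 1L - 1L
  if (df < 1L || any(expd < 5)) {
    return(methods::new("OccupancySummary", histogram = hist, lambda_hat = lambda,
                        gof_stat = NA_real_, gof_df = NA_real_, gof_p = NA_real_,
                        degenerate = TRUE))
  }
  stat <- sum((obs - expd)^2 / expd)
  methods::new("OccupancySummary", histogram = hist, lambda_hat = lambda,
               gof_stat = stat, gof_df = as.numeric(df),
               gof_p = pchisq(stat, df, lower.tail = FALSE), degenerate = FALSE)
}

#' Expected droplet occupancy and multiplet rate for a loading concentration
#'
#' Under Poisson loading the mean occupancy is concentration times
#' droplet volume, and among occupied droplets the multiplet fraction is
#' \code{1 - lambda * exp(-lambda) / (1 - exp(-lambda))}.
#'
#' @param concentration cell concentration in cells/uL.
#' @param droplet_volume_nl droplet volume in nanolitres (default 1).
#' @return list with \code{lambda} and \code{multiplet_fraction} (the
#'   multiplet fraction among occupied droplets; 0 in the lambda -> 0
#'   limit).
#' @export
expectedCollision <- function(concentration, droplet_volume_nl = 1) {
  if (concentration < 0 || droplet_volume_nl <= 0) {
    stop("concentration must be >= 0 and droplet volume > 0")
  }
  lambda <- concentration * droplet_volume_nl * 1e-3   # cells/uL * nL, 1 nL = 1e-3 uL
  mult <- if (lambda == 0) 0 else 1 - lambda * exp(-lambda) / (1 - exp(-lambda))
  list(lambda = lambda, multiplet_fraction = mult)
}

#' Call barcode species from a two-species mixed run
#'
#' Classifies each barcode of a barnyard matrix as human, mouse or mixed
#' from its per-species UMI totals: human when the human fraction is at
#' least \code{purity_threshold}, mouse when at most
#' \code{1 - purity_threshold}, mixed in between. Barcodes below
#' \code{min_umi} total UMIs are excluded. The observed mixed fraction
#' underestimates the total collision rate because same-species
#' collisions are invisible; the inferred total rate divides by
#' \code{2 p q} (2 at an equal mix).
#'
#' @param x UMI matrix (or SingleCellExperiment) whose gene rows carry
#'   species prefixes.
#' @param purity_threshold fraction above which a barcode is called pure
#'   (default 0.9).
#' @param min_umi minimum total UMIs to call a barcode (default 500).
#' @param mix_fraction assumed human fraction among loaded cells used for
#'   the collision correction (default 0.5, an equal mix).
#' @param human_prefix,mouse_prefix gene-name prefixes (defaults
#'   \code{"hg_"}, \code{"mm_"}).
#' @return A \code{\linkS4class{SpeciesCalls}}.
#' @export
speciesMixing <- function(x, purity_threshold = 0.9, min_umi = 500,
                          mix_fraction = 0.5, human_prefix = "hg_",
                          mouse_prefix = "mm_") {
  counts <- getCounts(x)
  hg <- startsWith(rownames(counts), human_prefix)
  mm <- startsWith(rownames(counts), mouse_prefix)
  if (!any(hg) || !any(mm)) {
    stop("no species prefixes found: expected gene rows starting with '",
         human_prefix, "' and '", mouse_prefix, "'")
  }
  h <- Matrix::colSums(counts[hg, , drop = FALSE])
  m <- Matrix::colSums(counts[mm, , drop = FALSE])
  keep <- (h + m) >= min_umi
  if (!any(keep)) stop("no barcodes at or above ", min_umi, " UMIs")
  h <- h[keep]; m <- m[keep]
  frac <- h / (h + m)
  call <- ifelse(frac >= purity_threshold, "human",
                 ifelse(frac <= 1 - purity_threshold, "mouse", "mixed"))
  mixed_fraction <- mean(call == "mixed")
  p <- mix_fraction
  collision <- if (p <= 0 || p >= 1) NA_real_ else mixed_fraction / (2 * p * (1 - p))
  methods::new("SpeciesCalls",
               calls = data.frame(barcode = names(frac), human_umi = as.numeric(h),
                                  mouse_umi = as.numeric(m),
                                  human_fraction = as.numeric(frac), call = call,
                                  row.names = NULL, stringsAsFactors = FALSE),
               mixed_fraction = mixed_fraction, collision_rate = collision,
               purity_threshold = purity_threshold, min_umi = min_umi,
               mix_fraction = mix_fraction)
}

#' ERCC spike-in sensitivity and accuracy
#'
#' After discarding barcodes with fewer than \code{min_umi} total ERCC
#' UMIs, reports per-barcode sensitivity (total detected molecules) and
#' accuracy (Pearson correlation between log1p detected counts and log
#' expected molecules across all reference species, zeros included),
#' plus cohort mean and standard deviation of each.
#'
#' @param x UMI matrix of ERCC rows (or SingleCellExperiment); row names
#'   must all be reference identifiers.
#' @param ref an \code{\linkS4class{ErccReference}}.
#' @param min_umi barcode UMI floor (default 100).
#' @return An \code{\linkS4class{ErccMetrics}}.
#' @export
erccMetrics <- function(x, ref, min_umi = 100) {
  counts <- getCounts(x)
  unknown <- setdiff(rownames(counts), erccIds(ref))
  if (length(unknown)) {
    stop("matrix rows absent from the reference: ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  expected <- expectedMolecules(ref)
  # align detected counts over ALL reference species, zeros included
  full <- matrix(0, length(expected), ncol(counts),
                 dimnames = list(names(expected), colnames(counts)))
  full[rownames(counts), ] <- as.matrix(counts)
  totals <- colSums(full)
  keep <- totals >= min_umi
  if (!any(keep)) stop("no barcodes with at least ", min_umi, " ERCC UMIs")
  full <- full[, keep, drop = FALSE]
  lexp <- log(expected)
  acc <- apply(full, 2L, function(col) {
    d <- log1p(col)
    if (sd(d) == 0) NA_real_ else cor(d, lexp)
  })
  per <- data.frame(barcode = colnames(full), sensitivity = unname(totals[keep]),
                    accuracy_r = unname(acc), row.names = NULL,
                    stringsAsFactors = FALSE)
  methods::new("ErccMetrics", per_barcode = per,
               mean_sensitivity = mean(per$sensitivity),
               sd_sensitivity = if (nrow(per) > 1L) sd(per$sensitivity) else NA_real_,
               mean_accuracy = mean(per$accuracy_r, na.rm = TRUE),
               sd_accuracy = if (nrow(per) > 1L) sd(per$accuracy_r, na.rm = TRUE) else NA_real_,
               min_umi = min_umi, n_filtered = as.integer(sum(!keep)))
}
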