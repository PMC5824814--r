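#' ERCC spike-in reference
#'
#' Holds the known input concentration of each ERCC species (attomoles per
#' microlitre of the loaded mix) together with the expected number of
#' molecules per droplet implied by the droplet volume and any dilution of
#' the stock mix. Expected molecules are
#' \code{concentration * 602214.076 * volume_nl * 1e-3 / dilution}
#' (602214.076 molecules per attomole).
#'
#' @slot ids character, unique ERCC identifiers.
#' @slot concentration numeric, attomoles/uL in the loaded mix, all > 0.
#' @slot expected_molecules numeric, expected molecules per droplet.
#' @slot volume_nl numeric(1), droplet volume in nanolitres used.
#' @slot dilution numeric(1), fold dilution of the stock mix (>= 1 typical).
#'
#' @aliases ErccReference
#' @exportClass ErccReference
setClass("ErccReference",
  representation(ids = "character", concentration = "numeric",
                 expected_molecules = "numeric", volume_nl = "numeric",
                 dilution = "numeric"))

setValidity("ErccReference", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "ERCC identifiers must be unique")
  if (length(object@concentration) != length(object@ids))
    msg <- c(msg, "concentration length mismatch")
  if (any(!is.finite(object@concentration)) || any(object@concentration <= 0))
    msg <- c(msg, "concentrations must be positive and finite")
  if (length(object@volume_nl) != 1L || object@volume_nl <= 0)
    msg <- c(msg, "volume_nl must be a single positive number")
  if (length(object@dilution) != 1L || object@dilution <= 0)
    msg <- c(msg, "dilution must be a single positive number")
  expect <- object@concentration * 602214.076 * object@volume_nl * 1e-3 /
    object@dilution
  if (length(object@expected_molecules) != length(object@ids) ||
      any(abs(object@expected_molecules - expect) >
          1e-8 * pmax(1, abs(expect))))
    msg <- c(msg, "expected_molecules inconsistent with concentration and volume")
  if (length(msg)) msg else TRUE
})

#' @describeIn ErccReference identifiers of the reference species.
#' @param object,x an \code{ErccReference}.
#' @export
erccIds <- function(object) object@ids

#' @describeIn ErccReference expected molecules per droplet, named by id.
#' @export
expectedMolecules <- function(object) {
  stats::setNames(object@expected_molecules, object@ids)
}

#' @describeIn ErccReference input concentrations (attomoles/uL), named by id.
#' @export
erccConcentration <- function(object) {
  stats::setNames(object@concentration, object@ids)
}

setMethod("show", "ErccReference", function(object) {
  cat("ErccReference with", length(object@ids), "species\n",
      " droplet volume:", object@volume_nl, "nL; dilution:", object@dilution,
      "\n expected molecules/droplet: ",
      sprintf("%.3g - %.3g", min(object@expected_molecules),
              max(object@expected_molecules)), "\n")
})

#' Droplet occupancy summary
#'
#' Result of fitting a Poisson loading model to a droplet occupancy
#' histogram: the maximum-likelihood mean occupancy (the sample mean) and a
#' chi-square goodness-of-fit test against Poisson(lambda_hat) with tail
#' bins pooled to expected counts >= 5 and one degree of freedom spent on
#' the estimated mean.
#'
#' @slot histogram numeric, droplet counts named by occupancy (0, 1, 2, ...).
#' @slot lambda_hat numeric(1), estimated mean occupancy.
#' @slot gof_stat,gof_df,gof_p numeric(1), chi-square statistic, degrees of
#'   freedom and p-value (NA when the fit is degenerate).
#' @slot degenerate logical(1), TRUE when all mass is at occupancy 0 or too
#'   few bins remain for a test.
#'
#' @aliases OccupancySummary
#' @exportClass OccupancySummary
setClass("OccupancySummary",
  representation(histogram = "numeric", lambda_hat = "numeric",
                 gof_stat = "numeric", gof_df = "numeric", gof_p = "numeric",
                 degenerate = "logical"))

setValidity("OccupancySummary", function(object) {
  msg <- character()
  if (any(object@histogram < 0)) msg <- c(msg, "histogram counts must be >= 0")
  if (is.null(names(object@histogram))) msg <- c(msg, "histogram must be named by occupancy")
  if (length(object@lambda_hat) != 1L || object@lambda_hat < 0)
    msg <- c(msg, "lambda_hat must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' @describeIn OccupancySummary estimated mean occupancy (Poisson MLE).
#' @param object an \code{OccupancySummary}.
#' @export
occupancyLambda <- function(object) object@lambda_hat

#' @describeIn OccupancySummary the occupancy histogram.
#' @export
occupancyHistogram <- function(object) object@histogram

#' @describeIn OccupancySummary goodness-of-fit p-value vs Poisson.
#' @export
gofPvalue <- function(object) object@gof_p

setMethod("show", "OccupancySummary", function(object) {
  cat("OccupancySummary:", sum(object@histogram), "droplets, lambda_hat =",
      signif(object@lambda_hat, 4), "\n")
  if (object@degenerate) {
    cat("  goodness-of-fit: degenerate (not tested)\n")
  } else {
    cat(sprintf("  chi-square GOF: X2 = %.3f, df = %d, p = %.3g\n",
                object@gof_stat, as.integer(object@gof_df), object@gof_p))
  }
})

#' Species-mixing (barnyard) calls
#'
#' Per-barcode species assignment from a two-species mixed run, plus the
#' observed cross-species ("mixed") fraction and the inferred total
#' collision rate. With human fraction p and mouse fraction q = 1 - p among
#' loaded cells, only a fraction 2pq of multi-cell droplets is visible as
#' cross-species, so the total collision rate is estimated as
#' mixed_fraction / (2pq) (the familiar doubling at an equal mix).
#'
#' @slot calls data.frame with columns barcode, human_umi, mouse_umi,
#'   human_fraction, call (human/mouse/mixed).
#' @slot mixed_fraction numeric(1), fraction of retained barcodes called mixed.
#' @slot collision_rate numeric(1), inferred total collision rate.
#' @slot purity_threshold,min_umi,mix_fraction numeric(1), parameters used.
#'
#' @aliases SpeciesCalls
#' @exportClass SpeciesCalls
setClass("SpeciesCalls",
  representation(calls = "data.frame", mixed_fraction = "numeric",
                 collision_rate = "numeric", purity_threshold = "numeric",
                 min_umi = "numeric", mix_fraction = "numeric"))

setValidity("SpeciesCalls", function(object) {
  msg <- character()
  need <- c("barcode", "human_umi", "mouse_umi", "human_fraction", "call")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, "calls must have barcode, human_umi, mouse_umi, human_fraction, call")
  else {
    hf <- object@calls$human_fraction
    if (any(hf < 0 | hf > 1)) msg <- c(msg, "human_fraction must lie in [0, 1]")
    if (!all(object@calls$call %in% c("human", "mouse", "mixed")))
      msg <- c(msg, "call must be one of human/mouse/mixed")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SpeciesCalls per-barcode call table.
#' @param object a \code{SpeciesCalls}.
#' @export
speciesCallTable <- function(object) object@calls

#' @describeIn SpeciesCalls observed cross-species fraction.
#' @export
mixedFraction <- function(object) object@mixed_fraction

#' @describeIn SpeciesCalls inferred total collision rate.
#' @export
collisionRate <- function(object) object@collision_rate

setMethod("show", "SpeciesCalls", function(object) {
  tab <- table(object@calls$call)
  cat("SpeciesCalls:", nrow(object@calls), "barcodes (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n",
      sprintf("  mixed fraction = %.4f; inferred collision rate = %.4f\n",
              object@mixed_fraction, object@collision_rate))
})

#' ERCC sensitivity and accuracy metrics
#'
#' Per-barcode spike-in metrics: sensitivity is the total number of
#' detected molecules on a barcode, accuracy is the Pearson correlation of
#' log1p(detected counts) with log(expected molecules) across all reference
#' species (zeros included). Barcodes below the UMI floor are discarded
#' before computing either.
#'
#' @slot per_barcode data.frame with columns barcode, sensitivity, accuracy_r.
#' @slot mean_sensitivity,sd_sensitivity,mean_accuracy,sd_accuracy numeric(1).
#' @slot min_umi numeric(1), barcode UMI floor applied.
#' @slot n_filtered integer(1), barcodes removed by the floor.
#'
#' @aliases ErccMetrics
#' @exportClass ErccMetrics
setClass("ErccMetrics",
  representation(per_barcode = "data.frame", mean_sensitivity = "numeric",
                 sd_sensitivity = "numeric", mean_accuracy = "numeric",
                 sd_accuracy = "numeric", min_umi = "numeric",
                 n_filtered = "integer"))

setValidity("ErccMetrics", function(object) {
  msg <- character()
  need <- c("barcode", "sensitivity", "accuracy_r")
  if (!all(need %in% names(object@per_barcode)))
    msg <- c(msg, "per_barcode must have barcode, sensitivity, accuracy_r")
  else {
    if (any(object@per_barcode$sensitivity < object@min_umi))
      msg <- c(msg, "sensitivity below the min_umi floor after filtering")
    r <- object@per_barcode$accuracy_r
    if (any(!is.na(r) & (r < -1 | r > 1)))
      msg <- c(msg, "accuracy_r must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ErccMetrics per-barcode metric table.
#' @param object an \code{ErccMetrics}.
#' @export
erccPerBarcode <- function(object) object@per_barcode

#' @describeIn ErccMetrics mean per-barcode detected molecules.
#' @export
meanSensitivity <- function(object) object@mean_sensitivity

#' @describeIn ErccMetrics mean per-barcode accuracy correlation.
#' @export
meanAccuracy <- function(object) object@mean_accuracy

setMethod("show", "ErccMetrics", function(object) {
  cat("ErccMetrics:", nrow(object@per_barcode), "barcodes (",
      object@n_filtered, "removed below", object@min_umi, "UMIs )\n",
      sprintf("  sensitivity %.1f +/- %.1f molecules; accuracy r %.3f +/- %.3f\n",
              object@mean_sensitivity, object@sd_sensitivity,
              object@mean_accuracy, object@sd_accuracy))
})
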