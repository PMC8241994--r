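## RT-qPCR normalisation (delta-delta-Ct) and first-order mRNA decay fitting
## for actinomycin-D chase experiments.

## Coefficient of determination, safe for perfect and degenerate fits.
.rSquared <- function(obs, fitted) {
  ssRes <- sum((obs - fitted)^2)
  ssTot <- sum((obs - mean(obs))^2)
  if (ssTot == 0) return(if (ssRes == 0) 1 else 0)
  max(0, min(1, 1 - ssRes / ssTot))
}

#' Delta-delta-Ct fold changes
#'
#' Standard relative quantification with amplification efficiency fixed at 2:
#' `dCt = ct_target - ct_reference` (reference playing the cyclophilin-A
#' internal-control role), `ddCt = dCt - dCt(baseline)`, and
#' `fold = 2^(-ddCt)` relative to the baseline sample. When the baseline
#' label matches several rows, their mean dCt is the baseline.
#'
#' @param measurements `data.frame` with columns `sample_label`, `time`,
#'   `ct_target`, `ct_reference`.
#' @param baselineLabel `sample_label` of the unstimulated/t=0 baseline.
#' @return the input with `dCt`, `ddCt` and `fold` columns appended;
#'   the baseline row has `fold == 1` (exactly, up to the mean when
#'   replicated).
#' @examples
#' m <- data.frame(sample_label = c("t0", "t30"), time = c(0, 30),
#'                 ct_target = c(20, 22), ct_reference = c(15, 15))
#' ddCtFoldChange(m, "t0")$fold
#' @export
ddCtFoldChange <- function(measurements, baselineLabel) {
  need <- c("sample_label", "time", "ct_target", "ct_reference")
  if (!all(need %in% colnames(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (!baselineLabel %in% measurements$sample_label)
    stop("baseline sample '", baselineLabel, "' not present")
  ct <- c(measurements$ct_target, measurements$ct_reference)
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  if (any(ct < 5 | ct > 40))
    warning("Ct values outside the typical 5-40 cycle range")
  out <- measurements
  out$dCt <- out$ct_target - out$ct_reference
  base <- mean(out$dCt[out$sample_label == baselineLabel])
  out$ddCt <- out$dCt - base
  out$fold <- 2^(-out$ddCt)
  out
}

#' Fit a first-order decay and report the half-life
#'
#' Least-squares fit of `log(abundance) = -k * t + c`; the half-life is
#' `log(2) / k`. This log-linear fit is exact for noiseless exponential data
#' and is the standard analysis of actinomycin-D chase time courses; a
#' nonlinear least-squares refinement on the natural scale is available with
#' `method = "nls"`. The intercept absorbs any overall abundance scaling, so
#' k and the half-life are scale-invariant.
#'
#' @param curve a [DecayCurve-class], or a `data.frame` with columns `time`
#'   and `abundance`.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return a [HalfLifeFit-class]. When the fitted `k <= 0` (no decay) the
#'   half-life is reported as `Inf` with a warning.
#' @examples
#' fitHalfLife(simulateDecay(30, c(0, 15, 30, 60), 0))
#' @export
fitHalfLife <- function(curve, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (is.data.frame(curve)) {
    if (!all(c("time", "abundance") %in% colnames(curve)))
      stop("curve data.frame must have columns 'time' and 'abundance'")
    curve <- new("DecayCurve", time = as.numeric(curve$time),
                 abundance = as.numeric(curve$abundance))
  }
  methods::validObject(curve)
  t <- curve@time; ab <- curve@abundance
  if (length(t) < 3L) stop("at least 3 time points are required")

  fit <- stats::lm(log(ab) ~ t)
  k <- -unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- .rSquared(log(ab), stats::fitted(fit))

  if (method == "nls" && k > 0) {
    nl <- tryCatch(
      stats::nls(ab ~ exp(c0 - k0 * t),
                 start = list(c0 = intercept, k0 = k)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      k <- unname(stats::coef(nl)["k0"])
      intercept <- unname(stats::coef(nl)["c0"])
      r2 <- .rSquared(ab, stats::fitted(nl))
    }
  }

  if (k <= 0) {
    warning("no decay detected (k <= 0); reporting infinite half-life")
    hl <- Inf
  } else {
    hl <- log(2) / k
  }
  new("HalfLifeFit", decayRate = k, halfLife = hl, intercept = intercept,
      rSquared = r2, nPoints = length(t))
}

#' @describeIn fitHalfLife half-life accessor (minutes).
#' @param x a `HalfLifeFit`.
#' @export
halfLife <- function(x) x@halfLife

#' @describeIn fitHalfLife decay-rate accessor (per minute).
#' @export
decayRate <- function(x) x@decayRate

#' @describeIn fitHalfLife r-squared of the log-linear fit.
#' @export
fitRSquared <- function(x) x@rSquared

setMethod("show", "HalfLifeFit", function(object) {
  cat(sprintf(
    "HalfLifeFit: t1/2 = %.4g min (k = %.4g /min), r^2 = %.4f, n = %d\n",
    object@halfLife, object@decayRate, object@rSquared, object@nPoints))
})

#' Read a decay curve or Ct table from TSV
#'
#' Accepts either a two-column curve (`time`, `abundance`) or a Ct table
#' (`sample_label`, `time`, `ct_target`, `ct_reference`), which is converted
#' to relative abundance via [ddCtFoldChange()] against the earliest time
#' point.
#'
#' @param path TSV file path.
#' @return a [DecayCurve-class].
#' @export
readDecayTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("time", "abundance") %in% colnames(df))) {
    o <- order(df$time)
    return(new("DecayCurve", time = as.numeric(df$time[o]),
               abundance = as.numeric(df$abundance[o])))
  }
  if (all(c("sample_label", "time", "ct_target", "ct_reference")
          %in% colnames(df))) {
    base <- df$sample_label[which.min(df$time)]
    fc <- ddCtFoldChange(df, base)
    agg <- stats::aggregate(fold ~ time, data = fc, FUN = mean)
    o <- order(agg$time)
    return(new("DecayCurve", time = as.numeric(agg$time[o]),
               abundance = as.numeric(agg$fold[o])))
  }
  stop("TSV must provide (time, abundance) or ",
       "(sample_label, time, ct_target, ct_reference)")
}

#' Write a decay curve as TSV
#'
#' @param curve a [DecayCurve-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDecayTsv <- function(curve, path) {
  utils::write.table(
    data.frame(time = curve@time, abundance = curve@abundance),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
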