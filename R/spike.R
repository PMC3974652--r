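#' Spike-in calibration for absolute quantification
#'
#' Fits a least-squares line in (log10 amount, log10 fluorescence) space to
#' a spike-in titration series. The fit must be monotone increasing
#' (fluorescence grows with amount); a non-monotone series is a calibration
#' error. Fluorescence below the fitted value at the lowest spike is below
#' the detection limit and quantified as missing (rendered grey downstream).
#'
#' @param points data.frame with columns `amount_mol` and `fluorescence`
#'   (replicate measurements of the same amount are allowed).
#' @return object of class `spike_calibration`: intercept, slope,
#'   `linear_range` (mol), `detection_floor` (fluorescence units).
#' @export
spikein_calibrate <- function(points) {
  stopifnot(all(c("amount_mol", "fluorescence") %in% names(points)),
            all(points$amount_mol > 0), all(points$fluorescence > 0))
  if (length(unique(points$amount_mol)) < 2) {
    stop("need at least 2 distinct spike amounts")
  }
  med <- tapply(log10(points$fluorescence), points$amount_mol, mean)
  if (any(diff(med[order(as.numeric(names(med)))]) <= 0)) {
    stop("non-monotone spike series: calibration error")
  }
  fit <- stats::lm(log10(fluorescence) ~ log10(amount_mol), data = points)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("non-monotone spike fit: calibration error")
  rng <- range(points$amount_mol)
  floor_fl <- 10^unname(stats::predict(
    fit, data.frame(amount_mol = rng[1])))
  structure(list(intercept = unname(stats::coef(fit)[1]), slope = slope,
                 linear_range = rng, detection_floor = floor_fl,
                 points = points[, c("amount_mol", "fluorescence")]),
            class = "spike_calibration")
}

#' @export
print.spike_calibration <- function(x, ...) {
  cat(sprintf(
    "Spike calibration: log10(F) = %.3f + %.3f log10(mol); linear range %.1e-%.1e mol\n",
    x$intercept, x$slope, x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Quantify fluorescence into molar amounts
#'
#' Inverts a [spikein_calibrate()] fit. Fluorescence below the detection
#' floor yields `NA` with `below_detection = TRUE`; amounts outside the
#' calibrated linear range are flagged.
#'
#' @param calibration a `spike_calibration`.
#' @param fluorescence numeric vector.
#' @return data.frame: fluorescence, amount_mol, below_detection,
#'   in_linear_range.
#' @export
quantify <- function(calibration, fluorescence) {
  stopifnot(inherits(calibration, "spike_calibration"))
  amount <- 10^((log10(fluorescence) - calibration$intercept) /
                  calibration$slope)
  # strict comparison up to floating tolerance so a calibration point's own
  # fluorescence is never flagged below-detection
  below <- fluorescence < calibration$detection_floor * (1 - 1e-9)
  in_range <- !below & amount >= calibration$linear_range[1] &
    amount <= calibration$linear_range[2]
  amount[below] <- NA_real_
  data.frame(fluorescence = fluorescence, amount_mol = amount,
             below_detection = below, in_linear_range = in_range)
}

#' Spike-anchored loess normalization of a miRNA matrix
#'
#' Per-array smooth intensity-dependent correction anchored on spike-in
#' probes: for each array, the log2 ratio of its spike probes to the
#' across-array spike reference is smoothed against spike intensity
#' (lowess; constant extrapolation beyond the spike range; a plain median
#' shift when fewer than 4 spikes are available) and the predicted bias is
#' subtracted from every probe. Matrix shape and `NA` (below-detection)
#' entries are preserved.
#'
#' @param raw numeric matrix, probes x arrays, positive values with
#'   optional NAs.
#' @param spike_probes row names (or indices) of the spike-in probes.
#' @return normalized matrix of the same shape.
#' @export
normalize_mirna_matrix <- function(raw, spike_probes) {
  stopifnot(is.matrix(raw))
  sp <- if (is.character(spike_probes)) match(spike_probes, rownames(raw))
        else as.integer(spike_probes)
  if (any(is.na(sp)) || !length(sp)) stop("missing spikes")
  lg <- log2(raw)
  ref <- rowMeans(lg[sp, , drop = FALSE], na.rm = TRUE)
  out <- lg
  for (j in seq_len(ncol(lg))) {
    x <- lg[sp, j]
    d <- x - ref
    ok <- is.finite(x) & is.finite(d)
    if (sum(ok) < 1) stop("missing spikes in array ", j)
    if (sum(ok) >= 4) {
      fit <- stats::lowess(x[ok], d[ok], f = 1)
      corr <- stats::approx(fit$x, fit$y, xout = lg[, j], rule = 2)$y
    } else {
      corr <- rep(stats::median(d[ok]), nrow(lg))
    }
    out[, j] <- lg[, j] - corr
  }
  res <- 2^out
  dimnames(res) <- dimnames(raw)
  res
}
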