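#' Convert protein mass per volume to molar concentration
#'
#' c (uM) = mass (ng) / (MW (kDa) x volume (uL)); the unit algebra
#' ng / (kDa x uL) = uM holds exactly.
#'
#' @param mass_ng protein mass (ng)
#' @param volume_ul reaction volume (uL)
#' @param mw_kda molecular weight (kDa)
#' @export
mass_to_molar <- function(mass_ng, volume_ul, mw_kda) {
  if (any(c(mass_ng, volume_ul, mw_kda) <= 0))
    stop("mass, volume and molecular weight must all be positive")
  mass_ng / (mw_kda * volume_ul)
}

#' Fraction bound per lane of an EMSA binding series
#'
#' theta = 1 - free/total where total is the zero-protein lane signal; values
#' are clamped to the interval 0..0.999. Lanes at exactly 0 or the clamp bound are
#' flagged for exclusion from the Hill regression.
#'
#' @param series `binding_series` data.frame (columns conc, free; the
#'   zero-protein lane supplies the total signal)
#' @return data.frame conc, theta, usable (logical) for the protein lanes
#' @export
fraction_bound <- function(series) {
  total <- if (!is.null(attr(series, "total"))) attr(series, "total") else {
    z <- series$free[series$conc == 0]
    if (!length(z)) stop("series lacks a zero-protein lane")
    z[1]
  }
  if (total <= 0) stop("total signal must be positive")
  lanes <- series[series$conc > 0, , drop = FALSE]
  theta <- pmin(pmax(1 - lanes$free / total, 0), 0.999)
  data.frame(conc = lanes$conc, theta = theta,
             usable = theta > 0 & theta < 0.999)
}

#' Estimate Kd and Hill coefficient by the Hill transformation
#'
#' Ordinary least squares of log10(theta / (1 - theta)) on log10(c): the
#' slope is the Hill coefficient and Kd = 10^(-intercept/slope). Lanes with
#' theta outside (0, 0.999) are excluded (and reported), never silently
#' dropped.
#'
#' @param theta fraction bound per lane (or the data.frame returned by
#'   [fraction_bound()])
#' @param concentrations protein concentrations (uM), parallel to theta
#' @return list of class `kd_estimate`: kd, hill_n, r_squared, slope,
#'   intercept, n_lanes, excluded (indices)
#' @export
hill_fit <- function(theta, concentrations = NULL) {
  if (is.data.frame(theta)) {
    concentrations <- theta$conc
    theta <- theta$theta
  }
  stopifnot(length(theta) == length(concentrations))
  usable <- theta > 0 & theta < 0.999 & concentrations > 0
  excluded <- which(!usable)
  if (sum(usable) < 3)
    stop("need at least 3 lanes with theta in (0, 1) for the regression")
  x <- log10(concentrations[usable])
  y <- log10(theta[usable] / (1 - theta[usable]))
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) stop("non-binding data: Hill slope is not positive")
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(kd = 10^(-intercept / slope), hill_n = slope,
                 r_squared = r2, slope = slope, intercept = intercept,
                 n_lanes = sum(usable), excluded = excluded),
            class = "kd_estimate")
}

#' Integrate chromatogram peaks within labeled retention-time windows
#'
#' Trace input: trapezoidal integration of the baseline-subtracted intensity
#' within each window, the baseline being the median of the out-of-window
#' trace. Peak-list input: areas whose centers fall in the window are summed.
#'
#' @param chromatogram a `chromatogram` object (with `trace` or `peaks`)
#' @param windows named list, label -> c(rt_lo, rt_hi); non-overlapping
#' @return named numeric vector of areas
#' @export
integrate_peaks <- function(chromatogram, windows) {
  wm <- do.call(rbind, windows)
  if (nrow(wm) > 1) {
    o <- order(wm[, 1])
    if (any(wm[o, 2][-nrow(wm)] > wm[o, 1][-1]))
      stop("windows must be non-overlapping")
  }
  if (!is.null(chromatogram$peaks)) {
    pk <- chromatogram$peaks
    return(vapply(windows, function(w)
      sum(pk$area[pk$rt >= w[1] & pk$rt <= w[2]]), numeric(1)))
  }
  tr <- chromatogram$trace
  inside_any <- rep(FALSE, nrow(tr))
  for (w in windows) inside_any <- inside_any | (tr$rt >= w[1] & tr$rt <= w[2])
  baseline <- median(tr$intensity[!inside_any])
  vapply(windows, function(w) {
    sel <- tr$rt >= w[1] & tr$rt <= w[2]
    if (sum(sel) < 2) {
      warning("empty integration window")
      return(0)
    }
    pracma::trapz(tr$rt[sel], tr$intensity[sel] - baseline)
  }, numeric(1))
}

#' m6A/A area ratio
#' @param areas named numeric vector with elements "A" and "m6A"
#' @export
m6a_ratio <- function(areas) {
  if (!("A" %in% names(areas)) || areas[["A"]] <= 0)
    stop("adenosine area must be positive")
  areas[["m6A"]] / areas[["A"]]
}

#' Percent demethylation of a sample relative to a no-protein control
#'
#' 100 * (1 - ratio_sample / ratio_control).
#' @param ratio_sample,ratio_control m6A/A ratios
#' @export
demethylation_percent <- function(ratio_sample, ratio_control) {
  if (ratio_control <= 0) stop("control ratio must be positive")
  if (ratio_sample < 0) stop("ratios must be non-negative")
  100 * (1 - ratio_sample / ratio_control)
}
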