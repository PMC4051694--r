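#' Composite Simpson integration of a sampled trace
#'
#' Integrates intensity over retention time with the composite Simpson rule.
#' Consecutive interval pairs are integrated with the (non-uniform) Simpson
#' formula; when the number of intervals is odd the final interval falls back
#' to the trapezoid rule. Exact for cubic polynomials on a uniform grid.
#'
#' @param rt strictly increasing retention-time grid (>= 3 points).
#' @param intensity intensities on the grid, same length.
#' @return the integral as a scalar.
#' @examples
#' x <- seq(0, 2, length.out = 5)
#' integrate_simpson(x, x^2) # 8/3 exactly
#' @export
integrate_simpson <- function(rt, intensity) {
  n <- length(rt)
  if (n < 3L) {
    stop("Simpson integration needs at least 3 points", call. = FALSE)
  }
  if (length(intensity) != n) {
    stop("rt and intensity must have equal length", call. = FALSE)
  }
  if (any(diff(rt) <= 0)) {
    stop("retention-time grid must be strictly increasing", call. = FALSE)
  }
  total <- 0
  i <- 1L
  while (i + 2L <= n) {
    h0 <- rt[i + 1L] - rt[i]
    h1 <- rt[i + 2L] - rt[i + 1L]
    total <- total + (h0 + h1) / 6 * (
      (2 - h1 / h0) * intensity[i] +
        (h0 + h1)^2 / (h0 * h1) * intensity[i + 1L] +
        (2 - h0 / h1) * intensity[i + 2L]
    )
    i <- i + 2L
  }
  if (i + 1L == n) { # odd interval left over
    total <- total + (rt[n] - rt[n - 1L]) *
      (intensity[n] + intensity[n - 1L]) / 2
  }
  total
}

#' Match a light/heavy XIC pair
#'
#' Computes the Pearson correlation of the two traces over their overlapping
#' retention-time grid and accepts the pair only when it reaches the
#' correlation threshold — co-eluting isotope partners rise and fall
#' together, interference does not. Accepted pairs are restricted to an
#' integration window of at most `max_width` scans centred on the apex, with
#' scans below `xic_threshold` of the apex intensity excluded, and both
#' areas are obtained by Simpson integration over that window.
#'
#' @param rt_light,intensity_light light-label trace.
#' @param rt_heavy,intensity_heavy heavy-label trace (same grid convention).
#' @param correlation_threshold minimum Pearson correlation (default 0.8).
#' @param max_width maximum integration-window width in scans (default 7).
#' @param xic_threshold fraction of the apex intensity below which scans are
#'   excluded from the window (default 0.2).
#' @return For an accepted pair, a list of class `isotope_pair` with
#'   `accepted = TRUE`, `correlation`, `area_light`, `area_heavy` and the
#'   windowed traces. Otherwise `accepted = FALSE` with a `reason` code
#'   (`insufficient_overlap`, `zero_variance`, `low_correlation`,
#'   `window_too_narrow`).
#' @export
match_pair <- function(rt_light, intensity_light, rt_heavy, intensity_heavy,
                       correlation_threshold = 0.8, max_width = 7L,
                       xic_threshold = 0.2) {
  common <- intersect(rt_light, rt_heavy)
  if (length(common) < 3L) {
    return(reject_pair("insufficient_overlap"))
  }
  common <- sort(common)
  il <- intensity_light[match(common, rt_light)]
  ih <- intensity_heavy[match(common, rt_heavy)]
  if (stats::sd(il) == 0 || stats::sd(ih) == 0) {
    return(reject_pair("zero_variance"))
  }
  r <- stats::cor(il, ih)
  if (is.na(r) || r < correlation_threshold) {
    return(reject_pair("low_correlation", correlation = r))
  }
  combined <- il + ih
  apex <- which.max(combined)
  half <- (max_width - 1L) %/% 2L
  in_width <- abs(seq_along(common) - apex) <= half
  above <- combined >= xic_threshold * combined[apex]
  # contiguous run around the apex satisfying both constraints
  ok <- in_width & above
  lo <- apex
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- apex
  while (hi < length(common) && ok[hi + 1L]) hi <- hi + 1L
  win <- lo:hi
  if (length(win) < 3L) {
    return(reject_pair("window_too_narrow"))
  }
  structure(list(
    accepted = TRUE,
    correlation = r,
    rt = common[win],
    intensity_light = il[win],
    intensity_heavy = ih[win],
    area_light = integrate_simpson(common[win], il[win]),
    area_heavy = integrate_simpson(common[win], ih[win])
  ), class = "isotope_pair")
}

reject_pair <- function(reason, correlation = NA_real_) {
  structure(list(
    accepted = FALSE, reason = reason,
    correlation = correlation
  ), class = "isotope_pair")
}

#' @export
print.isotope_pair <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf(
      "Accepted isotope pair: r = %.3f, area L/H = %.4g / %.4g (H/L = %.3f)\n",
      x$correlation, x$area_light, x$area_heavy, x$area_heavy / x$area_light
    ))
  } else {
    cat(sprintf("Rejected isotope pair (%s)\n", x$reason))
  }
  invisible(x)
}
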