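#' Calibrate assembly index against MS2 peak count by quantile regression
#'
#' Fits three linear quantile regressions of computed MA on filtered MS2
#' peak count, at tau = 0.05, 0.5 and 0.95: the middle line is the median
#' predictor and the outer pair delimits a 90% prediction band. MA is
#' regressed on peak count (not the reverse) so that estimating the MA of
#' an unknown ion is direct evaluation of the fitted lines and the band is
#' a prediction interval in MA units.
#'
#' Each fit minimizes the mean pinball loss
#' \eqn{\rho_\tau(u) = u(\tau - 1[u<0])} exactly: an optimal linear
#' quantile fit passes through two observations, so the solver enumerates
#' all candidate lines through pairs of points and keeps the loss
#' minimizer (deterministic; ties broken by candidate order).
#'
#' @param points data.frame with columns `peak_count` and `ma` (or two
#'   vectors via `peak_count`/`ma`).
#' @param taus quantile levels (default 0.05, 0.5, 0.95).
#' @return an `ma_calibration`: `lines` (data.frame tau/slope/intercept),
#'   `n_points`, `pearson_r`, `peak_range`.
#' @export
fit_calibration <- function(points, taus = c(0.05, 0.5, 0.95)) {
  if (is.data.frame(points)) {
    stopifnot(all(c("peak_count", "ma") %in% names(points)))
    x <- as.numeric(points$peak_count); y <- as.numeric(points$ma)
  } else stop("points must be a data.frame with columns peak_count and ma")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("calibration needs at least 3 points, got ", n)
  if (stats::sd(x) == 0)
    stop("degenerate calibration: peak counts are constant")
  fits <- .pinball_fit(x, y, taus)
  lines <- data.frame(tau = taus, slope = fits[1, ], intercept = fits[2, ])
  structure(list(lines = lines, n_points = n,
                 pearson_r = stats::cor(x, y),
                 peak_range = range(x)),
            class = "ma_calibration")
}

# Exact linear quantile regression by pair enumeration (LP vertex
# solution); chunked so the candidate x residual matrix stays small, all
# quantile levels scored in one pass over the candidates.
.pinball_fit <- function(x, y, taus) {
  n <- length(x)
  pr <- utils::combn(n, 2L)
  dx <- x[pr[2, ]] - x[pr[1, ]]
  keep <- dx != 0
  slope <- (y[pr[2, keep]] - y[pr[1, keep]]) / dx[keep]
  icept <- y[pr[1, keep]] - slope * x[pr[1, keep]]
  if (length(slope) == 0L) stop("degenerate calibration: no sloped pair")
  best_loss <- rep(Inf, length(taus))
  best <- matrix(NA_real_, 2L, length(taus))
  for (chunk in split(seq_along(slope),
                      ceiling(seq_along(slope) / 2000L))) {
    r <- y - (outer(x, slope[chunk]) +
                matrix(icept[chunk], n, length(chunk), byrow = TRUE))
    pos <- colSums(r * (r > 0))   # sum of positive residuals
    neg <- pos - colSums(r)       # -sum of negative residuals
    for (t in seq_along(taus)) {
      loss <- taus[t] * pos + (1 - taus[t]) * neg
      i <- which.min(loss)
      if (loss[i] < best_loss[t] - 1e-12) {
        best_loss[t] <- loss[i]
        best[, t] <- c(slope[chunk[i]], icept[chunk[i]])
      }
    }
  }
  best
}

#' @export
print.ma_calibration <- function(x, ...) {
  cat(sprintf("<ma_calibration> %d standards, Pearson r = %.3f\n",
              x$n_points, x$pearson_r))
  for (i in seq_len(nrow(x$lines)))
    cat(sprintf("  tau = %.2f: MA = %.4f * peaks + %.4f\n",
                x$lines$tau[i], x$lines$slope[i], x$lines$intercept[i]))
  invisible(x)
}

#' Predict MA (with 90% band) from peak counts
#'
#' @param object an `ma_calibration`.
#' @param peak_count numeric vector of filtered MS2 peak counts.
#' @param ... unused.
#' @return data.frame with columns `peak_count`, `ma_low`, `ma_median`,
#'   `ma_high` (clamped at 0 from below; the three values are sorted so
#'   the band ordering holds even where fitted lines cross outside the
#'   training range).
#' @export
predict.ma_calibration <- function(object, peak_count, ...) {
  ln <- object$lines
  stopifnot(all(c(0.05, 0.5, 0.95) %in% ln$tau))
  ev <- function(tau) {
    i <- match(tau, ln$tau)
    pmax(ln$slope[i] * peak_count + ln$intercept[i], 0)
  }
  vals <- cbind(ev(0.05), ev(0.5), ev(0.95))
  vals <- t(apply(vals, 1L, sort))
  data.frame(peak_count = peak_count, ma_low = vals[, 1],
             ma_median = vals[, 2], ma_high = vals[, 3])
}

#' Estimate the MA of a single ion from its filtered peak count
#'
#' @param peak_count filtered MS2 peak count of the ion.
#' @param model a fitted [fit_calibration()] model.
#' @param precursor_mz optional precursor m/z carried into the record.
#' @return an `ion_estimate` data.frame row: `precursor_mz`,
#'   `filtered_peaks`, `ma_low`, `ma_median`, `ma_high`.
#' @export
estimate_ion <- function(peak_count, model, precursor_mz = NA_real_) {
  if (!inherits(model, "ma_calibration"))
    stop("model must be a fitted ma_calibration (see fit_calibration)")
  p <- predict(model, peak_count)
  out <- data.frame(precursor_mz = precursor_mz,
                    filtered_peaks = peak_count,
                    ma_low = p$ma_low, ma_median = p$ma_median,
                    ma_high = p$ma_high)
  class(out) <- c("ion_estimate", "data.frame")
  out
}

#' Persist / restore a calibration model as JSON
#'
#' @param model an `ma_calibration`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_calibration` returns the model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "ma_calibration"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$lines <- as.data.frame(m$lines)
  structure(m, class = "ma_calibration")
}
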