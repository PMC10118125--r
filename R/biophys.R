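# Biophysical quantifications: single-particle tracking and passive
# microrheology (MSD), ratiometric pH-biosensor calibration, growth-curve
# heat-resistance scoring, fluorescence heterogeneity, and trehalose
# quantification.
#
# Default tracking constants follow the imaging setup they emulate:
# 10/75 micron per pixel, 2 frames per second, minimal integrated-mass
# threshold 200 to reject spurious fluorescence.

#' Detect fluorescent particles in a 2-D image
#'
#' Local-maximum candidates within a `diameter`-sized window are refined to
#' a sub-pixel centroid by intensity-weighted averaging after local
#' background subtraction (the background is the median of the window's
#' perimeter ring). The integrated mass is the background-subtracted sum
#' over the window; candidates below `mass_threshold` are dropped, and of
#' two candidates closer than `separation` pixels only the more massive one
#' is kept.
#'
#' @param image numeric matrix (rows = y, columns = x), finite and
#'   non-negative.
#' @param diameter odd window size in pixels.
#' @param mass_threshold minimal integrated mass (default 200).
#' @param separation minimal center-to-center distance in pixels; defaults
#'   to `diameter`.
#' @return data.frame with columns `x`, `y` (sub-pixel, 1-based pixel
#'   coordinates) and `mass`, one row per detection.
#' @export
detect_particles <- function(image, diameter, mass_threshold = 200,
                             separation = diameter) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("image must be a numeric matrix", class = "solubilome_domain_error")
  if (any(!is.finite(image)) || any(image < 0))
    stopf("image must be finite and non-negative", class = "solubilome_domain_error")
  if (diameter %% 2 != 1)
    stopf("diameter must be odd", class = "solubilome_parameter_error")
  if (diameter > min(dim(image)))
    stopf("diameter exceeds image size", class = "solubilome_parameter_error")
  r <- (diameter - 1) / 2
  ny <- nrow(image); nx <- ncol(image)

  # local maxima via shift-compare over the full window
  is_max <- matrix(TRUE, ny, nx)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    shifted[ys, xs] <- image[ys - dy, xs - dx]
    # strict on one lexicographic half so plateaus yield a single maximum
    if (dy > 0 || (dy == 0 && dx > 0)) {
      is_max <- is_max & (image >= shifted)
    } else {
      is_max <- is_max & (image > shifted)
    }
  }
  # exclude borders where the window does not fit
  keep <- matrix(FALSE, ny, nx)
  if (ny - r >= r + 1 && nx - r >= r + 1)
    keep[(r + 1):(ny - r), (r + 1):(nx - r)] <- TRUE
  cand <- which(is_max & keep & image > 0, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), mass = numeric(0)))

  win <- -r:r
  ring <- abs(outer(win, rep(1, diameter))) == r |
          abs(outer(rep(1, diameter), win)) == r
  feats <- lapply(seq_len(nrow(cand)), function(i) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    w <- image[cy + win, cx + win, drop = FALSE]
    bg <- median(w[ring])
    net <- pmax(w - bg, 0)
    mass <- sum(net)
    if (mass <= 0) return(NULL)
    yy <- cy + win; xx <- cx + win
    data.frame(x = sum(net * matrix(xx, diameter, diameter, byrow = TRUE)) / mass,
               y = sum(net * matrix(yy, diameter, diameter)) / mass,
               mass = mass)
  })
  det <- do.call(rbind, feats)
  if (is.null(det) || nrow(det) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), mass = numeric(0)))
  det <- det[order(-det$mass), , drop = FALSE]
  # suppress neighbors closer than `separation`: keep the more massive
  kept <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!kept[i]) next
    if (i < nrow(det)) {
      j <- (i + 1):nrow(det)
      d2 <- (det$x[j] - det$x[i])^2 + (det$y[j] - det$y[i])^2
      kept[j[d2 < separation^2]] <- FALSE
    }
  }
  det <- det[kept & det$mass >= mass_threshold, , drop = FALSE]
  rownames(det) <- NULL
  det
}

# minimal-cost matching of detections to track ends; exhaustive for small
# problems (the documented conflict-resolution rule), greedy
# nearest-neighbor otherwise. Unlinked detections carry cost max_disp^2.
.match_frame <- function(cost, max_disp, exhaustive_limit = 7L) {
  n_det <- nrow(cost); n_trk <- ncol(cost)
  if (n_det == 0) return(integer(0))
  cost[cost > max_disp^2] <- Inf
  if (n_det <= exhaustive_limit && n_trk <= exhaustive_limit) {
    best <- NULL; best_cost <- Inf
    assign_rec <- function(i, used, acc, cur) {
      if (cur >= best_cost) return()
      if (i > n_det) {
        best <<- acc; best_cost <<- cur
        return()
      }
      for (j in seq_len(n_trk)) {
        if (!used[j] && is.finite(cost[i, j])) {
          used[j] <- TRUE
          assign_rec(i + 1, used, c(acc, j), cur + cost[i, j])
          used[j] <- FALSE
        }
      }
      assign_rec(i + 1, used, c(acc, NA_integer_), cur + max_disp^2)
    }
    assign_rec(1L, rep(FALSE, n_trk), integer(0), 0)
    return(best)
  }
  # greedy: accept candidate links in ascending distance order
  out <- rep(NA_integer_, n_det)
  used <- rep(FALSE, n_trk)
  finite <- which(is.finite(cost), arr.ind = TRUE)
  if (nrow(finite) > 0) {
    ord <- order(cost[finite])
    for (idx in ord) {
      i <- finite[idx, 1]; j <- finite[idx, 2]
      if (is.na(out[i]) && !used[j]) {
        out[i] <- j; used[j] <- TRUE
      }
    }
  }
  out
}

#' Link per-frame detections into particle trajectories
#'
#' Frame-to-frame assignment minimizing total squared displacement, with no
#' link longer than `max_disp` (same units as the coordinates). Conflicts
#' are resolved exhaustively when at most 7 detections/tracks compete
#' (minimal-cost matching, with an unlinked detection costing
#' `max_disp^2`), and by greedy ascending-distance assignment otherwise.
#' Track ends may survive up to `memory` skipped frames and still be
#' linked; unlinkable detections start new tracks.
#'
#' @param detections data.frame with columns `frame` (integer), `x`, `y`.
#' @param max_disp maximum link displacement.
#' @param memory number of frames a lost particle may skip (default 0).
#' @return data.frame `particle`, `frame`, `x`, `y`, ordered by particle
#'   then frame.
#' @export
link_tracks <- function(detections, max_disp, memory = 0L) {
  det <- as.data.frame(detections)
  if (!all(c("frame", "x", "y") %in% names(det)))
    stopf("detections need columns frame, x, y", class = "solubilome_schema_error")
  det <- det[order(det$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  det$particle <- NA_integer_
  last_pos <- matrix(numeric(0), ncol = 2)   # one row per track: x, y
  last_frame <- integer(0)
  n_tracks <- 0L
  for (f in frames) {
    rows <- which(det$frame == f)
    active <- which(last_frame >= f - 1L - memory)
    if (length(active) > 0 && length(rows) > 0) {
      cost <- outer(seq_along(rows), seq_along(active),
                    Vectorize(function(i, j) {
                      (det$x[rows[i]] - last_pos[active[j], 1])^2 +
                      (det$y[rows[i]] - last_pos[active[j], 2])^2
                    }))
      cost <- matrix(cost, nrow = length(rows))
      m <- .match_frame(cost, max_disp)
    } else {
      m <- rep(NA_integer_, length(rows))
    }
    for (i in seq_along(rows)) {
      if (!is.na(m[i])) {
        trk <- active[m[i]]
      } else {
        n_tracks <- n_tracks + 1L
        trk <- n_tracks
        last_pos <- rbind(last_pos, c(NA_real_, NA_real_))
        last_frame <- c(last_frame, -Inf)
      }
      det$particle[rows[i]] <- trk
      last_pos[trk, ] <- c(det$x[rows[i]], det$y[rows[i]])
      last_frame[trk] <- f
    }
  }
  det <- det[order(det$particle, det$frame),
             c("particle", "frame", "x", "y")]
  rownames(det) <- NULL
  det
}

#' Convert linked pixel tracks to physical units
#'
#' @param tracks data.frame `particle`, `frame`, `x`, `y` in pixels.
#' @param mpp microns per pixel (default 10/75).
#' @param fps frames per second (default 2).
#' @return data.frame `particle`, `frame`, `x_um`, `y_um`, `t_s` with an
#'   `fps` attribute.
#' @export
tracks_to_um <- function(tracks, mpp = 10 / 75, fps = 2) {
  out <- data.frame(particle = tracks$particle, frame = tracks$frame,
                    x_um = tracks$x * mpp, y_um = tracks$y * mpp,
                    t_s = tracks$frame / fps)
  attr(out, "fps") <- fps
  out
}

#' Per-particle and ensemble mean squared displacement
#'
#' For each particle, `MSD(tau)` is the mean over all ordered position
#' pairs separated by lag `tau` of the squared Euclidean displacement
#' (overlapping windows; gaps in a track simply contribute no pairs at the
#' affected lags). The ensemble curve at each lag is the mean over
#' particles weighted by their number of displacement pairs.
#'
#' @param tracks data.frame `particle`, `frame`, `x_um`, `y_um` (microns);
#'   frame spacing is `1/fps` seconds.
#' @param max_lag largest lag in seconds (default: longest track span;
#'   larger requests are truncated with a warning).
#' @param fps frames per second; defaults to the `fps` attribute of
#'   `tracks`, else 2.
#' @return list with `imsd` (data.frame `particle`, `lag_s`, `msd`,
#'   `n_pairs`) and `emsd` (data.frame `lag_s`, `msd`, `n_pairs`).
#' @export
msd_curves <- function(tracks, max_lag = NULL, fps = NULL) {
  fps <- fps %||% attr(tracks, "fps") %||% 2
  tr <- as.data.frame(tracks)
  if (!all(c("particle", "frame", "x_um", "y_um") %in% names(tr)))
    stopf("tracks need columns particle, frame, x_um, y_um",
          class = "solubilome_schema_error")
  span <- max(tr$frame) - min(tr$frame)
  max_lag_frames <- if (is.null(max_lag)) span else round(max_lag * fps)
  if (max_lag_frames > span) {
    warnf("max_lag exceeds the longest track; truncating to %g s", span / fps)
    max_lag_frames <- span
  }
  per <- lapply(split(tr, tr$particle), function(d) {
    if (nrow(d) < 2) return(NULL)
    f0 <- min(d$frame)
    idx <- d$frame - f0 + 1L
    x <- rep(NA_real_, max(idx)); y <- x
    x[idx] <- d$x_um; y[idx] <- d$y_um
    L <- min(max_lag_frames, max(idx) - 1L)
    if (L < 1) return(NULL)
    res <- lapply(seq_len(L), function(lag) {
      dx <- x[-seq_len(lag)] - x[seq_len(length(x) - lag)]
      dy <- y[-seq_len(lag)] - y[seq_len(length(y) - lag)]
      sq <- dx^2 + dy^2
      n <- sum(!is.na(sq))
      data.frame(particle = d$particle[1], lag_s = lag / fps,
                 msd = if (n > 0) mean(sq, na.rm = TRUE) else NA_real_,
                 n_pairs = n)
    })
    do.call(rbind, res)
  })
  imsd <- do.call(rbind, per)
  rownames(imsd) <- NULL
  ok <- imsd[!is.na(imsd$msd) & imsd$n_pairs > 0, ]
  agg <- split(ok, ok$lag_s)
  emsd <- do.call(rbind, lapply(agg, function(d) {
    data.frame(lag_s = d$lag_s[1],
               msd = sum(d$msd * d$n_pairs) / sum(d$n_pairs),
               n_pairs = sum(d$n_pairs))
  }))
  emsd <- emsd[order(emsd$lag_s), ]
  rownames(emsd) <- NULL
  list(imsd = imsd, emsd = emsd)
}

#' Diffusion coefficient from an ensemble MSD curve
#'
#' Weighted least squares of `MSD = 4 D tau` through the origin over the
#' lags in `fit_lags` (inclusive, seconds), with weights proportional to
#' the number of displacement pairs at each lag. No localization-noise
#' offset is subtracted. A residual diagnostic flags fits where the linear
#' model explains less than 90% of the weighted variation about the origin
#' (e.g. ballistic motion), and negative fitted values are returned with a
#' warning flag rather than an error.
#'
#' @param emsd ensemble MSD data.frame (`lag_s`, `msd`, `n_pairs`).
#' @param fit_lags length-2 numeric, lag window in seconds (default
#'   `c(0.5, 5)`).
#' @return list `D` (um^2/s), `se`, `r_squared`, `flagged` (TRUE when D < 0
#'   or the fit is poor), `n_lags`.
#' @export
estimate_diffusion <- function(emsd, fit_lags = c(0.5, 5)) {
  d <- emsd[emsd$lag_s >= fit_lags[1] & emsd$lag_s <= fit_lags[2], ]
  if (nrow(d) < 2)
    stopf("need >= 2 lags inside fit_lags", class = "solubilome_domain_error")
  w <- if ("n_pairs" %in% names(d)) d$n_pairs else rep(1, nrow(d))
  x <- 4 * d$lag_s
  D <- sum(w * x * d$msd) / sum(w * x^2)
  res <- d$msd - D * x
  dof <- nrow(d) - 1
  sigma2 <- sum(w * res^2) / (dof * mean(w))
  se <- sqrt(sigma2 / sum(w * x^2) * mean(w))
  ybar <- sum(w * d$msd) / sum(w)
  ss_tot <- sum(w * (d$msd - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * res^2) / ss_tot else 1
  flagged <- D < 0 || r2 < 0.9
  if (D < 0) warnf("fitted diffusion coefficient is negative (noise-dominated)")
  list(D = D, se = se, r_squared = r2, flagged = flagged, n_lags = nrow(d))
}

# four-parameter logistic, increasing in pH for this sensor class
.fpl <- function(ph, lower, upper, midpoint, slope) {
  lower + (upper - lower) / (1 + exp(-slope * (ph - midpoint)))
}

#' Fit a ratiometric pH calibration curve
#'
#' Background-subtracted median excitation ratios (405/488) at known buffer
#' pH are fitted by least squares to a four-parameter logistic,
#' `ratio = lower + (upper - lower) / (1 + exp(-slope (pH - midpoint)))`,
#' increasing in pH. Flat data (relative ratio range < 2% of the mean) and
#' non-monotone data (Spearman correlation of ratio vs pH below 0.5) are
#' rejected with named errors before fitting.
#'
#' @param points data.frame with columns `ph` and `ratio` (raw median
#'   ratios), >= 5 rows spanning the transition.
#' @param blank autofluorescence ratio of unlabeled cells, subtracted from
#'   `ratio` before fitting (default 0, i.e. already corrected).
#' @return object of class `ph_calibration`: list with `coefficients`
#'   (lower, upper, midpoint, slope), `residuals`, `fitted`, `data`,
#'   `blank`.
#' @export
fit_ph_calibration <- function(points, blank = 0) {
  df <- as.data.frame(points)
  if (!all(c("ph", "ratio") %in% names(df)))
    stopf("points need columns ph and ratio", class = "solubilome_schema_error")
  if (nrow(df) < 5)
    stopf("calibration needs >= 5 pH points", class = "solubilome_domain_error")
  y <- df$ratio - blank
  if ((max(y) - min(y)) < 0.02 * abs(mean(y)) || max(y) == min(y))
    stopf("flat-data error: calibration ratios do not vary with pH",
          class = "solubilome_fit_error")
  rho <- cor(df$ph, y, method = "spearman")
  if (!is.finite(rho) || rho < 0.5)
    stopf("non-monotone calibration data (Spearman rho = %.2f)", rho,
          class = "solubilome_fit_error")
  # start values: asymptotes from the data range, slope from a logit-line
  # fit of the scaled response, midpoint by interpolation at half-maximum
  rng <- max(y) - min(y)
  l0 <- min(y) - 0.05 * rng; u0 <- max(y) + 0.05 * rng
  z <- pmin(pmax((y - l0) / (u0 - l0), 1e-3), 1 - 1e-3)
  lf <- stats::lm(stats::qlogis(z) ~ df$ph)
  start <- list(lower = l0, upper = u0,
                midpoint = -coef(lf)[1] / coef(lf)[2],
                slope = max(coef(lf)[2], 0.1))
  obj <- function(p) sum((y - .fpl(df$ph, p[1], p[2], p[3], p[4]))^2)
  fit <- tryCatch(
    nls(y ~ .fpl(ph, lower, upper, midpoint, slope),
        data = data.frame(ph = df$ph, y = y), start = start,
        algorithm = "port",
        lower = c(lower = -Inf, upper = -Inf, midpoint = min(df$ph) - 5,
                  slope = 1e-3),
        control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- as.list(coef(fit))
    fitted_y <- as.numeric(fitted(fit))
  } else {
    # fall back to direct least squares when nls cannot converge
    op <- stats::optim(unlist(start), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
    if (op$convergence != 0)
      stopf("sigmoid fit failed to converge", class = "solubilome_fit_error")
    cf <- as.list(setNames(op$par, c("lower", "upper", "midpoint", "slope")))
    fitted_y <- .fpl(df$ph, cf$lower, cf$upper, cf$midpoint, cf$slope)
  }
  if (cf$upper <= cf$lower)
    stopf("fit degenerate: upper asymptote <= lower", class = "solubilome_fit_error")
  structure(list(coefficients = lapply(cf, unname),
                 residuals = y - fitted_y,
                 fitted = fitted_y,
                 data = data.frame(ph = df$ph, ratio_corrected = y),
                 blank = blank),
            class = "ph_calibration")
}

#' Evaluate a fitted calibration curve
#' @param curve a `ph_calibration`.
#' @param ph pH values.
#' @return predicted background-corrected ratios.
#' @export
ratio_at_ph <- function(curve, ph) {
  cf <- curve$coefficients
  .fpl(ph, cf$lower, cf$upper, cf$midpoint, cf$slope)
}

#' Estimate intracellular pH from measured ratios
#'
#' Applies the analytic inverse of the fitted four-parameter logistic to
#' background-subtracted per-cell ratios. Ratios outside the open interval
#' (lower, upper) are clamped just inside the asymptotes and flagged; if
#' every ratio is out of range the estimation fails.
#'
#' @param curve a `ph_calibration` from [fit_ph_calibration()].
#' @param sample_ratios raw per-cell 405/488 ratios.
#' @param blank background ratio subtracted before inversion (same
#'   convention as the calibration; defaults to the curve's blank).
#' @return list `median_ph`, `ph` (per cell), `n_clamped`.
#' @export
estimate_ph <- function(curve, sample_ratios, blank = curve$blank) {
  cf <- curve$coefficients
  r <- sample_ratios - blank
  eps <- 1e-9 * (cf$upper - cf$lower)
  out_of_range <- r <= cf$lower | r >= cf$upper
  if (all(out_of_range))
    stopf("all sample ratios fall outside the calibration range (%.3g, %.3g)",
          cf$lower, cf$upper, class = "solubilome_domain_error")
  r_cl <- pmin(pmax(r, cf$lower + eps), cf$upper - eps)
  ph <- cf$midpoint - log((cf$upper - cf$lower) / (r_cl - cf$lower) - 1) / cf$slope
  list(median_ph = median(ph), ph = ph, n_clamped = sum(out_of_range))
}

#' Growth-curve area under the curve
#'
#' Trapezoidal area of the optical density above its initial baseline
#' (the first reading) from the first time point to `t_end`, interpolating
#' linearly at `t_end` when it falls between readings. Negative excursions
#' below baseline are clipped to zero so read noise cannot produce negative
#' areas.
#'
#' @param curve data.frame with columns `time_h` (strictly increasing) and
#'   `od` (non-negative).
#' @param t_end end of the integration window (hours).
#' @return area in OD x h.
#' @export
growth_auc <- function(curve, t_end) {
  df <- as.data.frame(curve)
  if (!all(c("time_h", "od") %in% names(df)))
    stopf("curve needs columns time_h and od", class = "solubilome_schema_error")
  if (any(diff(df$time_h) <= 0))
    stopf("times must be strictly increasing", class = "solubilome_validation_error")
  if (any(df$od < 0))
    stopf("optical density must be non-negative", class = "solubilome_validation_error")
  if (t_end < df$time_h[2])
    stopf("t_end precedes the second time point", class = "solubilome_domain_error")
  t_end <- min(t_end, max(df$time_h))
  y <- pmax(df$od - df$od[1], 0)
  tt <- df$time_h
  if (!(t_end %in% tt)) {
    y_end <- approx(tt, y, xout = t_end)$y
    keep <- tt < t_end
    tt <- c(tt[keep], t_end); y <- c(y[keep], y_end)
  } else {
    keep <- tt <= t_end
    tt <- tt[keep]; y <- y[keep]
  }
  sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
}

# first time the smoothed curve stays within `tol` of its maximum for
# `consecutive` readings; NA when it never plateaus
.plateau_time <- function(curve, tol = 0.02, consecutive = 3L, window = 3L) {
  od <- curve$od
  n <- length(od)
  half <- (window - 1) %/% 2
  sm <- vapply(seq_len(n), function(i) {
    mean(od[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  near <- sm >= (1 - tol) * max(sm)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (near[i]) run + 1L else 0L
    if (run >= consecutive) return(curve$time_h[i - consecutive + 1L])
  }
  NA_real_
}

#' Heat-resistance score from paired growth curves
#'
#' The score is the ratio of the area under the heat-treated growth curve
#' to the area under the untreated curve, both integrated over the time the
#' untreated culture needs to reach its stationary plateau. Plateau
#' detection: first time the 3-point moving average of the untreated curve
#' stays within 2% of its maximum for 3 consecutive readings; if it never
#' plateaus the full window is used with a warning.
#'
#' @param treated,untreated growth-curve data.frames (`time_h`, `od`) on
#'   the same sampling grid.
#' @return score in \[0, ~1\] (1 = treated grows like untreated, 0 = no
#'   growth after treatment).
#' @export
heat_resistance_score <- function(treated, untreated) {
  tr <- as.data.frame(treated); un <- as.data.frame(untreated)
  if (length(tr$time_h) != length(un$time_h) ||
      any(abs(tr$time_h - un$time_h) > 1e-9))
    stopf("treated and untreated curves must share the sampling window",
          class = "solubilome_validation_error")
  t_end <- .plateau_time(un)
  if (is.na(t_end)) {
    warnf("untreated culture never plateaus within the window; using the last time point")
    t_end <- max(un$time_h)
  }
  t_end <- max(t_end, un$time_h[2])
  auc_un <- growth_auc(un, t_end)
  if (auc_un <= 0)
    stopf("untreated culture shows no growth; score undefined",
          class = "solubilome_domain_error")
  max(growth_auc(tr, t_end) / auc_un, 0)
}

#' Fluorescence heterogeneity score (coefficient of variation)
#'
#' Sample standard deviation of the pixel intensities within one cell mask
#' divided by their mean. High values indicate concentrated foci, low
#' values a diffuse signal. Invariant under multiplying all intensities by
#' a positive constant.
#'
#' @param pixels numeric vector of >= 2 intensities with positive mean.
#' @return the coefficient of variation.
#' @export
heterogeneity_cv <- function(pixels) {
  if (length(pixels) < 2)
    stopf("need >= 2 pixels", class = "solubilome_domain_error")
  m <- mean(pixels)
  if (!is.finite(m) || m <= 0)
    stopf("mean intensity must be positive", class = "solubilome_domain_error")
  sd(pixels) / m
}

#' Trehalose content from paired glucose assays
#'
#' Trehalose (in glucose equivalents) is the glucose concentration measured
#' after trehalase digestion minus the concentration without treatment.
#' Small negative differences (assay noise) are floored at 0 with a
#' warning.
#'
#' @param glucose_with_trehalase,glucose_without glucose readings (mg/mL),
#'   both non-negative.
#' @return trehalose content in glucose equivalents (mg/mL).
#' @export
trehalose_content <- function(glucose_with_trehalase, glucose_without) {
  if (glucose_with_trehalase < 0 || glucose_without < 0)
    stopf("glucose readings must be non-negative", class = "solubilome_domain_error")
  d <- glucose_with_trehalase - glucose_without
  if (d < 0) {
    warnf("negative glucose difference (%.3g); flooring trehalose content at 0", d)
    d <- 0
  }
  d
}
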