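# Ratiometric optode image analysis: two-channel (indicator/reference)
# stacks -> Stern-Volmer calibration -> O2 maps -> pixel-wise volumetric
# rate maps with outlier removal, median filtering and chlorophyll masking.

#' Average replicate frames from one time point
#'
#' @param images list of numeric matrices (or a 3D array with frames along
#'   the third dimension) sharing one shape.
#' @return per-pixel arithmetic mean as a matrix.
#' @export
average_frames <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  if (!length(images)) stop("need at least one image", call. = FALSE)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), TRUE)))
    stop("all images must share the same shape", call. = FALSE)
  Reduce(`+`, images) / length(images)
}

#' Pixel-wise indicator/reference ratio
#'
#' Divides the red (O2 indicator) channel by the green (reference) channel.
#' Pixels whose reference intensity falls below `green_floor` are flagged
#' invalid (`NA`) instead of producing infinities.
#'
#' @param red,green numeric matrices of equal shape, intensities >= 0.
#' @param green_floor minimum usable reference intensity (absolute).
#' @return ratio matrix with `NA` at invalid pixels.
#' @export
compute_ratio <- function(red, green, green_floor = 1e-9) {
  if (!identical(dim(red), dim(green)))
    stop("red and green must share the same shape", call. = FALSE)
  ratio <- red / green
  ratio[!is.finite(ratio) | green < green_floor] <- NA_real_
  ratio
}

#' Fit a Stern-Volmer calibration curve
#'
#' Relates the indicator/reference ratio to O2.  The simple model is
#' R(C) = R0 / (1 + Ksv C); the two-site variant
#' R(C) = R0 (f / (1 + Ksv C) + 1 - f) leaves a fraction `1 - f` of the
#' indicator inaccessible to quenching (f = 1 recovers the simple model).
#' Fitting is nonlinear least squares on the ratio scale, seeded from the
#' linearised form 1/R = 1/R0 + (Ksv/R0) C.
#'
#' @param table data frame with columns `o2_umol_L` and `ratio`, at least
#'   3 points spanning zero to near air saturation; `ratio` must decrease
#'   monotonically with O2.
#' @param model `"simple"` or `"two-site"`.
#' @return object of class `calibration_curve`: `model`, `R0`, `K_sv`
#'   ((umol/L)^-1), `f`, and the RMS `fit_residual`.
#' @export
fit_calibration <- function(table, model = c("simple", "two-site")) {
  model <- match.arg(model)
  C <- as.numeric(table$o2_umol_L)
  R <- as.numeric(table$ratio)
  if (length(C) < 3L) stop("need at least 3 calibration points", call. = FALSE)
  o <- order(C)
  if (any(diff(R[o]) >= 0))
    stop("calibration table is not strictly monotone (ratio must decrease ",
         "with O2)", call. = FALSE)
  lin <- stats::lm(I(1 / R) ~ C)
  R0_0 <- 1 / stats::coef(lin)[1]
  Ksv_0 <- stats::coef(lin)[2] * R0_0
  start <- list(R0 = unname(R0_0), Ksv = unname(max(Ksv_0, 1e-6)))
  # scaleOffset makes the convergence test sound on (near-)zero-residual
  # tables, e.g. synthetic calibrations
  ctrl <- stats::nls.control(maxiter = 200, scaleOffset = 1)
  if (model == "simple") {
    fit <- stats::nls(R ~ R0 / (1 + Ksv * C), start = start, control = ctrl)
    f <- 1
  } else {
    fit <- stats::nls(R ~ R0 * (f / (1 + Ksv * C) + 1 - f),
                      start = c(start, list(f = 0.95)), control = ctrl,
                      lower = c(1e-6, 1e-9, 1e-3), upper = c(Inf, Inf, 1),
                      algorithm = "port")
    f <- unname(stats::coef(fit)["f"])
  }
  cf <- stats::coef(fit)
  structure(list(model = model, R0 = unname(cf["R0"]),
                 K_sv = unname(cf["Ksv"]), f = f,
                 fit_residual = sqrt(mean(stats::residuals(fit)^2)),
                 range_umol_L = range(C)),
            class = "calibration_curve")
}

#' Map a ratio image to O2 concentration
#'
#' Inverts the fitted Stern-Volmer curve in closed form.
#'
#' @param cal a [fit_calibration()] object.
#' @param ratio ratio values (vector or matrix).
#' @return O2 in umol L^-1 (same shape as `ratio`).
#' @export
ratio_to_o2 <- function(cal, ratio) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (cal$model == "simple" || cal$f >= 1 - 1e-12) {
    (cal$R0 / ratio - 1) / cal$K_sv
  } else {
    x <- ratio / cal$R0 - 1 + cal$f
    (cal$f / x - 1) / cal$K_sv
  }
}

#' Map O2 concentration to the expected ratio
#'
#' Forward Stern-Volmer model; inverse of [ratio_to_o2()].
#'
#' @param cal a [fit_calibration()] object (or a list with `model`, `R0`,
#'   `K_sv`, `f`).
#' @param o2_umol_L O2 concentration(s), umol L^-1.
#' @return ratio values (same shape).
#' @export
o2_to_ratio <- function(cal, o2_umol_L) {
  if (identical(cal$model, "simple") || is.null(cal$f) || cal$f >= 1 - 1e-12)
    cal$R0 / (1 + cal$K_sv * o2_umol_L)
  else
    cal$R0 * (cal$f / (1 + cal$K_sv * o2_umol_L) + 1 - cal$f)
}

#' Two-dimensional median filter
#'
#' Square-kernel median with reflective padding at the borders; `NA`
#' (invalid) pixels are ignored within each window.
#'
#' @param x numeric matrix.
#' @param size odd kernel edge length (default 5).
#' @return filtered matrix of the same shape.
#' @export
median_filter2 <- function(x, size = 5) {
  if (size %% 2 != 1 || size < 1) stop("`size` must be odd", call. = FALSE)
  p <- size %/% 2
  nr <- nrow(x); nc <- ncol(x)
  ridx <- c(rev(seq_len(p) + 1L), seq_len(nr), nr - seq_len(p))
  cidx <- c(rev(seq_len(p) + 1L), seq_len(nc), nc - seq_len(p))
  xp <- x[ridx, cidx, drop = FALSE]
  win <- matrix(NA_real_, nr * nc, size * size)
  k <- 0L
  for (dj in 0:(size - 1L)) for (di in 0:(size - 1L)) {
    k <- k + 1L
    win[, k] <- as.vector(xp[di + seq_len(nr), dj + seq_len(nc)])
  }
  matrix(apply(win, 1L, stats::median, na.rm = TRUE), nr, nc)
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximising the between-class variance; used as
#' the default cut on chlorophyll autofluorescence images.
#'
#' @param x numeric matrix or vector.
#' @param n_bins number of histogram bins.
#' @return threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- x[is.finite(x)]
  if (!length(v)) stop("no finite values", call. = FALSE)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(
    v, seq(rng[1], rng[2], length.out = n_bins + 1L),
    all.inside = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # midpoint of the arg-max plateau (empty bins between modes tie)
  top <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  k <- mean(range(top))
  rng[1] + diff(rng) * k / n_bins
}

#' Pixel-wise volumetric O2 rate map from a ratio stack
#'
#' Converts the ratio images at two time points to O2 via the calibration,
#' divides the difference by the elapsed time (hours), invalidates rates
#' beyond `outlier_threshold` in magnitude, smooths with a square median
#' filter, and attaches a chlorophyll mask (phototroph pixels) thresholded
#' on the autofluorescence image.
#'
#' @param stack a ratio stack: list with `frames` (each a list of `time_h`,
#'   `red`, `green`) and `pixel_size_um`, as produced by
#'   [make_ratio_series()] or [read_ratio_stack()].
#' @param cal a [fit_calibration()] object.
#' @param t0,t1 frame times (h) to difference; `t1 > t0`.
#' @param outlier_threshold absolute rate (umol L^-1 h^-1) beyond which a
#'   pixel is invalidated before filtering.
#' @param chl_image optional chlorophyll autofluorescence matrix.
#' @param chl_threshold threshold on `chl_image`; default Otsu.
#' @param median_size median filter kernel edge (odd; default 5).
#' @return object of class `rate_map`: `rate` (umol O2 L^-1 h^-1, negative
#'   = consumption), logical `valid_mask` and `chl_mask`, plus metadata.
#' @export
rate_map <- function(stack, cal, t0, t1, outlier_threshold = 500,
                     chl_image = NULL, chl_threshold = NULL,
                     median_size = 5) {
  if (t1 <= t0) stop("t1 must be greater than t0", call. = FALSE)
  times <- vapply(stack$frames, `[[`, 0, "time_h")
  pick <- function(t) {
    i <- which(abs(times - t) < 1e-9)
    if (!length(i)) stop("no frame at t = ", t, " h", call. = FALSE)
    stack$frames[[i[1]]]
  }
  f0 <- pick(t0); f1 <- pick(t1)
  r0 <- compute_ratio(f0$red, f0$green)
  r1 <- compute_ratio(f1$red, f1$green)
  C0 <- ratio_to_o2(cal, r0)
  C1 <- ratio_to_o2(cal, r1)
  rate <- (C1 - C0) / (t1 - t0)
  valid <- is.finite(rate)
  rate[valid & abs(rate) > outlier_threshold] <- NA_real_
  valid <- is.finite(rate)
  rate <- median_filter2(rate, median_size)
  valid <- valid & is.finite(rate)
  chl_mask <- NULL
  if (!is.null(chl_image)) {
    if (is.null(chl_threshold)) chl_threshold <- otsu_threshold(chl_image)
    chl_mask <- chl_image >= chl_threshold
  }
  structure(list(rate = rate, valid_mask = valid, chl_mask = chl_mask,
                 t0_h = t0, t1_h = t1,
                 pixel_size_um = stack$pixel_size_um),
            class = "rate_map")
}

#' Rate statistics per surface class
#'
#' Median and quartiles of the valid rates for the chlorophyll-positive
#' (phototroph) and chlorophyll-negative pixel classes, plus the whole-map
#' net statistics.  An empty class is reported as an absent row rather
#' than an error.
#'
#' @param rmap a [rate_map()] object (with a chlorophyll mask for the
#'   per-class split).
#' @return data frame with columns `class`, `n`, `q25`, `median`, `q75`.
#' @export
patch_statistics <- function(rmap) {
  stopifnot(inherits(rmap, "rate_map"))
  v <- rmap$valid_mask
  one <- function(label, sel) {
    x <- rmap$rate[sel]
    x <- x[is.finite(x)]
    if (!length(x)) return(NULL)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = label, n = length(x),
               q25 = q[1], median = q[2], q75 = q[3])
  }
  rows <- list(one("all", v))
  if (!is.null(rmap$chl_mask)) {
    rows <- c(rows, list(one("chl_positive", v & rmap$chl_mask),
                         one("chl_negative", v & !rmap$chl_mask)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "O2 rate map %d x %d px (%.3g-%.3g h): %d valid px, median %.3g umol/L/h\n",
    nrow(x$rate), ncol(x$rate), x$t0_h, x$t1_h, sum(x$valid_mask),
    stats::median(x$rate[x$valid_mask])))
  invisible(x)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Stern-Volmer calibration (%s): R0 = %.4g, Ksv = %.4g (umol/L)^-1%s, RMS residual %.3g\n",
    x$model, x$R0, x$K_sv,
    if (x$model == "two-site") sprintf(", f = %.3f", x$f) else "",
    x$fit_residual))
  invisible(x)
}
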