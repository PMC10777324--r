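#' Construct a raw FID
#'
#' A `raw_fid` holds the complex time-domain signal together with the
#' acquisition metadata needed to process it: spectral width, observe
#' frequency, nucleus, solvent, the carrier position in ppm, and (for data
#' from digitally filtered spectrometers) the group delay in points.
#'
#' @param data complex (or numeric, coerced) vector of time-domain samples,
#'   length >= 2.
#' @param sw_hz spectral width in Hz; the dwell time is `1/sw_hz`.
#' @param sfo1_mhz observe frequency in MHz.
#' @param nucleus observed nucleus, e.g. `"1H"`.
#' @param solvent solvent name, e.g. `"CDCl3"`.
#' @param group_delay_pts digital-filter group delay in points, or `NULL`.
#'   It is recorded here and compensated during [fourier_transform()], never
#'   silently applied to the time-domain data.
#' @param center_ppm chemical shift of the carrier (center of the spectrum).
#' @return an object of class `raw_fid`.
#' @export
raw_fid <- function(data, sw_hz, sfo1_mhz, nucleus = "1H", solvent = "unknown",
                    group_delay_pts = NULL, center_ppm = 0) {
  if (length(data) < 2L) stop("FID needs at least 2 points")
  if (!is.numeric(sw_hz) || sw_hz <= 0) stop("sw_hz must be > 0")
  if (!is.numeric(sfo1_mhz) || sfo1_mhz <= 0) stop("sfo1_mhz must be > 0")
  structure(list(
    data = as.complex(data),
    dwell_s = 1 / sw_hz,
    sw_hz = sw_hz,
    sfo1_mhz = sfo1_mhz,
    nucleus = nucleus,
    solvent = solvent,
    group_delay_pts = group_delay_pts,
    center_ppm = center_ppm,
    chain = list()
  ), class = "raw_fid")
}

#' @export
print.raw_fid <- function(x, ...) {
  cat(sprintf("<raw_fid> %d complex points, sw %.6g Hz, %s at %.6g MHz (%s)\n",
              length(x$data), x$sw_hz, x$nucleus, x$sfo1_mhz, x$solvent))
  invisible(x)
}

new_spectrum1d <- function(data, ppm, sfo1_mhz, sw_hz, nucleus, solvent,
                           center_ppm, chain = list()) {
  structure(list(
    data = data,
    ppm = ppm,
    sfo1_mhz = sfo1_mhz,
    sw_hz = sw_hz,
    nucleus = nucleus,
    solvent = solvent,
    center_ppm = center_ppm,
    digital_resolution_hz = sw_hz / length(data),
    chain = chain,
    baseline_estimate = NULL
  ), class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf(
    "<spectrum1d> %d points, %.4f..%.4f ppm, %s at %.6g MHz, %d filters\n",
    length(x$data), x$ppm[1], x$ppm[length(x$ppm)], x$nucleus, x$sfo1_mhz,
    length(x$chain)))
  invisible(x)
}

#' Create a filter record
#'
#' Processing operations are recorded as named, parameterized filters.  An
#' ordered chain of filter records fully determines a spectrum's processing
#' state and can be re-executed from the originating raw FID; editing a
#' record's parameters and re-applying the chain is therefore equivalent to
#' having processed with the edited parameters from the start.
#'
#' @param name one of `"exponential_apodization"`, `"gaussian_apodization"`,
#'   `"zero_fill"`, `"fourier_transform"`, `"phase"`, `"baseline"`,
#'   `"reference_shift"`.
#' @param params named list of filter parameters.
#' @param enabled logical; disabled records stay in the chain but are skipped
#'   on execution.
#' @return an object of class `filter_record`.
#' @export
filter_record <- function(name, params = list(), enabled = TRUE) {
  registry <- c("exponential_apodization", "gaussian_apodization", "zero_fill",
                "fourier_transform", "phase", "baseline", "reference_shift")
  if (!name %in% registry)
    stop("unknown filter name: ", name)
  structure(list(name = name, params = params, enabled = isTRUE(enabled)),
            class = "filter_record")
}

append_filter <- function(obj, name, params) {
  obj$chain <- c(obj$chain, list(filter_record(name, params)))
  obj
}

#' Exponential apodization (line broadening)
#'
#' Multiplies the FID by `exp(-pi * lb_hz * t)`, adding `lb_hz` Hz of
#' Lorentzian width to every line after Fourier transformation.
#'
#' @param fid a [raw_fid()].
#' @param lb_hz line broadening in Hz, >= 0.
#' @return the apodized `raw_fid`, with the filter recorded in its chain.
#' @export
apodize_exponential <- function(fid, lb_hz) {
  stopifnot(inherits(fid, "raw_fid"))
  if (!is.finite(lb_hz)) stop("lb_hz must be finite")
  if (lb_hz < 0) stop("lb_hz must be >= 0 (resolution enhancement is a different filter)")
  t <- (seq_along(fid$data) - 1) * fid$dwell_s
  fid$data <- fid$data * exp(-pi * lb_hz * t)
  append_filter(fid, "exponential_apodization", list(lb_hz = lb_hz))
}

#' Gaussian apodization
#'
#' Multiplies the FID by a Gaussian window `exp(-(pi * gb_hz * t)^2 / (4 ln 2))`
#' which contributes a Gaussian component of FWHM `gb_hz` to the lineshape.
#'
#' @param fid a [raw_fid()].
#' @param gb_hz Gaussian broadening in Hz, >= 0.
#' @return the apodized `raw_fid`.
#' @export
apodize_gaussian <- function(fid, gb_hz) {
  stopifnot(inherits(fid, "raw_fid"))
  if (!is.finite(gb_hz) || gb_hz < 0) stop("gb_hz must be finite and >= 0")
  t <- (seq_along(fid$data) - 1) * fid$dwell_s
  fid$data <- fid$data * exp(-(pi * gb_hz * t)^2 / (4 * log(2)))
  append_filter(fid, "gaussian_apodization", list(gb_hz = gb_hz))
}

#' Default zero-fill size: twice the next power of two
#' @param n current number of points.
#' @return the default zero-fill target.
#' @export
default_zero_fill <- function(n) 2L * 2L^ceiling(log2(n))

#' Zero-filling
#'
#' Pads the FID with trailing zeros, improving the digital resolution of the
#' transformed spectrum (interpolation; no new information).  The default
#' target is twice the next power of two above the current length.
#'
#' @param fid a [raw_fid()].
#' @param target_n total number of points after padding; must be >= the
#'   current length.  `NULL` selects the default.
#' @return the padded `raw_fid`.
#' @export
zero_fill <- function(fid, target_n = NULL) {
  stopifnot(inherits(fid, "raw_fid"))
  n <- length(fid$data)
  if (is.null(target_n)) target_n <- default_zero_fill(n)
  target_n <- as.integer(target_n)
  if (target_n < n) stop("target_n < current length: truncation is not zero-filling")
  fid$data <- c(fid$data, complex(real = rep(0, target_n - n)))
  append_filter(fid, "zero_fill", list(target_n = target_n))
}

#' Fourier transform of a raw FID
#'
#' Discrete Fourier transform with the frequency axis centered at the
#' carrier.  The first time-domain point is halved before the transform
#' (suppresses the constant offset a one-sided DFT would otherwise add to
#' the baseline), and a recorded digital-filter group delay is compensated
#' by the equivalent frequency-proportional phase ramp.  The ppm axis is
#' stored strictly descending (NMR plotting convention).
#'
#' @param fid a [raw_fid()].
#' @return a `spectrum1d`.
#' @export
fourier_transform <- function(fid) {
  stopifnot(inherits(fid, "raw_fid"))
  x <- fid$data
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
    stop("non-finite samples in FID")
  n <- length(x)
  x[1] <- x[1] * 0.5
  sp <- stats::fft(x)
  g <- fid$group_delay_pts
  if (!is.null(g) && is.finite(g) && g != 0) {
    k <- 0:(n - 1)
    sp <- sp * exp(2i * pi * k * g / n)
  }
  k <- 0:(n - 1)
  f_signed <- ((k + floor(n / 2)) %% n - floor(n / 2)) * fid$sw_hz / n
  ord <- order(f_signed)
  sp <- sp[ord]
  f <- f_signed[ord]
  ppm <- fid$center_ppm + f / fid$sfo1_mhz
  # descending ppm left to right
  sp <- rev(sp)
  ppm <- rev(ppm)
  chain <- c(fid$chain, list(filter_record("fourier_transform", list())))
  new_spectrum1d(sp, ppm, fid$sfo1_mhz, fid$sw_hz, fid$nucleus, fid$solvent,
                 fid$center_ppm, chain)
}

#' Phase correction
#'
#' Applies zero-order (`ph0_deg`) and first-order (`ph1_deg`) phase
#' correction: each point is multiplied by
#' `exp(i * (ph0 + ph1 * (x - pivot) / sw_ppm))` with angles in degrees.
#' `ph1_deg` is the phase change across the full spectral width; it is zero
#' at the pivot.
#'
#' @param spec a `spectrum1d`.
#' @param ph0_deg zero-order phase in degrees.
#' @param ph1_deg first-order phase in degrees across the spectral width.
#' @param pivot_ppm pivot position in ppm (default: center of the axis).
#' @return the phased `spectrum1d`.
#' @export
phase_correct <- function(spec, ph0_deg, ph1_deg = 0, pivot_ppm = NULL) {
  stopifnot(inherits(spec, "spectrum1d"))
  if (is.null(pivot_ppm)) pivot_ppm <- spec$center_ppm
  if (pivot_ppm > max(spec$ppm) || pivot_ppm < min(spec$ppm))
    stop("pivot_ppm outside the spectrum axis")
  sw_ppm <- spec$sw_hz / spec$sfo1_mhz
  ang <- (ph0_deg + ph1_deg * (spec$ppm - pivot_ppm) / sw_ppm) * pi / 180
  spec$data <- spec$data * exp(1i * ang)
  append_filter(spec, "phase", list(ph0_deg = ph0_deg, ph1_deg = ph1_deg,
                                    pivot_ppm = pivot_ppm))
}

#' Automatic phase correction
#'
#' Estimates the zero- and first-order phases that bring the spectrum to
#' pure absorption.  The objective — evaluated over the signal regions
#' only, so that baseline noise cannot swamp it — penalizes negative area
#' of the real part plus the entropy of its first derivative.  Candidate
#' starting points come from (a) a 2-degree grid search on ph0 and (b) a
#' weighted linear fit of the local dephasing angles measured at the
#' strongest peaks (each angle taken from the complex sum over a window
#' symmetric about the line, which cancels the steep dispersive phase
#' gradient across a Lorentzian); both are refined by Nelder-Mead simplex
#' and the better optimum returned.  The pivot is the tallest magnitude
#' peak.
#'
#' @param spec a `spectrum1d` with at least one peak above the noise.
#' @return list with `ph0_deg`, `ph1_deg` (corrections to feed to
#'   [phase_correct()]) and `pivot_ppm`.
#' @export
auto_phase <- function(spec) {
  stopifnot(inherits(spec, "spectrum1d"))
  y <- spec$data
  n <- length(y)
  mag <- Mod(y)
  ns <- estimate_noise_vec(Re(y))
  ns <- max(ns, estimate_noise_vec(Im(y)), .Machine$double.eps)
  if (max(mag) < 10 * ns)
    stop("no signal to phase")
  ipk <- which.max(mag)
  pivot <- spec$ppm[ipk]
  sw_ppm <- spec$sw_hz / spec$sfo1_mhz
  u <- (spec$ppm - pivot) / sw_ppm

  # magnitude FWHM of the tallest line, in bins
  half <- mag[ipk] / 2
  l <- ipk; while (l > 1 && mag[l - 1] > half) l <- l - 1
  r <- ipk; while (r < n && mag[r + 1] > half) r <- r + 1
  fwhm_bins <- max(2L, r - l)
  win <- 2L * fwhm_bins

  # signal mask: magnitude above 3x noise, dilated by one window
  sigpts <- which(mag > 3 * ns)
  mask <- rep(FALSE, n)
  for (i in sigpts) mask[max(1, i - win):min(n, i + win)] <- TRUE
  if (!any(mask)) mask <- rep(TRUE, n)
  ym <- y[mask]
  um <- u[mask]

  obj <- function(p) {
    rr <- Re(ym * exp(1i * (p[1] + p[2] * um) * pi / 180))
    tot <- sum(rr * rr)
    if (tot <= 0) return(Inf)
    neg <- sum(pmin(rr, 0)^2) / tot
    h <- abs(diff(rr))
    s <- sum(h)
    ent <- 0
    if (s > 0) {
      h <- h[h > 0] / s
      ent <- -sum(h * log(h)) / log(length(rr))
    }
    1000 * neg + ent
  }

  # (a) coarse ph0 grid at ph1 = 0, then simplex
  grid <- seq(-179, 179, by = 2)
  vals <- vapply(grid, function(a) obj(c(a, 0)), numeric(1))
  p_a <- c(grid[which.min(vals)], 0)
  o_a <- stats::optim(p_a, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))

  # (b) multiplet-cluster phase regression: peaks are grouped into
  # clusters (one per multiplet); the complex sum over a symmetric window
  # around each whole cluster cancels the dispersive tails both of its own
  # lines and between them
  pk <- sort(local_maxima(mag)[mag[local_maxima(mag)] > 10 * ns])
  o_b <- NULL
  if (length(pk) >= 1) {
    gap_bins <- max(2L * win, ceiling(30 / (spec$sw_hz / n)))
    cl_id <- cumsum(c(1L, diff(pk) > gap_bins))
    th <- wgt <- ucl <- numeric(max(cl_id))
    for (k in seq_len(max(cl_id))) {
      mem <- pk[cl_id == k]
      # window symmetric about the magnitude centroid, so the odd
      # dispersive component of each line integrates to zero
      ctr <- round(sum(mem * mag[mem]) / sum(mag[mem]))
      halfspan <- max(abs(mem - ctr)) + win
      i1 <- max(1, ctr - halfspan)
      i2 <- min(n, ctr + halfspan)
      idx <- i1:i2
      w <- mag[idx]                     # matched-filter weights
      s <- sum(w * y[idx])
      th[k] <- Arg(s) * 180 / pi
      wgt[k] <- Mod(s)^2 / sum(w^2)     # ~ inverse angle variance
      ucl[k] <- sum(u[mem] * mag[mem]) / sum(mag[mem])
    }
    ref <- th[which.max(wgt)]
    th <- ((th - ref + 180) %% 360) - 180 + ref   # unwrap about tallest
    start <- if (length(th) >= 2) {
      # refine the weighted fit on the wrapped cluster-angle residual
      obj_cl <- function(p) {
        res <- th + p[1] + p[2] * ucl
        res <- ((res + 180) %% 360) - 180
        sum(wgt * res^2)
      }
      fit <- stats::lm.wfit(cbind(1, ucl), th, wgt)
      s0 <- c(-fit$coefficients[1], -fit$coefficients[2])
      s0[is.na(s0)] <- 0
      stats::optim(s0, obj_cl, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12))$par
    } else c(-th[1], 0)
    start[is.na(start)] <- 0
    o_b <- list(par = start, value = obj(start))
  }
  # prefer the cluster-regression solution; fall back to the grid branch
  # when it is clearly worse on the absorption objective
  best <- if (!is.null(o_b) && o_b$value < o_a$value * 1.5) o_b else o_a
  ph0 <- ((best$par[1] + 180) %% 360) - 180
  list(ph0_deg = unname(ph0), ph1_deg = unname(best$par[2]),
       pivot_ppm = pivot)
}

local_maxima <- function(r) {
  n <- length(r)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[r[i] > r[i - 1] & r[i] >= r[i + 1]]
}

# robust noise scale of a numeric vector (quiet-window MAD); internal
estimate_noise_vec <- function(r, w = 32L) {
  n <- length(r)
  if (n < 2L * w) return(stats::mad(r))
  nw <- n %/% w
  m <- matrix(r[seq_len(nw * w)], nrow = w)
  sds <- apply(m, 2, stats::sd)
  k <- max(1L, nw %/% 10L)
  quiet <- order(sds)[seq_len(k)]
  1.26 * stats::mad(as.vector(m[, quiet, drop = FALSE]))
}

#' Baseline correction
#'
#' Estimates and subtracts a slowly varying baseline from the real part.
#' `"polynomial"` iteratively fits a low-degree polynomial, after each pass
#' down-selecting to points whose residual lies below mean + 2 sd (so peaks
#' drop out of the fit).  `"airpls"` is adaptive iteratively reweighted
#' penalized least squares on a Whittaker smoother.
#'
#' @param spec a `spectrum1d`.
#' @param method `"polynomial"` or `"airpls"`.
#' @param degree polynomial degree (polynomial method).
#' @param iterations number of reweighting passes.
#' @param lambda roughness penalty (airpls method).
#' @return the corrected `spectrum1d`; the baseline estimate is kept in
#'   `$baseline_estimate` for inspection.
#' @export
baseline_correct <- function(spec, method = c("polynomial", "airpls"),
                             degree = 3, iterations = 10, lambda = 1e7) {
  stopifnot(inherits(spec, "spectrum1d"))
  method <- match.arg(method)
  r <- Re(spec$data)
  n <- length(r)
  if (method == "polynomial") {
    if (degree >= n) stop("polynomial degree must be < number of points")
    x <- seq(-1, 1, length.out = n)
    X <- stats::poly(x, degree = degree, raw = FALSE)
    X <- cbind(1, X)
    keep <- rep(TRUE, n)
    base <- rep(0, n)
    for (it in seq_len(iterations)) {
      fit <- stats::lm.fit(X[keep, , drop = FALSE], r[keep])
      base <- drop(X %*% fit$coefficients)
      resid <- r - base
      thr <- mean(resid[keep]) + 2 * stats::sd(resid[keep])
      keep2 <- resid < thr
      if (sum(keep2) <= degree + 1) break
      keep <- keep2
    }
  } else {
    base <- airpls_baseline(r, lambda = lambda, iterations = iterations)
  }
  spec$data <- complex(real = r - base, imaginary = Im(spec$data))
  spec$baseline_estimate <- base
  append_filter(spec, "baseline",
                list(method = method, degree = degree,
                     iterations = iterations, lambda = lambda))
}

airpls_baseline <- function(y, lambda = 1e7, iterations = 10) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iterations)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    d <- y - z
    neg <- d < 0
    s <- sum(abs(d[neg]))
    if (s <= 1e-12 * sum(abs(y))) break
    w <- ifelse(neg, exp(it * abs(d) / s), 0)
    w[1] <- w[n] <- 1
  }
  z
}

#' Re-reference the chemical shift axis
#'
#' Shifts the ppm axis so that a chosen position (typically a reference peak
#' such as TMS) lands at a target chemical shift.
#'
#' @param spec a `spectrum1d`.
#' @param from_ppm current position of the reference peak.
#' @param to_ppm desired position, e.g. `0` for TMS.
#' @return the re-referenced `spectrum1d`.
#' @export
reference_shift <- function(spec, from_ppm, to_ppm) {
  stopifnot(inherits(spec, "spectrum1d"))
  d <- to_ppm - from_ppm
  spec$ppm <- spec$ppm + d
  spec$center_ppm <- spec$center_ppm + d
  append_filter(spec, "reference_shift",
                list(from_ppm = from_ppm, to_ppm = to_ppm))
}

#' Execute a filter chain on a raw FID
#'
#' Deterministically re-executes an ordered list of [filter_record()]s on a
#' raw FID.  Time-domain filters must precede the (single) Fourier
#' transform; frequency-domain filters must follow it.  Disabled records
#' are skipped.  Re-execution is bit-deterministic, so editing one record's
#' parameters and re-applying gives exactly the spectrum that the edited
#' chain would have produced from scratch.
#'
#' @param fid a [raw_fid()] (its own recorded chain is ignored).
#' @param chain list of [filter_record()]s.
#' @return a `spectrum1d` if the chain contains a Fourier transform,
#'   otherwise a `raw_fid`.
#' @export
apply_chain <- function(fid, chain) {
  stopifnot(inherits(fid, "raw_fid"))
  td <- c("exponential_apodization", "gaussian_apodization", "zero_fill")
  fd <- c("phase", "baseline", "reference_shift")
  n_ft <- sum(vapply(chain, function(f) f$name == "fourier_transform", logical(1)))
  if (n_ft > 1) stop("at most one fourier_transform allowed in a chain")
  seen_ft <- FALSE
  for (f in chain) {
    if (!inherits(f, "filter_record")) stop("chain must contain filter_record objects")
    if (f$name == "fourier_transform") seen_ft <- TRUE
    if (f$name %in% fd && !seen_ft)
      stop("frequency-domain filter before fourier_transform: ", f$name)
    if (f$name %in% td && seen_ft)
      stop("time-domain filter after fourier_transform: ", f$name)
  }
  obj <- fid
  obj$chain <- list()
  for (f in chain) {
    if (!f$enabled) next
    p <- f$params
    obj <- switch(f$name,
      exponential_apodization = apodize_exponential(obj, p$lb_hz),
      gaussian_apodization = apodize_gaussian(obj, p$gb_hz),
      zero_fill = zero_fill(obj, p$target_n),
      fourier_transform = fourier_transform(obj),
      phase = phase_correct(obj, p$ph0_deg, p$ph1_deg, p$pivot_ppm),
      baseline = baseline_correct(obj, p$method, p$degree, p$iterations,
                                  p$lambda),
      reference_shift = reference_shift(obj, p$from_ppm, p$to_ppm))
  }
  obj$chain <- chain
  obj
}

#' Distance between two axis positions in Hz
#'
#' @param spec a `spectrum1d`.
#' @param x1_ppm,x2_ppm positions in ppm, both within the axis.
#' @return `|x1 - x2| * sfo1_mhz` in Hz.
#' @export
delta_hz <- function(spec, x1_ppm, x2_ppm) {
  stopifnot(inherits(spec, "spectrum1d"))
  lo <- min(spec$ppm); hi <- max(spec$ppm)
  if (x1_ppm < lo || x1_ppm > hi || x2_ppm < lo || x2_ppm > hi)
    stop("positions must lie within the spectrum axis")
  abs(x1_ppm - x2_ppm) * spec$sfo1_mhz
}
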