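#' Declare a first-order spin system
#'
#' A spin system is a list of signals, each with a chemical shift, a proton
#' count, and a list of scalar couplings.  Splitting is built to first
#' order: every coupling to `n_partners` equivalent protons multiplies the
#' stick pattern by an (n_partners + 1)-line binomial.
#'
#' @param signals list of signals; each is a list with `delta_ppm`,
#'   `n_protons`, and optional `couplings` = list of `list(j_hz, n_partners)`.
#' @param t2_s transverse relaxation time in seconds; the Lorentzian
#'   linewidth is `1 / (pi * t2_s)`.
#' @return an object of class `spin_system`.
#' @export
spin_system <- function(signals, t2_s = 1) {
  stopifnot(length(signals) >= 1, t2_s > 0)
  for (s in signals) {
    if (is.null(s$delta_ppm) || is.null(s$n_protons) || s$n_protons < 1)
      stop("each signal needs delta_ppm and n_protons >= 1")
    for (cp in s$couplings %||% list())
      if (cp$j_hz <= 0 || cp$n_partners < 1)
        stop("couplings need j_hz > 0 and n_partners >= 1")
  }
  structure(list(signals = signals, t2_s = t2_s), class = "spin_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' @param sfo1_mhz observe frequency in MHz.
#' @param sw_hz spectral width in Hz.
#' @param td number of complex time-domain points (>= 64).
#' @param noise_sigma standard deviation of the complex Gaussian noise added
#'   to each quadrature of the FID.
#' @param seed integer RNG seed; mandatory so simulations are reproducible.
#' @param center_ppm carrier position; `NULL` centers on the mean shift of
#'   the system being simulated.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(sfo1_mhz = 400, sw_hz = 4000, td = 8192,
                       noise_sigma = 0, seed = 1L, center_ppm = NULL) {
  stopifnot(td >= 64, sw_hz > 0, sfo1_mhz > 0, noise_sigma >= 0)
  structure(list(sfo1_mhz = sfo1_mhz, sw_hz = sw_hz, td = as.integer(td),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 center_ppm = center_ppm), class = "sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# stick pattern of one signal: data.frame(offset_hz, intensity)
signal_sticks <- function(sig) {
  off <- 0
  int <- sig$n_protons
  for (cp in sig$couplings %||% list()) {
    n <- cp$n_partners
    w <- choose(n, 0:n) / 2^n
    o <- (0:n - n / 2) * cp$j_hz
    off <- as.vector(outer(off, o, `+`))
    int <- as.vector(outer(int, w, `*`))
  }
  list(offset_hz = off, intensity = int)
}

#' Simulate a free induction decay from a spin system
#'
#' Builds each signal's first-order stick pattern (iterated binomial
#' convolution of its splittings), sums damped complex exponentials
#' `I_k exp(i 2 pi nu_k t) exp(-t / T2)` and adds seeded complex circular
#' Gaussian noise.  The stick intensities of a signal sum to its proton
#' count, so the time-domain amplitude at t = 0 is proportional to the
#' total number of protons.
#'
#' @param sys a [spin_system()].
#' @param cfg a [sim_config()].
#' @return a [raw_fid()].
#' @export
simulate_fid <- function(sys, cfg) {
  stopifnot(inherits(sys, "spin_system"), inherits(cfg, "sim_config"))
  deltas <- vapply(sys$signals, function(s) s$delta_ppm, numeric(1))
  center <- cfg$center_ppm %||% mean(range(deltas))
  dt <- 1 / cfg$sw_hz
  t <- (0:(cfg$td - 1)) * dt
  acc <- complex(real = rep(0, cfg$td))
  for (sig in sys$signals) {
    st <- signal_sticks(sig)
    nu <- (sig$delta_ppm - center) * cfg$sfo1_mhz + st$offset_hz
    if (any(abs(nu) >= cfg$sw_hz / 2))
      stop("signal line outside the spectral width")
    for (k in seq_along(nu))
      acc <- acc + st$intensity[k] * exp(2i * pi * nu[k] * t)
  }
  acc <- acc * exp(-t / sys$t2_s)
  if (cfg$noise_sigma > 0) {
    noise <- with_seed(cfg$seed, complex(
      real = stats::rnorm(cfg$td, sd = cfg$noise_sigma),
      imaginary = stats::rnorm(cfg$td, sd = cfg$noise_sigma)))
    acc <- acc + noise
  }
  raw_fid(acc, sw_hz = cfg$sw_hz, sfo1_mhz = cfg$sfo1_mhz,
          nucleus = "1H", solvent = "simulated", center_ppm = center)
}

#' Noise level for a target spectral signal-to-noise ratio
#'
#' Computes the time-domain `noise_sigma` that makes the tallest line of the
#' simulated spectrum reach the requested S/N after plain FT (no
#' apodization), using the spectrometer convention
#' `S/N = peak height / (2 x rms noise)`.  Peak height is the coherent sum
#' `sum(exp(-t/T2))` of the tallest stick; spectral rms noise is
#' `sigma * sqrt(td)`.
#'
#' @param sys a [spin_system()].
#' @param cfg a [sim_config()] (its `noise_sigma` is ignored).
#' @param snr target signal-to-noise ratio of the tallest line.
#' @return noise sigma to put into the configuration.
#' @export
noise_sigma_for_snr <- function(sys, cfg, snr) {
  stopifnot(snr > 0)
  tallest <- max(vapply(sys$signals,
                        function(s) max(signal_sticks(s)$intensity),
                        numeric(1)))
  t <- (0:(cfg$td - 1)) / cfg$sw_hz
  height <- tallest * sum(exp(-t / sys$t2_s))
  height / (2 * snr * sqrt(cfg$td))
}

#' Exact AB two-spin pattern
#'
#' Closed-form solution for two strongly coupled spins: with
#' `C = sqrt(delta_nu^2 + j^2)`, the four lines sit at offsets
#' `+-(C + j)/2` and `+-(C - j)/2` about the center, with intensities
#' `1 - j/C` (outer) and `1 + j/C` (inner).  This is the second-order
#' oracle that the first-order engine cannot produce; in the limits it
#' degenerates to a singlet (`delta_nu = 0`) or two equal singlets
#' (`j = 0`).
#'
#' @param delta_nu_hz chemical-shift difference in Hz, >= 0.
#' @param j_hz coupling constant in Hz, >= 0.
#' @return data.frame with `offset_hz` (about the pattern center) and
#'   `intensity` for the four transitions.
#' @export
simulate_ab <- function(delta_nu_hz, j_hz) {
  stopifnot(delta_nu_hz >= 0, j_hz >= 0)
  C <- sqrt(delta_nu_hz^2 + j_hz^2)
  inner_int <- if (C > 0) 1 + j_hz / C else 1
  outer_int <- if (C > 0) 1 - j_hz / C else 1
  data.frame(
    offset_hz = c(-(C + j_hz) / 2, -(C - j_hz) / 2,
                  (C - j_hz) / 2, (C + j_hz) / 2),
    intensity = c(outer_int, inner_int, inner_int, outer_int)
  )
}

#' Write a ready-to-use exercise fixture
#'
#' Simulates the given spin systems, processes them with a plain
#' zero-fill + FT chain, and writes JCAMP-DX spectra together with the
#' solution molfile in the folder layout that [build_toc()] consumes.
#'
#' @param systems list of [spin_system()]s (one JCAMP-DX file each).
#' @param cfg a [sim_config()].
#' @param dir output exercise folder (created if needed).
#' @param molfile character scalar: V2000 molfile text of the solution.
#' @param name base name for the spectra files.
#' @return invisibly, the paths written.
#' @export
make_exercise_fixture <- function(systems, cfg, dir, molfile,
                                  name = "spectrum") {
  if (inherits(systems, "spin_system")) systems <- list(systems)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(systems)) {
    fid <- simulate_fid(systems[[i]], cfg)
    spec <- fourier_transform(zero_fill(fid))
    blk <- spectrum_to_jcamp_block(spec, title = sprintf("%s %d", name, i))
    p <- file.path(dir, sprintf("%s-%d.jdx", name, i))
    writeLines(write_jcamp(blk, compression = "dif_dup"), p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "solution.mol")
  writeLines(molfile, mp)
  invisible(c(paths, mp))
}
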