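test_that("exponential apodization broadens lines by exactly lb", {
  s <- sim_singlet(t2 = 1, sw = 200, td = 4096)
  f0 <- apodize_exponential(s$fid, 0)
  expect_identical(f0$data, s$fid$data)
  expect_error(apodize_exponential(s$fid, -1), "lb_hz")
  spec1 <- fourier_transform(zero_fill(apodize_exponential(s$fid, 1), 16384))
  expect_equal(measure_fwhm_hz(spec1), 1 / pi + 1, tolerance = 0.05)
})

test_that("apodization reduces noise in the transformed spectrum", {
  cfg <- sim_config(sw_hz = 1000, td = 4096, noise_sigma = 1, seed = 31)
  sys <- spin_system(list(list(delta_ppm = 0, n_protons = 1)), t2_s = 0.2)
  fid <- simulate_fid(sys, cfg)
  sd0 <- sd(Re(fourier_transform(fid)$data[1:1000]))
  sd5 <- sd(Re(fourier_transform(apodize_exponential(fid, 5))$data[1:1000]))
  expect_lt(sd5, sd0)
})

test_that("zero filling pads, interpolates and never truncates", {
  s <- sim_singlet(sw = 500, td = 512, delta = 2.6)
  zf <- zero_fill(s$fid, 1024)
  expect_length(zf$data, 1024)
  expect_true(all(zf$data[513:1024] == 0))
  expect_error(zero_fill(s$fid, 256), "truncation")
  # default rule: twice the next power of two
  expect_equal(default_zero_fill(700), 2048)
  f700 <- raw_fid(complex(real = rnorm(700)), sw_hz = 1000, sfo1_mhz = 400)
  expect_length(zero_fill(f700)$data, 2048)
  # peak position is stable under zero filling within one post-fill bin
  p1 <- pick_peaks(fourier_transform(zero_fill(s$fid, 2048)), 10)
  p2 <- pick_peaks(fourier_transform(zero_fill(s$fid, 8192)), 10)
  expect_lt(abs(p1$x_ppm[which.max(p1$intensity)] -
                  p2$x_ppm[which.max(p2$intensity)]), 500 / 2048 / 400)
})

test_that("the Fourier transform places a complex exponential at its offset", {
  sw <- 1000; td <- 2048
  t <- (0:(td - 1)) / sw
  fid <- raw_fid(exp(2i * pi * 100 * t) * exp(-t / 0.5),
                 sw_hz = sw, sfo1_mhz = 400, center_ppm = 0)
  spec <- fourier_transform(fid)
  i <- which.max(Mod(spec$data))
  expect_lt(abs(spec$ppm[i] * 400 - 100), spec$digital_resolution_hz)
  # linearity: the all-zero FID transforms to the all-zero spectrum
  z <- raw_fid(complex(real = rep(0, 64)), sw_hz = 100, sfo1_mhz = 400)
  expect_true(all(fourier_transform(z)$data == 0))
  # ppm axis is strictly descending
  expect_true(all(diff(spec$ppm) < 0))
})

test_that("component amplitudes carry through to integrated areas", {
  sys <- spin_system(list(list(delta_ppm = 1, n_protons = 2),
                          list(delta_ppm = 3, n_protons = 1)), t2_s = 0.7)
  cfg <- sim_config(sw_hz = 2000, td = 16384, seed = 1)
  spec <- fourier_transform(zero_fill(simulate_fid(sys, cfg)))
  r <- integrate_region(spec, 1.2, 0.8) / integrate_region(spec, 3.2, 2.8)
  expect_equal(r, 2, tolerance = 0.01)
})

test_that("Parseval holds for the chosen transform normalization", {
  set.seed(77)
  for (k in 1:5) {
    n <- sample(c(256, 500, 1024), 1)
    fid <- raw_fid(complex(real = rnorm(n), imaginary = rnorm(n)),
                   sw_hz = 1000, sfo1_mhz = 400)
    spec <- fourier_transform(fid)
    x <- fid$data; x[1] <- x[1] * 0.5
    expect_equal(sum(Mod(x)^2), sum(Mod(spec$data)^2) / n,
                 tolerance = 1e-9)
  }
})

test_that("phase correction is a group action with identity and inverse", {
  spec <- singlet_comb_spectrum(snr = 500, seed = 2)
  id <- phase_correct(spec, 0, 0, 4)
  expect_equal(id$data, spec$data)
  fwd <- phase_correct(spec, 30, 0, 4)
  back <- phase_correct(fwd, -30, 0, 4)
  expect_equal(back$data, spec$data, tolerance = 1e-12)
  # dephasing lowers the real maximum; re-phasing restores it
  de <- phase_correct(spec, 37, 0, 4)
  expect_lt(max(Re(de$data)), max(Re(spec$data)))
  re <- phase_correct(de, -37, 0, 4)
  expect_equal(max(Re(re$data)), max(Re(spec$data)), tolerance = 1e-9)
  expect_error(phase_correct(spec, 10, 0, pivot_ppm = 99), "pivot")
})

test_that("automatic phasing recovers known dephasing", {
  spec <- singlet_comb_spectrum(snr = 100, seed = 7)
  pivot <- spec$ppm[which.max(Mod(spec$data))]
  # zero-order only
  ap <- auto_phase(phase_correct(spec, 25, 0, pivot))
  expect_lt(abs(ap$ph0_deg + 25), 1)
  expect_lt(abs(ap$ph1_deg), 1)
  # already phased: the fixed point
  ap0 <- auto_phase(spec)
  expect_lt(abs(ap0$ph0_deg), 1)
  expect_lt(abs(ap0$ph1_deg), 1)
  # mixed orders
  ap2 <- auto_phase(phase_correct(spec, 40, 60, pivot))
  expect_lt(abs(ap2$ph0_deg + 40), 3)
  expect_lt(abs(ap2$ph1_deg + 60), 3)
  # applying the answer is locally optimal against 5-degree perturbations
  # (negative-area fraction measured over the signal regions, where it is
  # phase-sensitive rather than noise-dominated)
  de <- phase_correct(spec, 40, 60, pivot)
  sigmask <- Mod(spec$data) > 5 * estimate_noise(spec)$std
  sigmask <- which(sigmask)
  sigmask <- unique(unlist(lapply(sigmask, function(i)
    max(1, i - 20):min(length(spec$data), i + 20))))
  negfrac <- function(s) {
    r <- Re(s$data)[sigmask]; sum(pmin(r, 0)^2) / sum(r^2)
  }
  base <- negfrac(phase_correct(de, ap2$ph0_deg, ap2$ph1_deg, ap2$pivot_ppm))
  for (d in list(c(5, 0), c(-5, 0), c(0, 5), c(0, -5))) {
    pert <- negfrac(phase_correct(de, ap2$ph0_deg + d[1],
                                  ap2$ph1_deg + d[2], ap2$pivot_ppm))
    expect_lte(base, pert)
  }
  # noise-only input refuses to phase
  nz <- raw_fid(complex(real = rnorm(512), imaginary = rnorm(512)),
                sw_hz = 1000, sfo1_mhz = 400)
  expect_error(auto_phase(fourier_transform(nz)), "no signal")
})

test_that("baseline estimation recovers an added polynomial drift", {
  sys <- spin_system(list(list(delta_ppm = 2, n_protons = 1),
                          list(delta_ppm = 4, n_protons = 2)), t2_s = 0.5)
  cfg <- sim_config(sw_hz = 2000, td = 4096, noise_sigma = 0.02, seed = 9)
  spec <- fourier_transform(zero_fill(simulate_fid(sys, cfg)))
  x <- seq(-1, 1, length.out = length(spec$data))
  drift <- 50 + 80 * x + 120 * x^2
  spoiled <- spec
  spoiled$data <- spec$data + drift
  for (m in c("polynomial", "airpls")) {
    fixed <- baseline_correct(spoiled, m)
    quiet <- abs(fixed$ppm - 3) < 0.5
    expect_lt(sqrt(mean(Re(fixed$data[quiet])^2)),
              0.01 * max(Re(fixed$data)))
    expect_length(fixed$baseline_estimate, length(spec$data))
  }
  # an already-flat spectrum is left essentially unchanged
  flat <- baseline_correct(spec, "polynomial")
  expect_lt(max(abs(Re(flat$data - spec$data))), 0.02 * max(Re(spec$data)))
  # baseline-only input comes back near zero
  only <- spec
  only$data <- complex(real = drift)
  cleaned <- baseline_correct(only, "polynomial")
  expect_lt(max(abs(Re(cleaned$data))), 1)
  expect_error(baseline_correct(spec, "polynomial",
                                degree = length(spec$data)), "degree")
})

test_that("filter chains re-execute deterministically and honor edits", {
  sys <- ethyl_system()
  cfg <- sim_config(sw_hz = 2000, td = 2048, noise_sigma = 0.1, seed = 5)
  fid <- simulate_fid(sys, cfg)
  chain <- list(
    filter_record("exponential_apodization", list(lb_hz = 1)),
    filter_record("zero_fill", list(target_n = 8192)),
    filter_record("fourier_transform", list()),
    filter_record("phase", list(ph0_deg = 10, ph1_deg = 0, pivot_ppm = 2.4)))
  s1 <- apply_chain(fid, chain)
  s2 <- apply_chain(fid, chain)
  expect_identical(s1$data, s2$data)
  # editing one record and re-running equals the directly built chain
  edited <- chain
  edited[[1]]$params$lb_hz <- 2
  s3 <- apply_chain(fid, edited)
  direct <- phase_correct(
    fourier_transform(zero_fill(apodize_exponential(fid, 2), 8192)),
    10, 0, 2.4)
  expect_identical(s3$data, direct$data)
  # disabling a record equals omitting it
  dis <- chain
  dis[[4]]$enabled <- FALSE
  expect_identical(apply_chain(fid, dis)$data,
                   apply_chain(fid, chain[1:3])$data)
  # ordering is validated
  bad <- c(chain[4], chain[1:3])
  expect_error(apply_chain(fid, bad), "phase")
  expect_error(apply_chain(fid, c(chain, chain[3])), "at most one")
})

test_that("linear filters commute with scalar multiplication", {
  s <- sim_singlet(noise = 0.05, seed = 41, td = 512)
  k <- 3.7
  scaled <- s$fid; scaled$data <- scaled$data * k
  a <- fourier_transform(zero_fill(apodize_exponential(scaled, 2), 1024))
  b <- fourier_transform(zero_fill(apodize_exponential(s$fid, 2), 1024))
  expect_equal(a$data, b$data * k, tolerance = 1e-12)
})

test_that("axis distances convert between ppm and Hz via the field", {
  spec <- singlet_comb_spectrum(snr = 500, seed = 2)
  expect_equal(delta_hz(spec, 4.00, 3.99), 4, tolerance = 1e-9)
  expect_equal(delta_hz(spec, 4, 4), 0)
  spec13 <- spec; spec13$sfo1_mhz <- 100
  expect_equal(delta_hz(spec13, 5, 4), 100)
  expect_error(delta_hz(spec, 4, 99), "within")
})

test_that("reference shift moves the axis rigidly", {
  spec <- singlet_comb_spectrum(snr = 500, seed = 2)
  pk <- pick_peaks(spec, 10)
  shifted <- reference_shift(spec, from_ppm = pk$x_ppm[1], to_ppm = 7.27)
  pk2 <- pick_peaks(shifted, 10)
  expect_equal(pk2$x_ppm[1], 7.27, tolerance = 1e-9)
  expect_equal(diff(pk2$x_ppm), diff(pk$x_ppm), tolerance = 1e-12)
})
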