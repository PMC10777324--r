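noise_spectrum <- function(seed, n = 4096, sigma = 1) {
  set.seed(seed)
  fid <- raw_fid(complex(real = rnorm(n, sd = sigma),
                         imaginary = rnorm(n, sd = sigma)),
                 sw_hz = 1000, sfo1_mhz = 400, center_ppm = 5)
  fourier_transform(fid)
}

test_that("the noise estimator tracks sigma and ignores peaks", {
  ests <- vapply(1:10, function(s) {
    sp <- noise_spectrum(s)
    estimate_noise(sp)$std / sd(Re(sp$data))
  }, numeric(1))
  expect_true(all(ests > 0.8 & ests < 1.2))
  # injecting one huge line changes the estimate by less than 10%
  sp <- noise_spectrum(42)
  e0 <- estimate_noise(sp)$std
  sp2 <- sp
  i <- 2000:2010
  sp2$data[i] <- sp2$data[i] + 1e5
  expect_lt(abs(estimate_noise(sp2)$std - e0) / e0, 0.1)
  # degenerate all-zero input is flagged
  z <- fourier_transform(raw_fid(complex(real = rep(0, 256)),
                                 sw_hz = 100, sfo1_mhz = 400))
  ez <- estimate_noise(z)
  expect_equal(ez$std, 0)
  expect_true(isTRUE(attr(ez, "degenerate")))
})

test_that("peak picking finds simulated lines at sub-bin accuracy", {
  s <- sim_singlet(t2 = 1, sw = 400, td = 4096, noise = 0, seed = 2)
  cfg <- s$cfg; cfg$noise_sigma <- noise_sigma_for_snr(s$sys, cfg, 100)
  spec <- fourier_transform(zero_fill(simulate_fid(s$sys, cfg), 16384))
  pk <- pick_peaks(spec, min_snr = 10)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x_ppm - 2.5),
            spec$digital_resolution_hz / spec$sfo1_mhz)
  expect_gt(pk$fwhm_hz, 0)
})

test_that("pure noise rarely yields peaks at a 5 sigma threshold", {
  hits <- vapply(1:100, function(s)
    nrow(pick_peaks(noise_spectrum(s, n = 2048), min_snr = 5)),
    numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("two lines five widths apart resolve into exactly two peaks", {
  sys <- spin_system(list(list(delta_ppm = 3, n_protons = 1),
                          list(delta_ppm = 3 + 5 / pi / 400, n_protons = 1)),
                     t2_s = 1)
  cfg <- sim_config(sw_hz = 400, td = 8192, noise_sigma = 0, seed = 3,
                    center_ppm = 3)
  cfg$noise_sigma <- noise_sigma_for_snr(sys, cfg, 100)
  spec <- fourier_transform(zero_fill(simulate_fid(sys, cfg)))
  pk <- pick_peaks(spec, min_snr = 10, from_ppm = 3.05, to_ppm = 2.95)
  expect_equal(nrow(pk), 2)
})

test_that("trapezoidal integration is exactly additive and bounded on noise", {
  sp <- noise_spectrum(9)      # axis spans 3.75..6.25 ppm
  a <- 6.1; b <- 5.37; cc <- 4.1
  expect_equal(integrate_region(sp, a, cc),
               integrate_region(sp, a, b) + integrate_region(sp, b, cc),
               tolerance = 1e-12)
  expect_equal(integrate_region(sp, 4, 4), 0)
  ns <- estimate_noise(sp)$std
  expect_lt(abs(integrate_region(sp, 6.2, 5.2)), 3 * ns * 1)
  expect_error(integrate_region(sp, 8, 7), "outside")
})

test_that("proton ratios come out of integrals and Lorentzian fits", {
  sys <- spin_system(list(list(delta_ppm = 2, n_protons = 3),
                          list(delta_ppm = 5, n_protons = 2)), t2_s = 1.5)
  cfg <- sim_config(sw_hz = 2400, td = 16384, seed = 1, center_ppm = 3.5)
  cfg$noise_sigma <- noise_sigma_for_snr(sys, cfg, 80)
  spec <- fourier_transform(zero_fill(simulate_fid(sys, cfg)))
  fitratio <- sum(fit_lorentzians(spec, 2.1, 1.9)$area) /
    sum(fit_lorentzians(spec, 5.1, 4.9)$area)
  expect_equal(fitratio, 1.5, tolerance = 0.02)
  # integration is invariant under further zero filling within 1%
  spec2 <- fourier_transform(zero_fill(simulate_fid(sys, cfg), 65536))
  expect_equal(integrate_region(spec, 2.2, 1.8),
               integrate_region(spec2, 2.2, 1.8), tolerance = 0.01)
})

test_that("range detection separates multiplets and normalizes integrals", {
  sys <- spin_system(list(
    list(delta_ppm = 1.2, n_protons = 3,
         couplings = list(list(j_hz = 7, n_partners = 2))),
    list(delta_ppm = 3.6, n_protons = 2,
         couplings = list(list(j_hz = 7, n_partners = 3))),
    list(delta_ppm = 2.1, n_protons = 1,
         couplings = list(list(j_hz = 12, n_partners = 1),
                          list(j_hz = 4, n_partners = 1)))), t2_s = 1)
  cfg <- sim_config(sw_hz = 2000, td = 8192, seed = 7)
  cfg$noise_sigma <- noise_sigma_for_snr(sys, cfg, 100)
  spec <- fourier_transform(zero_fill(simulate_fid(sys, cfg)))
  rs <- detect_ranges(spec, min_snr = 3)
  expect_length(rs, 3)
  # descending ppm order
  froms <- vapply(rs, function(r) r$from_ppm, numeric(1))
  expect_true(all(diff(froms) < 0))
  expect_equal(rs[[1]]$signals[[1]]$multiplicity, "q")
  expect_equal(rs[[2]]$signals[[1]]$multiplicity, "dd")
  expect_equal(rs[[3]]$signals[[1]]$multiplicity, "t")
  rs <- set_relative_integrals(rs, 3, 3)
  rels <- vapply(rs, function(r) r$relative_integral, numeric(1))
  expect_equal(rels, c(2, 1, 3), tolerance = 0.1)
  # an empty spectrum has no ranges
  expect_length(detect_ranges(noise_spectrum(1), min_snr = 5), 0)
})

test_that("first-order patterns classify with accurate couplings", {
  cases <- list(list("d", 7), list("t", 7), list("q", 7), list("s", 0),
                list("dd", 12))
  for (cs in cases) {
    mult <- cs[[1]]; J <- cs[[2]]
    spec <- grid_cell_spectrum(mult, max(J, 2), seed = 5)
    rs <- detect_ranges(spec, min_snr = 3)
    rg <- NULL
    for (r in rs) if (r$from_ppm > 2 && r$from_ppm < 4) rg <- r
    expect_length(rg$signals, 1)
    sig <- rg$signals[[1]]
    expect_equal(sig$multiplicity, mult)
    expect_equal(abs(sig$delta_ppm - 3) < 0.01, TRUE)
    if (mult == "d") expect_equal(sig$j_hz, 7, tolerance = 0.02)
    if (mult == "dd")
      expect_equal(sig$j_hz, c(12, 4), tolerance = 0.02)
    if (mult == "s") expect_length(sig$j_hz, 0)
  }
})

test_that("interleaved equal doublets are resolved as two signals", {
  sys <- spin_system(list(
    list(delta_ppm = 7.20, n_protons = 1,
         couplings = list(list(j_hz = 8, n_partners = 1))),
    list(delta_ppm = 7.23, n_protons = 1,
         couplings = list(list(j_hz = 8, n_partners = 1)))), t2_s = 1)
  cfg <- sim_config(sw_hz = 1000, td = 8192, seed = 11, center_ppm = 7.2)
  cfg$noise_sigma <- noise_sigma_for_snr(sys, cfg, 100)
  spec <- fourier_transform(zero_fill(simulate_fid(sys, cfg)))
  rs <- detect_ranges(spec, min_snr = 3)
  expect_length(rs, 1)
  sig <- rs[[1]]$signals
  expect_length(sig, 2)
  expect_true(all(vapply(sig, function(s) s$multiplicity, "") == "d"))
  js <- vapply(sig, function(s) s$j_hz, numeric(1))
  expect_true(all(abs(js - 8) <= 0.3))
  deltas <- sort(vapply(sig, function(s) s$delta_ppm, numeric(1)))
  expect_equal(deltas, c(7.20, 7.23), tolerance = 0.002)
})

test_that("deconvolution and direct classification agree when lines resolve", {
  spec <- grid_cell_spectrum("t", 10, seed = 8)
  rg <- list(from_ppm = 3.1, to_ppm = 2.9)
  direct <- analyze_multiplet(spec, rg)
  forced <- analyze_multiplet(spec, rg, max_lorentzians = 12)
  fitted <- fit_lorentzians(spec, 3.1, 2.9)
  expect_equal(direct[[1]]$multiplicity, "t")
  expect_equal(nrow(fitted), 3)
  gaps <- diff(sort(fitted$x_ppm)) * 400
  expect_equal(mean(gaps), direct[[1]]$j_hz, tolerance = 0.05)
})

test_that("publication strings follow the journal format", {
  spec <- structure(list(sfo1_mhz = 400, nucleus = "1H", solvent = "CDCl3"),
                    class = "spectrum1d")
  sig <- structure(list(delta_ppm = 7.26, multiplicity = "d", j_hz = 7,
                        intensity_sum = 1, assigned_atoms = integer(0),
                        n_h = 2), class = "nmr_signal")
  rg <- structure(list(from_ppm = 7.3, to_ppm = 7.2,
                       absolute_integral = 1, relative_integral = 2,
                       signals = list(sig)), class = "nmr_range")
  expect_equal(to_publication_string(spec, list(rg)),
               "¹H NMR (400 MHz, CDCl₃) δ 7.26 (d, J = 7.0 Hz, 2H).")
  # ranges are emitted in descending shift regardless of input order
  sig2 <- sig; sig2$delta_ppm <- 2.10; sig2$multiplicity <- "s"
  sig2$j_hz <- numeric(0); sig2$n_h <- 3
  rg2 <- rg; rg2$from_ppm <- 2.2; rg2$to_ppm <- 2.0
  rg2$signals <- list(sig2)
  out <- to_publication_string(spec, list(rg2, rg))
  expect_match(out, "7.26 \\(d.*2.10 \\(s")
  expect_error(to_publication_string(spec, list()), "no ranges")
  rg3 <- rg; rg3$relative_integral <- NA_real_
  expect_error(to_publication_string(spec, list(rg3)), "relative")
})
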