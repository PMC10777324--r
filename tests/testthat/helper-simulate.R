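# shared simulation builders and independent physics oracles

sim_singlet <- function(t2 = 1, sw = 200, td = 4096, zf = 16384,
                        noise = 0, seed = 1, delta = 2.5, sfo1 = 400) {
  sys <- spin_system(list(list(delta_ppm = delta, n_protons = 1)), t2_s = t2)
  cfg <- sim_config(sfo1_mhz = sfo1, sw_hz = sw, td = td,
                    noise_sigma = noise, seed = seed, center_ppm = delta)
  list(sys = sys, cfg = cfg, fid = simulate_fid(sys, cfg))
}

# ethyl pattern: CH2 quartet + CH3 triplet, J = 7 Hz
ethyl_system <- function(t2 = 1) {
  spin_system(list(
    list(delta_ppm = 3.6, n_protons = 2,
         couplings = list(list(j_hz = 7, n_partners = 3))),
    list(delta_ppm = 1.2, n_protons = 3,
         couplings = list(list(j_hz = 7, n_partners = 2)))
  ), t2_s = t2)
}

# comb of well-separated singlets; the standard phase-recovery subject
singlet_comb_spectrum <- function(snr = 100, seed = 7) {
  sys <- spin_system(lapply(c(1, 2.5, 4, 5.5, 7), function(d)
    list(delta_ppm = d, n_protons = 1)), t2_s = 1)
  cfg <- sim_config(sfo1_mhz = 400, sw_hz = 4000, td = 16384,
                    noise_sigma = 0, seed = seed)
  cfg$noise_sigma <- noise_sigma_for_snr(sys, cfg, snr)
  fourier_transform(zero_fill(simulate_fid(sys, cfg)))
}

# measure FWHM of the tallest peak, independent of pick_peaks
measure_fwhm_hz <- function(spec) {
  r <- Re(spec$data)
  i <- which.max(r)
  half <- r[i] / 2
  l <- i; while (l > 1 && r[l - 1] > half) l <- l - 1
  xl <- approx(r[(l - 1):l], spec$ppm[(l - 1):l], xout = half)$y
  rr <- i; while (rr < length(r) && r[rr + 1] > half) rr <- rr + 1
  xr <- approx(r[rr:(rr + 1)], spec$ppm[rr:(rr + 1)], xout = half)$y
  abs(xl - xr) * spec$sfo1_mhz
}

# independent two-spin oracle: numeric diagonalization of the AB
# Hamiltonian, single-quantum transitions only
ab_numeric_oracle <- function(dnu, J) {
  nu1 <- dnu / 2; nu2 <- -dnu / 2
  H <- matrix(0, 4, 4)
  H[1, 1] <- (nu1 + nu2) / 2 + J / 4
  H[2, 2] <- (nu1 - nu2) / 2 - J / 4
  H[3, 3] <- (-nu1 + nu2) / 2 - J / 4
  H[4, 4] <- -(nu1 + nu2) / 2 + J / 4
  H[2, 3] <- H[3, 2] <- J / 2
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors; lam <- e$values
  mz <- diag(t(V) %*% diag(c(1, 0, 0, -1)) %*% V)
  Ix <- matrix(0, 4, 4)
  Ix[1, 2] <- Ix[2, 1] <- Ix[1, 3] <- Ix[3, 1] <- 0.5
  Ix[2, 4] <- Ix[4, 2] <- Ix[3, 4] <- Ix[4, 3] <- 0.5
  M <- t(V) %*% Ix %*% V
  lines <- NULL
  for (a in 1:4) for (b in 1:4) {
    if (abs(mz[a] - mz[b] - 1) < 1e-9 && abs(M[a, b]) > 1e-12)
      lines <- rbind(lines, c(lam[a] - lam[b], 4 * M[a, b]^2))
  }
  lines[order(lines[, 1]), , drop = FALSE]
}

# one multiplet (at 3 ppm) plus a 3H reference singlet (at 6 ppm), with the
# noise level set from the multiplet's own tallest line
grid_cell_spectrum <- function(mult, J, snr = 50, seed = 1) {
  cps <- switch(mult,
    s = NULL,
    d = list(list(j_hz = J, n_partners = 1)),
    t = list(list(j_hz = J, n_partners = 2)),
    q = list(list(j_hz = J, n_partners = 3)),
    dd = list(list(j_hz = J, n_partners = 1),
              list(j_hz = J / 3, n_partners = 1)))
  sig <- list(delta_ppm = 3, n_protons = 2, couplings = cps)
  sys <- spin_system(list(sig, list(delta_ppm = 6, n_protons = 3)),
                     t2_s = 1.5)
  cfg <- sim_config(sfo1_mhz = 400, sw_hz = 2400, td = 16384,
                    noise_sigma = 0, seed = seed, center_ppm = 4.5)
  cfg$noise_sigma <- noise_sigma_for_snr(
    spin_system(list(sig), t2_s = 1.5), cfg, snr)
  fourier_transform(zero_fill(simulate_fid(sys, cfg)))
}
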