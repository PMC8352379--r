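# Separable grid-search oracle for the first-order fit: for each candidate
# tau on a fixed grid, the model T(t) = T0 * e + Tinf * (1 - e) with
# e = exp(-t/tau) is linear in (T0, Tinf), so the conditionally optimal SSE
# has a closed form from the normal equations. Independent of the package's
# Levenberg-Marquardt path.
grid_search_first_order <- function(t, y, taus = seq(1, 200, by = 0.01)) {
  n <- length(t)
  sy <- sum(y)
  syy <- sum(y * y)
  best_sse <- Inf
  best_tau <- NA_real_
  for (chunk in split(taus, ceiling(seq_along(taus) / 2000))) {
    E <- exp(-outer(t, chunk, "/"))
    s_e <- colSums(E)
    s_e2 <- colSums(E * E)
    s_ey <- colSums(E * y)
    a11 <- s_e2
    a12 <- s_e - s_e2
    a22 <- n - 2 * s_e + s_e2
    b1 <- s_ey
    b2 <- sy - s_ey
    det <- a11 * a22 - a12 * a12
    t0 <- (b1 * a22 - b2 * a12) / det
    tinf <- (a11 * b2 - a12 * b1) / det
    sse <- syy - (t0 * b1 + tinf * b2)
    i <- which.min(sse)
    if (sse[i] < best_sse) {
      best_sse <- sse[i]
      best_tau <- chunk[i]
    }
  }
  list(sse = best_sse, tau = best_tau)
}

# Brute-force circular ROI membership: scan every pixel of the frame.
brute_force_roi_members <- function(center, diameter, frame_dim) {
  out <- list()
  radius <- diameter / 2
  for (r in seq_len(frame_dim[1])) {
    for (c in seq_len(frame_dim[2])) {
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2 + 1e-9) {
        out[[length(out) + 1]] <- c(r, c)
      }
    }
  }
  do.call(rbind, out)
}

# Canonical string form of a pixel set for set comparison.
pixel_set_key <- function(m) sort(paste(m[, 1], m[, 2], sep = ","))

# Group parameters with no between-animal spread, for fixed-truth traces.
fixed_params <- function(t0, tinf, tau, wavelength = NA_real_,
                         injection = NA_character_) {
  list(t0_mean = t0, t0_sd = 0, tinf_mean = tinf, tinf_sd = 0,
       tau_mean = tau, tau_sd = 0, wavelength = wavelength,
       injection = injection)
}
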