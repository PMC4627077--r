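# shared fixtures and independent oracles

row1 <- function() reference_rates(1)   # k12 36, k_m12 3.6, k3 15.4, k4 19.6
row2 <- function() reference_rates(2)   # k12 100, k_m12 120, k3 19.9, k4 19.6

fast_grid <- function(t_max = 1.5) default_time_grid(t_max)

# matrix-exponential solution of the linearized R -> B -> C -> PRE chain at
# constant TC (pseudo-first-order); independent of the ODE solver
expm_chain <- function(rates, conc_70SIC, conc_TC, time_grid) {
  A <- rbind(c(-rates$k12 * conc_TC, rates$k_m12, 0, 0),
             c(rates$k12 * conc_TC, -(rates$k_m12 + rates$k3), 0, 0),
             c(0, rates$k3, -rates$k4, 0),
             c(0, 0, rates$k4, 0))
  x0 <- c(conc_70SIC, 0, 0, 0)
  out <- t(vapply(time_grid,
                  function(t) as.vector(Matrix::expm(A * t) %*% x0),
                  numeric(4)))
  colnames(out) <- c("R", "B", "C", "PRE")
  out
}

# closed-form irreversible second-order association R + T -> B
second_order_B <- function(k, R0, T0, t) {
  if (abs(R0 - T0) < 1e-12) return(R0 - R0 / (1 + k * R0 * t))
  e <- exp((T0 - R0) * k * t)
  R0 * T0 * (e - 1) / (T0 * e - R0)
}

# the two nonzero eigenvalue magnitudes of the linearized binding chain,
# the oracle for the biexponential apparent rates
chain_eigenrates <- function(rates, conc_TC) {
  M <- rbind(c(-rates$k12 * conc_TC, rates$k_m12),
             c(rates$k12 * conc_TC, -(rates$k_m12 + rates$k3)))
  sort(abs(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
}

# build an sm_trace by hand from per-frame intensities
make_sm_trace <- function(I_cy3, I_cy5, frame_interval = 0.011,
                          injection_frame = 0L, total_intensity = NULL) {
  n <- length(I_cy3)
  total <- I_cy3 + I_cy5
  ref <- total_intensity %||% max(total)
  fret <- ifelse(total >= 0.5 * ref, I_cy5 / total, 0)
  out <- tibble::tibble(frame = seq_len(n) - 1L,
                        time_s = (seq_len(n) - 1L - injection_frame) * frame_interval,
                        I_cy3 = I_cy3, I_cy5 = I_cy5, fret = fret)
  attr(out, "frame_interval") <- frame_interval
  attr(out, "injection_frame") <- injection_frame
  attr(out, "total_intensity") <- ref
  attr(out, "noise_sigma") <- 0
  class(out) <- c("sm_trace", class(out))
  out
}

# step trace: bound (constant two-channel emission) during [start, end) frames
step_trace <- function(n_frames, start, end, E = 0.9, I_tot = 1000) {
  w <- numeric(n_frames)
  w[(start + 1):end] <- 1
  make_sm_trace(I_cy3 = w * (1 - E) * I_tot, I_cy5 = w * E * I_tot,
                total_intensity = I_tot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
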