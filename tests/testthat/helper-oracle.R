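# Independent brute-force oracle for the compartment model: explicit Euler
# integration at a small fixed step, written against the model equations
# directly (no shared code with the package's closed-form solver).

euler_traces <- function(spec, protocol, dt = 0.001) {
  ft <- frame_times(protocol)
  dur <- protocol_duration(protocol)
  n_steps <- round(dur / dt)
  sinuses <- sinus_regions()
  regions <- c("nasal_left", "nasal_right", sinuses)
  kin <- spec$kinetics[match(sinuses, spec$kinetics$region), ]
  ceq <- kin$c_eq
  side_nasal <- ifelse(endsWith(sinuses, "_L"), "nasal_left", "nasal_right")
  s <- 1 / spec$nasal_tau_s

  phases <- protocol$phases
  # per-phase sinus rate vector and gas indicator
  k_by_phase <- t(vapply(seq_len(nrow(phases)), function(i) {
    dir <- if (phases$gas[i] == "xenon") "in" else "out"
    unlist(kin[[paste0("k_", phases$flow[i], "_", dir)]])
  }, numeric(length(sinuses))))
  g_by_phase <- as.numeric(phases$gas == "xenon")

  step_t <- (0:(n_steps - 1)) * dt
  phase_idx <- findInterval(step_t + dt / 4, phases$start_s)

  C <- stats::setNames(numeric(length(regions)), regions)
  out <- matrix(NA_real_, length(ft), length(regions),
                dimnames = list(NULL, regions))
  rec <- round(ft / dt) + 1L  # step whose start time equals each frame time
  nf <- 1L
  for (i in seq_len(n_steps)) {
    if (nf <= length(rec) && i == rec[nf]) {
      out[nf, ] <- C
      nf <- nf + 1L
    }
    p <- phase_idx[i]
    G <- g_by_phase[p]
    k <- k_by_phase[p, ]
    cn <- C[c("nasal_left", "nasal_right")]
    dn <- s * (G - cn)
    ds <- k * (ceq * C[side_nasal] - C[sinuses])
    C[c("nasal_left", "nasal_right")] <- cn + dt * dn
    C[sinuses] <- C[sinuses] + dt * ds
  }
  if (nf <= length(rec)) out[nf, ] <- C  # frame at the final instant, if any
  tibble::tibble(
    region = rep(regions, each = length(ft)),
    time_s = rep(ft, times = length(regions)),
    c = as.vector(out)
  )
}
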