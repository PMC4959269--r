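# all-ones parameter set: every rate, basal term and half-saturation = 1
# (fat synthesis included); used for hand-computable derivative checks
unit_params <- function(...) {
  v <- setNames(rep(1, length(adiposwitch:::.param_names)),
                adiposwitch:::.param_names)
  over <- list(...)
  v[names(over)] <- unlist(over)
  adipo_params(values = as.list(v))
}

# a parameter set with every feedback silenced: loop terms removed via the
# variant, remaining Hill terms pushed to zero by huge half-saturations
linear_params <- function() {
  adipo_params(alpha2 = 1e8, alpha4 = 1e8, alpha6 = 1e8)
}

no_feedback_variant <- function() feedback_variant(loop2_on = FALSE, loop3_on = FALSE)

# fixed-step classic Runge-Kutta integrator over one constant-input segment;
# independent of the deSolve path used by simulate_adipo()
rk4_segment <- function(y0, params, inputs, variant, t_end, dt = 1e-3) {
  f <- function(y) unname(adipo_derivatives(pmax(y, 0), params, inputs, variant))
  y <- setNames(as.numeric(y0), adipo_species)
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  setNames(pmax(y, 0), adipo_species)
}

# RK4 oracle across a whole protocol (restarts at breakpoints)
rk4_protocol <- function(protocol, params, variant, times, dt = 1e-3) {
  bps <- sort(unique(c(adiposwitch:::protocol_breakpoints(protocol), times)))
  y <- basal_state(params, variant)
  out <- list()
  if (0 %in% times) out[["0"]] <- y
  for (k in seq_len(length(bps) - 1)) {
    u <- as.list(protocol_levels(protocol, bps[k])[1, c("gr", "camp", "insulin", "rosi")])
    y <- rk4_segment(y, params, u, variant, bps[k + 1] - bps[k], dt)
    if (bps[k + 1] %in% times) out[[as.character(bps[k + 1])]] <- y
  }
  out
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
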