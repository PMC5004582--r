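# Shared fixtures: everything is generated in code at test time.

default_p <- osmo_params()

# Plain-R RK4 integrator over model_rhs(); the independent route against
# the compiled integrators (no lagged branches).
rk4_reference <- function(scheme, shock, params, t_end, h) {
  y <- equilibrium_state(params)
  steps <- round(t_end / h)
  out <- matrix(NA_real_, steps + 1, 7,
                dimnames = list(NULL, c("time", names(y))))
  out[1, ] <- c(0, y)
  for (i in seq_len(steps)) {
    # time enters the RHS only through the step input, which is held at
    # its step-start value (matching the compiled integrator)
    t <- (i - 1) * h
    k1 <- model_rhs(t, y, scheme, shock, params)$deriv
    k2 <- model_rhs(t, y + h / 2 * k1, scheme, shock, params)$deriv
    k3 <- model_rhs(t, y + h / 2 * k2, scheme, shock, params)$deriv
    k4 <- model_rhs(t, y + h * k3, scheme, shock, params)$deriv
    y <- y + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    out[i + 1, ] <- c(i * h, y)
  }
  out
}
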