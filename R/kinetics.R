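# Hodgkin-Huxley-type kinetics of the nodal channels: fast Na+ (gates
# m^3 h), persistent Na+ (p^3) and slow K+ (s).  Rate equations follow
# the standard double-cable CNS axon formulation, tabulated at 36 C and
# rescaled to the model temperature by per-gate Q10 factors (2.2 for
# m and p, 2.9 for h, 3.0 for s).  Rates are in 1/ms, voltages in mV.

# rate parameterisation: each rate is either
#   linoid : a * u / (1 - exp(-u / k)),  u = s * (V - Vh)
#   sigmoid: a / (1 + exp(-s * (V - Vh) / k))
# rows: alpha_m, beta_m, alpha_h, beta_h, alpha_p, beta_p, alpha_s, beta_s
# cols: form (0 linoid, 1 sigmoid), a, Vh, k, s
kinetics_table <- function() {
  m <- rbind(
    alpha_m = c(0, 6.57,     -20.4, 10.3,  1),
    beta_m  = c(0, 0.304,    -25.7, 9.16, -1),
    alpha_h = c(0, 0.34,    -114.0, 11.0, -1),
    beta_h  = c(1, 12.6,     -31.8, 13.4,  1),
    alpha_p = c(0, 0.0353,   -27.0, 10.2,  1),
    beta_p  = c(0, 0.000883, -34.0, 10.0, -1),
    alpha_s = c(1, 0.3,      -53.0, 5.0,   1),
    beta_s  = c(1, 0.03,     -90.0, 1.0,   1))
  colnames(m) <- c("form", "a", "Vh", "k", "s")
  m
}

#' Nodal channel kinetics
#'
#' Voltage-dependent gating of the three nodal channel types: fast Na+
#' (activation \code{m}, exponent 3, inactivation \code{h}), persistent
#' Na+ (\code{p}, exponent 3) and slow K+ (\code{s}, exponent 1).
#' Rates are defined at 36 C and rescaled to \code{temperature} with
#' per-gate Q10 factors; Q10 scaling multiplies forward and backward
#' rates equally, so steady states are temperature independent while
#' time constants shrink with warming.
#'
#' @param temperature Model temperature in degrees C (default 37).
#' @return Object of class \code{channel_kinetics} with the rate table,
#'   Q10 factors and accessor-friendly fields \code{gates} ("m", "h",
#'   "p", "s") and \code{exponents}.
#' @examples
#' kin <- channel_kinetics()
#' gate_inf(kin, "m", -82)   # resting fast-Na activation
#' gate_tau(kin, "h", -82)   # inactivation time constant (ms)
#' @export
channel_kinetics <- function(temperature = 37) {
  q10 <- c(m = 2.2, h = 2.9, p = 2.2, s = 3.0)^((temperature - 36) / 10)
  structure(list(table = kinetics_table(), q10 = q10,
                 temperature = temperature,
                 gates = c("m", "h", "p", "s"),
                 exponents = c(m = 3, h = 1, p = 3, s = 1)),
            class = "channel_kinetics")
}

#' @export
print.channel_kinetics <- function(x, ...) {
  cat(sprintf(
    "Nodal channel kinetics at %g C (fast Na+ m^3*h, persistent Na+ p^3, slow K+ s)\n",
    x$temperature))
  cat("  Q10 rate factors:",
      paste(sprintf("%s %.3f", names(x$q10), x$q10), collapse = ", "),
      "\n")
  invisible(x)
}

# x/(1 - exp(-x/k)) with the removable singularity at x = 0 filled in
vtrap <- function(x, k) {
  out <- ifelse(abs(x / k) < 1e-6, k * (1 + x / (2 * k)),
                x / (1 - exp(-x / k)))
  out
}

eval_rate <- function(row, V) {
  if (row[["form"]] == 0) {
    u <- row[["s"]] * (V - row[["Vh"]])
    row[["a"]] * vtrap(u, row[["k"]])
  } else {
    row[["a"]] / (1 + exp(-row[["s"]] * (V - row[["Vh"]]) / row[["k"]]))
  }
}

#' Gating rates, steady states and time constants
#'
#' @param kinetics A \code{\link{channel_kinetics}} object.
#' @param gate One of \code{"m"}, \code{"h"}, \code{"p"}, \code{"s"}.
#' @param V Membrane potential(s), mV.
#' @return \code{gate_rates}: list with \code{alpha} and \code{beta}
#'   (1/ms, Q10-scaled); \code{gate_inf}: steady-state activation in
#'   [0, 1]; \code{gate_tau}: time constant (ms).
#' @export
gate_rates <- function(kinetics, gate, V) {
  stopifnot(inherits(kinetics, "channel_kinetics"),
            gate %in% kinetics$gates)
  q <- kinetics$q10[[gate]]
  a <- eval_rate(kinetics$table[paste0("alpha_", gate), ], V)
  b <- eval_rate(kinetics$table[paste0("beta_", gate), ], V)
  list(alpha = q * a, beta = q * b)
}

#' @rdname gate_rates
#' @export
gate_inf <- function(kinetics, gate, V) {
  r <- gate_rates(kinetics, gate, V)
  r$alpha / (r$alpha + r$beta)
}

#' @rdname gate_rates
#' @export
gate_tau <- function(kinetics, gate, V) {
  r <- gate_rates(kinetics, gate, V)
  1 / (r$alpha + r$beta)
}

#' Steady-state gating vector at a voltage
#'
#' @inheritParams gate_rates
#' @return Named vector with steady-state \code{m}, \code{h}, \code{p},
#'   \code{s}.
#' @export
steady_state_gates <- function(kinetics, V) {
  vapply(kinetics$gates, function(g) gate_inf(kinetics, g, V), 0)
}

#' Nodal ionic membrane current density at fixed gating
#'
#' Total nodal current density (uA/cm^2) at voltage \code{V} with gates
#' at their steady state for \code{V}: fast Na+, persistent Na+, slow
#' K+ and leak.  Used to report the residual current at the nominal
#' resting potential (the leak potential in the shipped presets does
#' not exactly zero it; see \code{\link{resting_state}}).
#'
#' @param params A \code{\link{cable_params}} object.
#' @param kinetics A \code{\link{channel_kinetics}} object.
#' @param V Membrane potential, mV.
#' @return Current density in uA/cm^2 (positive = outward).
#' @export
nodal_current_density <- function(params, kinetics, V) {
  g <- steady_state_gates(kinetics, V)
  params$g_Na * g[["m"]]^3 * g[["h"]] * (V - params$E_Na) +
    params$g_Nap * g[["p"]]^3 * (V - params$E_Na) +
    params$g_Ks * g[["s"]] * (V - params$E_K) +
    params$g_L_node * (V - params$E_Lk)
}
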