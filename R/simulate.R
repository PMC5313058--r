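# Front end for the compiled double-cable integrator.

chain_arrays <- function(chain) {
  n <- nrow(chain)
  list(
    is_node = as.integer(chain$kind == "node"),
    c_mem = chain$c_mem, c_my = chain$c_my,
    g_my = chain$g_my, g_L = chain$g_L,
    g_Na = chain$g_Na, g_Ks = chain$g_Ks, g_Nap = chain$g_Nap,
    g_ax = 1e3 / chain$r_ax_next[-n],   # Mohm -> nS
    g_p = ifelse(chain$r_p_next[-n] > 0, 1e3 / chain$r_p_next[-n], 0))
}

#' Resting state of the axon model
#'
#' Finds the stationary state of the full nonlinear model by a damped
#' fixed-point iteration: gating variables at their voltage steady
#' state, alternated with a solve of the stationary (capacitance-free)
#' linear network.  The leak potential shipped with the presets was
#' tuned by the source nodal model so that the nominal resting
#' potential is approximately stationary; a small residual nodal
#' current remains under the transcribed kinetics and is reported
#' rather than re-tuned away.
#'
#' @param chain A \code{\link{build_axon}} chain.
#' @param kinetics A \code{\link{channel_kinetics}} object.
#' @param tol Convergence tolerance on the voltage update (mV).
#' @return List with per-compartment \code{V} (intracellular, mV),
#'   \code{U} (periaxonal, mV), \code{gates} (n x 4 matrix, columns m,
#'   h, p, s), the stationary nodal membrane potential
#'   \code{V_node_rest}, and \code{residual_at_Er}: the nodal ionic
#'   current density (uA/cm^2) at the nominal resting potential with
#'   gates at steady state, zero if the leak potential were exactly
#'   tuned.
#' @examples
#' ch <- build_axon(cable_params("optic_nerve"), n_nodes = 5)
#' rs <- resting_state(ch)
#' rs$V_node_rest
#' @export
resting_state <- function(chain, kinetics = channel_kinetics(),
                          tol = 1e-10) {
  p <- attr(chain, "params")
  a <- chain_arrays(chain)
  n <- nrow(chain)
  out <- cable_stationary_cpp(
    a$is_node, a$g_my, a$g_L, a$g_Na, a$g_Ks, a$g_Nap,
    p$E_Na, p$E_K, p$E_Lk, a$g_ax, a$g_p,
    kinetics$table, kinetics$q10,
    rep(p$E_r, n), rep(0, n),
    1000L, 0.7, tol)
  if (out$delta > 1e-6) {
    warning("stationary solve did not fully converge (delta = ",
            format(out$delta), " mV)")
  }
  node_V <- out$V[a$is_node == 1L]
  res <- nodal_current_density(p, kinetics, p$E_r)
  if (abs(res) > 1) {
    attr(res, "note") <- paste0(
      "leak potential does not exactly zero the nodal current at E_r; ",
      "stationary nodal potential is ",
      sprintf("%.2f", stats::median(node_V)), " mV")
  }
  colnames(out$gates) <- c("m", "h", "p", "s")
  list(V = out$V, U = out$U, gates = out$gates,
       V_node_rest = stats::median(node_V),
       residual_at_Er = res,
       iterations = out$iterations, delta = out$delta)
}

#' Simulation configuration
#'
#' @param dt Time step in ms (default 2.5e-4 ms = 0.25 us).
#' @param duration Total simulated time, ms.
#' @param stim_node Node (of Ranvier) index receiving the stimulus
#'   (1 = first node).
#' @param stim_amp Stimulus current amplitude, nA.
#' @param stim_onset Stimulus onset, ms.
#' @param stim_width Stimulus duration, ms.
#' @param record \code{"nodes"} (default: all node compartments),
#'   \code{"all"}, or a vector of compartment indices.
#' @param record_every Record every this many steps (default 4, i.e.
#'   1 us sampling at the default dt).
#' @param stop_node Optional node index: once this node's membrane
#'   potential crosses 0 mV, integrate a further \code{stop_delay} ms
#'   and stop.  Saves time when only a conduction delay is needed.
#' @param stop_delay Extra time integrated after the stop trigger (ms).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(dt = 2.5e-4, duration = 3, stim_node = 1L,
                       stim_amp = 1, stim_onset = 0, stim_width = 0.1,
                       record = "nodes", record_every = 4L,
                       stop_node = NA_integer_, stop_delay = 0.3) {
  stopifnot(dt > 0, duration > 0)
  if (stim_amp != 0 && duration <= stim_onset + stim_width) {
    stop("duration must cover the stimulus", call. = FALSE)
  }
  structure(list(dt = dt, duration = duration, stim_node = stim_node,
                 stim_amp = stim_amp, stim_onset = stim_onset,
                 stim_width = stim_width, record = record,
                 record_every = as.integer(record_every),
                 stop_node = stop_node, stop_delay = stop_delay),
            class = "sim_config")
}

#' Simulate action potential propagation along the axon
#'
#' Integrates the double-cable equations with an implicit
#' (backward-Euler) scheme on the linear membrane/axial terms and the
#' standard exponential-integrator update for the nodal gating
#' variables.  The integration starts from the model's stationary
#' state (see \code{\link{resting_state}}) and injects a brief current
#' pulse into one node.
#'
#' @param chain A \code{\link{build_axon}} chain.
#' @param kinetics A \code{\link{channel_kinetics}} object.
#' @param config A \code{\link{sim_config}}.
#' @param init Optional initial state (list with \code{V}, \code{U},
#'   \code{gates}); defaults to the resting state.
#' @return Object of class \code{axon_sim}: list with \code{t} (ms),
#'   \code{Vm} (axolemmal membrane potential, time x recorded
#'   compartments, mV), \code{U} (periaxonal potential), \code{gates}
#'   (time x 4*recorded), \code{record_idx} (compartment indices),
#'   \code{node_of_rec} (node index or NA per recorded compartment),
#'   \code{node_positions} (axial centre position of every node, um),
#'   \code{diverged} (-1 if stable), \code{propagated} flag, plus the
#'   chain and config.
#' @examples
#' \donttest{
#' ch <- build_axon(cable_params("optic_nerve"), n_nodes = 11)
#' sim <- simulate_axon(ch, config = sim_config(duration = 1))
#' }
#' @export
simulate_axon <- function(chain, kinetics = channel_kinetics(),
                          config = sim_config(), init = NULL) {
  p <- attr(chain, "params")
  a <- chain_arrays(chain)
  n <- nrow(chain)
  if (is.null(init)) init <- resting_state(chain, kinetics)

  node_comp <- which(chain$kind == "node")
  if (identical(config$record, "nodes")) {
    rec <- node_comp
  } else if (identical(config$record, "all")) {
    rec <- seq_len(n)
  } else {
    rec <- as.integer(config$record)
  }
  stim_comp <- node_comp[config$stim_node]
  if (is.na(stim_comp)) stop("stim_node out of range", call. = FALSE)
  stop_comp <- if (is.na(config$stop_node)) -1L else
    node_comp[config$stop_node] - 1L

  n_steps <- as.integer(round(config$duration / config$dt))
  out <- cable_integrate_cpp(
    a$is_node, a$c_mem, a$c_my, a$g_my, a$g_L, a$g_Na, a$g_Ks, a$g_Nap,
    p$E_Na, p$E_K, p$E_Lk, a$g_ax, a$g_p,
    channel_kinetics_table(kinetics), kinetics$q10,
    init$V, init$U, unname(init$gates),
    config$dt, n_steps,
    stim_comp - 1L, config$stim_amp * 1e3,  # nA -> pA
    config$stim_onset, config$stim_onset + config$stim_width,
    rec - 1L, config$record_every,
    stop_comp, config$stop_delay)
  if (out$diverged >= 0) {
    stop("solver diverged at compartment ", out$diverged + 1L,
         " (kind ", chain$kind[out$diverged + 1L], ")", call. = FALSE)
  }
  if (out$n_samp < length(out$t)) {   # early stop: trim records
    keep <- seq_len(out$n_samp)
    out$t <- out$t[keep]
    out$Vm <- out$Vm[keep, , drop = FALSE]
    out$U <- out$U[keep, , drop = FALSE]
    out$gates_rec <- out$gates_rec[keep, , drop = FALSE]
  }

  # axial centre positions of the nodes
  ends <- cumsum(chain$length)
  centres <- ends - chain$length / 2
  node_positions <- centres[node_comp]

  node_of_rec <- chain$node_index[rec]
  # propagation check: did the far half of the axon spike?
  far_nodes <- which(!is.na(node_of_rec) &
                       node_of_rec > attr(chain, "n_nodes") / 2)
  propagated <- length(far_nodes) > 0 &&
    any(apply(out$Vm[, far_nodes, drop = FALSE], 2, max) > 0)

  structure(list(t = out$t, Vm = out$Vm, U = out$U,
                 gates = out$gates_rec,
                 record_idx = rec, node_of_rec = node_of_rec,
                 node_positions = node_positions,
                 V_final = out$V_final, U_final = out$U_final,
                 diverged = out$diverged,
                 propagated = propagated,
                 chain = chain, kinetics = kinetics, config = config),
            class = "axon_sim")
}

# the rate table is fixed; accessor kept separate so a modified
# kinetics object (e.g. different temperature) flows through
channel_kinetics_table <- function(kinetics) kinetics$table

#' @export
print.axon_sim <- function(x, ...) {
  cat(sprintf(
    "Axon simulation: %d compartments, %.3g ms at dt = %.3g us\n",
    nrow(x$chain), max(x$t), x$config$dt * 1e3))
  cat(sprintf("  stimulus %.3g nA x %.3g ms at node %d; propagated: %s\n",
              x$config$stim_amp, x$config$stim_width,
              x$config$stim_node, x$propagated))
  invisible(x)
}

#' Plot recorded membrane potentials
#'
#' @param x An \code{axon_sim}.
#' @param nodes Node indices to draw (default up to 6, spread along
#'   the axon).
#' @param ... Passed to \code{matplot}.
#' @export
plot.axon_sim <- function(x, nodes = NULL, ...) {
  avail <- x$node_of_rec[!is.na(x$node_of_rec)]
  if (is.null(nodes)) {
    nodes <- unique(round(seq(min(avail), max(avail), length.out = 6)))
  }
  cols_idx <- match(nodes, x$node_of_rec)
  if (anyNA(cols_idx)) stop("requested node(s) were not recorded",
                            call. = FALSE)
  graphics::matplot(x$t, x$Vm[, cols_idx, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (ms)",
                    ylab = "membrane potential (mV)", ...)
  graphics::legend("topright", legend = paste("node", nodes),
                   col = seq_along(nodes), lty = 1, bty = "n")
  invisible(x)
}

#' Write recorded traces to CSV
#'
#' Long format: time, compartment index, node index (NA off-node),
#' membrane and periaxonal potential.
#' @param sim An \code{axon_sim}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_traces_csv <- function(sim, path) {
  n_rec <- length(sim$record_idx)
  df <- data.frame(
    t = rep(sim$t, n_rec),
    compartment = rep(sim$record_idx, each = length(sim$t)),
    node = rep(sim$node_of_rec, each = length(sim$t)),
    Vm = as.vector(sim$Vm),
    U = as.vector(sim$U))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
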