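# In-silico experiments: conduction speed measurement and parameter
# sweeps under the two channel-scaling assumptions.

#' Spike time at a recorded node
#'
#' Time of the upward crossing of \code{threshold} (default -20 mV),
#' linearly interpolated between samples.
#'
#' @param sim An \code{\link{simulate_axon}} result.
#' @param node Node (of Ranvier) index.
#' @param threshold Crossing level, mV.
#' @return Crossing time in ms, with attribute \code{t_peak} (time of
#'   the voltage maximum, parabolically interpolated).
#' @export
spike_time <- function(sim, node, threshold = -20) {
  j <- match(node, sim$node_of_rec)
  if (is.na(j)) stop("node ", node, " was not recorded", call. = FALSE)
  v <- sim$Vm[, j]
  above <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(above)) {
    stop("no upward crossing of ", threshold, " mV at node ", node,
         ": propagation failure", call. = FALSE)
  }
  i <- above[1]
  frac <- (threshold - v[i]) / (v[i + 1] - v[i])
  tc <- sim$t[i] + frac * (sim$t[i + 1] - sim$t[i])
  # parabolic peak interpolation
  ip <- which.max(v)
  tp <- sim$t[ip]
  if (ip > 1 && ip < length(v)) {
    dt1 <- sim$t[ip + 1] - sim$t[ip]
    denom <- v[ip - 1] - 2 * v[ip] + v[ip + 1]
    if (denom < 0) tp <- tp + 0.5 * dt1 * (v[ip - 1] - v[ip + 1]) / denom
  }
  attr(tc, "t_peak") <- tp
  tc
}

#' Conduction speed between two nodes
#'
#' Speed is the axial distance between the two node centres divided by
#' the difference of their spike times (threshold-crossing definition).
#' The same quantity computed from spike-peak times is attached as
#' \code{speed_peak}; the two typically agree within 1 percent.
#'
#' @inheritParams spike_time
#' @param first_node,last_node Node indices (1-based; defaults 21 and
#'   31, i.e. nodes 20 and 30 when counting the stimulated node as
#'   node 0, mid-axon of a 51-node chain).
#' @return Speed in m/s with attributes \code{delay_ms},
#'   \code{distance_um} and \code{speed_peak}.
#' @export
conduction_speed <- function(sim, first_node = 21L, last_node = 31L,
                             threshold = -20) {
  t1 <- spike_time(sim, first_node, threshold)
  t2 <- spike_time(sim, last_node, threshold)
  d_um <- sim$node_positions[last_node] - sim$node_positions[first_node]
  delay <- as.numeric(t2) - as.numeric(t1)
  if (delay <= 0) stop("non-positive conduction delay", call. = FALSE)
  speed <- d_um / delay * 1e-3        # um/ms -> m/s
  delay_peak <- attr(t2, "t_peak") - attr(t1, "t_peak")
  attr(speed, "delay_ms") <- delay
  attr(speed, "distance_um") <- d_um
  attr(speed, "speed_peak") <- d_um / delay_peak * 1e-3
  speed
}

#' Rescale nodal channel densities for a changed node length
#'
#' Under the constant-channel-number assumption the nodal conductance
#' densities (fast and persistent Na+, slow K+, and the nodal leak)
#' vary inversely with node length, holding the absolute number of
#' channels at the value for the preset's mean node length.  Under
#' constant density the densities are untouched.
#'
#' @param params A \code{\link{cable_params}} object.
#' @param node_length New node length (um).
#' @param mode \code{"constant_density"} or \code{"constant_number"}.
#' @return A new \code{cable_params} with \code{L_node = node_length}
#'   and densities scaled according to \code{mode}.
#' @examples
#' p <- scale_nodal_channels(cable_params("optic_nerve"), 2.04,
#'                           "constant_number")
#' p$g_Na  # 1500 mS/cm2: half density at double length
#' @export
scale_nodal_channels <- function(params, node_length,
                                 mode = c("constant_density",
                                          "constant_number")) {
  mode <- match.arg(mode)
  if (node_length <= 0) stop("node_length must be positive",
                             call. = FALSE)
  s <- if (mode == "constant_number") params$L_node_ref / node_length
       else 1
  cable_params_update(params, L_node = node_length,
                      g_Na = params$g_Na * s, g_Ks = params$g_Ks * s,
                      g_Nap = params$g_Nap * s,
                      g_L_node = params$g_L_node * s)
}

cable_params_update <- function(params, ...) {
  over <- list(...)
  p <- unclass(params)
  p[names(over)] <- over
  validate_cable_params(p)
  structure(p, class = "cable_params")
}

#' Conduction speed for one model configuration
#'
#' Builds the chain, simulates a suprathreshold stimulus at the first
#' node and measures speed between \code{first_node} and
#' \code{last_node}.  The duration is sized from the axon geometry and
#' the integration stops shortly after the last measured node spikes.
#'
#' @param params A \code{\link{cable_params}} object.
#' @param node_lengths Scalar or per-node node lengths (um); default
#'   the preset node length.
#' @param mode Channel scaling mode, see
#'   \code{\link{scale_nodal_channels}}.
#' @param n_nodes Number of nodes (default 51).
#' @param N_wraps,L_internode Geometry overrides.
#' @param first_node,last_node Measurement nodes (default 21 and 31).
#' @param dt Time step, ms.
#' @param stim_amp Stimulus amplitude, nA.
#' @param keep_sim Return the simulation as an attribute.
#' @return Speed in m/s (attributes as in
#'   \code{\link{conduction_speed}}).
#' @export
axon_speed <- function(params, node_lengths = NULL,
                       mode = c("constant_density", "constant_number"),
                       n_nodes = 51L, N_wraps = NULL,
                       L_internode = NULL,
                       first_node = 21L, last_node = 31L,
                       dt = 2.5e-4, stim_amp = 1, keep_sim = FALSE) {
  mode <- match.arg(mode)
  chain <- build_axon(params, n_nodes = n_nodes,
                      node_lengths = node_lengths,
                      channel_mode = mode, N_wraps = N_wraps,
                      L_internode = L_internode)
  # duration: distance to the last measured node at a conservative
  # 0.8 m/s, plus margin; early stop trims the actual cost
  ends <- cumsum(chain$length)
  pos_mm <- (ends[which(chain$node_index == last_node)] -
               chain$length[which(chain$node_index == last_node)] / 2) *
    1e-3
  duration <- pos_mm / 0.8 + 1
  cfg <- sim_config(dt = dt, duration = duration, stim_amp = stim_amp,
                    stop_node = min(last_node + 2L, n_nodes))
  sim <- simulate_axon(chain, config = cfg)
  if (!sim$propagated) {
    stop("action potential did not propagate", call. = FALSE)
  }
  sp <- conduction_speed(sim, first_node, last_node)
  if (keep_sim) attr(sp, "sim") <- sim
  sp
}

new_sweep <- function(df, parameter, mode, baseline_speed, baseline,
                      preset) {
  structure(df, parameter = parameter, mode = mode,
            baseline_speed = baseline_speed, baseline_value = baseline,
            preset = preset,
            class = c("node_sweep", "data.frame"))
}

#' Sweep conduction speed over node length
#'
#' One simulation per node length with the internodal region length
#' held fixed; speeds are reported together with the percent change
#' relative to the preset's mean node length.
#'
#' @param params A \code{\link{cable_params}} object.
#' @param lengths Node lengths to simulate (um).
#' @param mode Channel scaling mode.
#' @param ... Passed to \code{\link{axon_speed}}.
#' @return A \code{node_sweep} data frame with columns \code{value}
#'   (um), \code{speed_mps}, \code{pct_change}, and attributes
#'   \code{baseline_speed} (speed at the mean node length),
#'   \code{mode}, \code{parameter}.  Propagation failures yield
#'   \code{NA} speed.
#' @export
sweep_node_length <- function(params, lengths,
                              mode = c("constant_density",
                                       "constant_number"), ...) {
  mode <- match.arg(mode)
  base <- as.numeric(axon_speed(params, params$L_node_ref, mode, ...))
  sp <- vapply(lengths, function(L) {
    tryCatch(as.numeric(axon_speed(params, L, mode, ...)),
             error = function(e) NA_real_)
  }, 0)
  new_sweep(data.frame(value = lengths, speed_mps = sp,
                       pct_change = 100 * (sp / base - 1)),
            "node_length", mode, base, params$L_node_ref, params$name)
}

#' Sweep conduction speed over internode length
#'
#' The compartment count of each internodal region is re-derived per
#' internode length so the spatial resolution stays at the preset's
#' baseline value and the paranodes stay resolved by an integral
#' number of compartments.
#'
#' @inheritParams sweep_node_length
#' @param internode_lengths Internodal region lengths (um).
#' @param node_length Node length (um) used throughout.
#' @return A \code{node_sweep} data frame (percent change relative to
#'   the preset's internode length).
#' @export
sweep_internode_length <- function(params, internode_lengths,
                                   node_length = NULL,
                                   mode = c("constant_density",
                                            "constant_number"), ...) {
  mode <- match.arg(mode)
  if (is.null(node_length)) node_length <- params$L_node
  base <- as.numeric(axon_speed(params, node_length, mode, ...))
  sp <- vapply(internode_lengths, function(L) {
    tryCatch(as.numeric(axon_speed(params, node_length, mode,
                                   L_internode = L, ...)),
             error = function(e) NA_real_)
  }, 0)
  new_sweep(data.frame(value = internode_lengths, speed_mps = sp,
                       pct_change = 100 * (sp / base - 1)),
            "internode_length", mode, base, params$L_internode,
            params$name)
}

#' Conduction speed change from adding or removing myelin wraps
#'
#' Myelin capacitance and conductance are recomputed for the changed
#' lamella count; node length, internode length and paranode length
#' (and the paranodal effective periaxonal width) are left unchanged,
#' and nodal conductances stay at their preset values.
#'
#' @inheritParams sweep_node_length
#' @param wraps_delta Integer change(s) in wrap count (default -1).
#' @return A \code{node_sweep} data frame with \code{value} = wrap
#'   count.
#' @export
sweep_wraps <- function(params, wraps_delta = -1L, ...) {
  wraps <- params$N_wraps + wraps_delta
  if (any(wraps < 1)) stop("resulting wrap count must be >= 1",
                           call. = FALSE)
  base <- as.numeric(axon_speed(params, ...))
  sp <- vapply(wraps, function(w) {
    if (w == params$N_wraps) return(base)
    tryCatch(as.numeric(axon_speed(params, N_wraps = w, ...)),
             error = function(e) NA_real_)
  }, 0)
  new_sweep(data.frame(value = wraps, speed_mps = sp,
                       pct_change = 100 * (sp / base - 1)),
            "N_wraps", "constant_density", base, params$N_wraps,
            params$name)
}

#' Axon with alternating node lengths
#'
#' Alternate nodes are \code{delta} um shorter and longer than the
#' mean.  Under constant channel number the linear speed/length
#' relation makes the alternation cancel; under constant density the
#' concave relation slows conduction slightly (under 2 percent for the
#' measured along-axon variability).
#'
#' @inheritParams sweep_node_length
#' @param mean_length Mean node length (um).
#' @param delta Half-difference between alternate nodes (um).
#' @return List with \code{speed} (alternating axon), \code{uniform}
#'   (all nodes at \code{mean_length}) and \code{pct_change}.
#' @export
alternating_node_axon <- function(params, mean_length = NULL,
                                  delta = 0.25,
                                  mode = c("constant_density",
                                           "constant_number"),
                                  n_nodes = 51L, ...) {
  mode <- match.arg(mode)
  if (is.null(mean_length)) mean_length <- params$L_node
  if (mean_length - delta <= 0) {
    stop("mean_length - delta must be positive", call. = FALSE)
  }
  lens <- rep(c(mean_length - delta, mean_length + delta),
              length.out = n_nodes)
  s_alt <- as.numeric(axon_speed(params, lens, mode,
                                 n_nodes = n_nodes, ...))
  s_uni <- as.numeric(axon_speed(params, mean_length, mode,
                                 n_nodes = n_nodes, ...))
  list(speed = s_alt, uniform = s_uni,
       pct_change = 100 * (s_alt / s_uni - 1))
}

#' Parameter changes equivalent to a target speed change
#'
#' Finds, by bisection on simulated speed, the change in (a) nodal
#' Na+ conductance density, (b) internode length and (c) node length
#' (constant-density mode) that each reproduce a target percent change
#' in conduction speed, to within \code{tol_pp} percentage points.
#'
#' @inheritParams sweep_node_length
#' @param target_pct Target percent speed change (negative = slower).
#' @param knobs Which knobs to solve.
#' @param tol_pp Tolerance, percentage points of speed change.
#' @param ... Passed to \code{\link{axon_speed}}.
#' @return List with, per requested knob, \code{density_change_pct},
#'   \code{internode_change_pct} and/or \code{node_length_um}, plus
#'   the baseline speed.
#' @export
speed_matched_equivalents <- function(params, target_pct,
                                      knobs = c("density", "internode",
                                                "node_length"),
                                      tol_pp = 0.2, ...) {
  knobs <- match.arg(knobs, several.ok = TRUE)
  base <- as.numeric(axon_speed(params, ...))
  pct_of <- function(speed) 100 * (speed / base - 1)
  out <- list(baseline_speed = base, target_pct = target_pct)
  if (target_pct == 0) {
    if ("density" %in% knobs) out$density_change_pct <- 0
    if ("internode" %in% knobs) out$internode_change_pct <- 0
    if ("node_length" %in% knobs) out$node_length_um <- params$L_node
    return(out)
  }

  bisect <- function(f, lo, hi) {
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || sign(flo - target_pct) ==
        sign(fhi - target_pct)) {
      stop("target speed change is not reachable with this knob",
           call. = FALSE)
    }
    repeat {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (!is.na(fm) && abs(fm - target_pct) < tol_pp) return(mid)
      if (sign(fm - target_pct) == sign(flo - target_pct)) {
        lo <- mid; flo <- fm
      } else hi <- mid
      if (abs(hi - lo) < 1e-4 * max(abs(hi), 1)) return(mid)
    }
  }

  if ("density" %in% knobs) {
    f <- function(s) {
      p2 <- cable_params_update(params, g_Na = params$g_Na * s,
                                g_Nap = params$g_Nap * s)
      pct_of(tryCatch(as.numeric(axon_speed(p2, ...)),
                      error = function(e) NA_real_))
    }
    s <- bisect(f, if (target_pct < 0) 0.05 else 1,
                if (target_pct < 0) 1 else 5)
    out$density_change_pct <- 100 * (s - 1)
  }
  if ("internode" %in% knobs) {
    f <- function(L) {
      pct_of(tryCatch(
        as.numeric(axon_speed(params, L_internode = L, ...)),
        error = function(e) NA_real_))
    }
    # speed falls with internode length above the preset value
    L <- bisect(f, params$L_internode,
                if (target_pct < 0) 4 * params$L_internode
                else max(2.5 * params$L_paranode + 1,
                         0.2 * params$L_internode))
    out$internode_change_pct <- 100 * (L / params$L_internode - 1)
  }
  if ("node_length" %in% knobs) {
    f <- function(L) {
      pct_of(tryCatch(
        as.numeric(axon_speed(params, L, "constant_density", ...)),
        error = function(e) NA_real_))
    }
    # solve on the short-node branch below the speed maximum
    L <- bisect(f, 0.2, params$L_node_ref)
    out$node_length_um <- L
  }
  out
}

#' Propagation delay over a path
#'
#' @param axon_length Path length in metres.
#' @param speed Conduction speed in m/s.
#' @return Delay in ms.
#' @examples
#' propagation_delay(0.01, 2.61)  # rat inter-cortical callosal axon
#' @export
propagation_delay <- function(axon_length, speed) {
  if (axon_length < 0 || speed <= 0) {
    stop("axon_length must be >= 0 and speed > 0", call. = FALSE)
  }
  axon_length / speed * 1e3
}

#' Threshold stimulus amplitude
#'
#' Bisection on the stimulus amplitude for a just-propagating action
#' potential (spike at the far half of the axon).
#'
#' @inheritParams axon_speed
#' @param lo,hi Bracketing amplitudes, nA.
#' @param rel_tol Relative bisection tolerance.
#' @export
threshold_amplitude <- function(params, n_nodes = 15L, lo = 0.01,
                                hi = 5, rel_tol = 0.05, dt = 1e-3) {
  chain <- build_axon(params, n_nodes = n_nodes)
  init <- resting_state(chain)
  spikes <- function(amp) {
    cfg <- sim_config(dt = dt, duration = 2.5, stim_amp = amp,
                      stop_node = n_nodes)
    sim <- simulate_axon(chain, config = cfg, init = init)
    sim$propagated
  }
  if (spikes(lo)) return(lo)
  if (!spikes(hi)) stop("upper bracket is subthreshold", call. = FALSE)
  while ((hi - lo) / hi > rel_tol) {
    mid <- sqrt(lo * hi)
    if (spikes(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' @export
print.node_sweep <- function(x, ...) {
  cat(sprintf(
    "Sweep of %s (%s), preset '%s': baseline %.3f m/s at %.4g\n",
    attr(x, "parameter"), attr(x, "mode"), attr(x, "preset"),
    attr(x, "baseline_speed"), attr(x, "baseline_value")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.node_sweep <- function(x, ...) {
  graphics::plot(x$value, x$speed_mps, type = "b", pch = 16,
                 xlab = attr(x, "parameter"),
                 ylab = "conduction speed (m/s)", ...)
  graphics::abline(h = attr(x, "baseline_speed"), lty = 3)
  invisible(x)
}

#' Maximum speed spread across a sweep
#'
#' The "up to X percent" spread statistic: the maximum speed
#' relative to the minimum across the swept range (and, for reference,
#' the max-vs-baseline spread).
#'
#' @param sweep A \code{node_sweep}.
#' @return List with \code{max_vs_min_pct} and
#'   \code{max_vs_baseline_pct}.
#' @export
sweep_spread <- function(sweep) {
  sp <- sweep$speed_mps[is.finite(sweep$speed_mps)]
  list(max_vs_min_pct = 100 * (max(sp) / min(sp) - 1),
       max_vs_baseline_pct =
         100 * (max(sp) / attr(sweep, "baseline_speed") - 1))
}
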