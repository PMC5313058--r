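# Shared fixtures.  Small axons (few nodes, coarse grid/dt) are used
# for property tests where the physics is scale-free; the acceptance
# tests use the full 51-node protocol.

optic <- function(...) cable_params("optic_nerve", ...)
cortex <- function(...) cable_params("cortex", ...)

# small optic axon: 34 compartments/internode keeps the paranode
# resolved by one exact 2.11-um compartment (dx = 4.096 um interior)
small_chain <- function(params = optic(), n_nodes = 11L, nc = 34L, ...) {
  build_axon(params, n_nodes = n_nodes, internodal_compartments = nc,
             ...)
}

# speed on a reduced axon: nodes 3 -> 8 of an 11-node chain, coarse dt
small_speed <- function(params = optic(), node_lengths = NULL,
                        mode = "constant_density", n_nodes = 11L,
                        dt = 1e-3, first_node = 3L, last_node = 8L,
                        ...) {
  as.numeric(axon_speed(params, node_lengths = node_lengths,
                        mode = mode, n_nodes = n_nodes,
                        first_node = first_node,
                        last_node = last_node, dt = dt, ...))
}

# cache expensive full-protocol speeds across tests in one file
speed_cache <- new.env(parent = emptyenv())
cached_speed <- function(key, expr) {
  if (is.null(speed_cache[[key]])) speed_cache[[key]] <- force(expr)
  speed_cache[[key]]
}
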