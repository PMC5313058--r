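# Geometry of the discretised double-cable axon.
#
# Unit conventions for absolute per-compartment quantities:
#   length/diameter um, area um^2, capacitance pF, conductance nS,
#   axial resistance Mohm.  Densities enter in mS/cm^2 and uF/cm^2
#   (1 mS/cm^2 * 1 um^2 = 0.01 nS; 1 uF/cm^2 * 1 um^2 = 0.01 pF;
#    1 ohm.cm * 1 um / 1 um^2 = 0.01 Mohm).

DENS2ABS <- 0.01   # mS/cm2*um2 -> nS, and uF/cm2*um2 -> pF
RES2MOHM <- 0.01   # ohm.cm*um/um2 -> Mohm

#' Effective periaxonal width of the paranodal spiral pathway
#'
#' At the paranode the periaxonal space is not an open annulus: current
#' must follow the spiral pathway between the myelin loops, of
#' cross-sectional area \code{A}, winding around the axon once per wrap.
#' A uniform periaxonal space of width \code{w} along the paranode has
#' the same axial resistance if
#' \deqn{w = A L / [(\pi d)^2 N_{wraps}]}
#' where \code{L} is the paranode length and \code{d} the axon diameter.
#'
#' @param A Spiral pathway cross-sectional area (nm^2); 170 nm^2 for CNS
#'   paranodes.
#' @param L_paranode Paranode length (um).
#' @param d_axon Internodal (= paranodal) axon diameter (um).
#' @param N_wraps Number of myelin wraps.
#' @return Effective periaxonal width in nm.
#' @examples
#' paranodal_effective_width(170, 2.11, 0.82, 7)  # ~0.0077 nm
#' paranodal_effective_width(170, 1.90, 0.73, 5)  # ~0.0123 nm
#' @export
paranodal_effective_width <- function(A, L_paranode, d_axon, N_wraps) {
  for (v in list(A, L_paranode, d_axon, N_wraps)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("all arguments must be single positive numbers", call. = FALSE)
    }
  }
  L_nm <- L_paranode * 1e3
  d_nm <- d_axon * 1e3
  A * L_nm / ((pi * d_nm)^2 * N_wraps)
}

#' Myelin wrap count implied by the g-ratio
#'
#' The radial thickness of the myelin sheath is
#' \code{(d_axon/g_ratio - d_axon)/2}.  After setting aside the
#' periaxonal space between the axolemma and the innermost wrap, the
#' remaining thickness is filled by wraps of the given periodicity; a
#' partial outermost wrap counts as a wrap (ceiling), which reproduces
#' the 7 (optic nerve, g = 0.78) and 5 (cortex, g = 0.81) wraps of the
#' shipped presets.
#'
#' @param d_axon Internodal axon diameter (um).
#' @param g_ratio Axon diameter / outer myelin diameter, in (0, 1).
#' @param periodicity Myelin wrap periodicity (nm).
#' @param periaxonal_width Internodal periaxonal space width (nm).
#' @return Integer number of wraps (>= 1).
#' @examples
#' wraps_from_gratio(0.82, 0.78)  # 7
#' wraps_from_gratio(0.73, 0.81)  # 5
#' @export
wraps_from_gratio <- function(d_axon, g_ratio, periodicity = 15.6,
                              periaxonal_width = 15) {
  if (!is.finite(g_ratio) || g_ratio <= 0 || g_ratio >= 1) {
    stop("g_ratio must lie strictly in (0, 1)", call. = FALSE)
  }
  if (d_axon <= 0 || periodicity <= 0 || periaxonal_width < 0) {
    stop("d_axon and periodicity must be positive", call. = FALSE)
  }
  thickness_nm <- (d_axon / g_ratio - d_axon) / 2 * 1e3
  n <- ceiling((thickness_nm - periaxonal_width) / periodicity)
  if (n < 1) {
    stop("g-ratio implies a sheath thinner than one myelin wrap",
         call. = FALSE)
  }
  as.integer(n)
}

# Radii (um) of the 2*N_wraps myelin membranes: innermost membrane sits
# one periaxonal-space width outside the axolemma, successive membranes
# are spaced by half the wrap periodicity.
lamella_radii <- function(d_axon, N_wraps, periodicity = 15.6,
                          periaxonal_width = 15) {
  r0 <- d_axon / 2 + periaxonal_width / 1e3
  r0 + (seq_len(2 * N_wraps) - 1) * (periodicity / 2) / 1e3
}

# Series myelin admittance of a compartment of length l (um): each
# membrane contributes dens * 2*pi*r_k * l, all in series.
myelin_series <- function(dens, l, radii) {
  1 / sum(1 / (dens * 2 * pi * radii * l * DENS2ABS))
}

#' Build the compartment chain for one axon
#'
#' Discretises an axon of \code{n_nodes} nodes of Ranvier alternating
#' with \code{n_nodes - 1} internodal regions.  Each node is a single
#' compartment; each internodal region is split into
#' \code{internodal_compartments} compartments of which an integral
#' number at each end represents the paranode.  When
#' \code{L_internode / internodal_compartments} divides the paranode
#' length exactly (as it does for both shipped presets: 139.26/66 =
#' 2.11 um and 81.7/86 = 0.95 um) the grid is uniform; otherwise the
#' paranodes keep their exact length (split into
#' \code{round(L_paranode/dx)} compartments) and the interior is uniform.
#'
#' Absolute per-compartment capacitances and conductances are density
#' times local axolemma area; the myelin admittance of a paranodal or
#' internodal compartment is the series combination of its
#' \code{2 * N_wraps} membranes, each evaluated at its own lamella
#' radius.  The internodal region length is independent of node length.
#'
#' @param params A \code{\link{cable_params}} object.
#' @param n_nodes Number of nodes of Ranvier (default 51).
#' @param internodal_compartments Compartments per internodal region
#'   (default taken from the preset: 66 optic nerve, 86 cortex).
#' @param node_lengths Optional node length override: a scalar applied
#'   to all nodes, or a vector of length \code{n_nodes}.
#' @param channel_mode \code{"constant_density"} (nodal conductance
#'   densities as given) or \code{"constant_number"} (densities scaled
#'   by \code{L_node_ref / node length}, holding channel number fixed).
#' @param N_wraps Myelin wrap count override.
#' @param L_internode Internodal region length override (um).
#' @return An object of class \code{compartment_chain}: a data frame
#'   with one row per compartment (columns \code{kind}, \code{length},
#'   \code{diam}, \code{area}, \code{c_mem}, \code{g_Na}, \code{g_Ks},
#'   \code{g_Nap}, \code{g_L}, \code{c_my}, \code{g_my},
#'   \code{w_periax}, \code{r_ax_next}, \code{r_p_next},
#'   \code{node_index}) and attributes \code{params}, \code{n_nodes},
#'   \code{N_wraps}.  Axial resistances (\code{Mohm}) are between this
#'   compartment's centre and the next's.
#' @examples
#' chain <- build_axon(cable_params("optic_nerve"), n_nodes = 5)
#' table(chain$kind)
#' @export
build_axon <- function(params, n_nodes = 51,
                       internodal_compartments = NULL,
                       node_lengths = NULL,
                       channel_mode = c("constant_density",
                                        "constant_number"),
                       N_wraps = NULL, L_internode = NULL) {
  stopifnot(inherits(params, "cable_params"))
  channel_mode <- match.arg(channel_mode)
  if (n_nodes < 2) stop("need at least 2 nodes", call. = FALSE)
  if (is.null(N_wraps)) N_wraps <- params$N_wraps
  if (N_wraps < 1) stop("N_wraps must be >= 1", call. = FALSE)
  if (is.null(L_internode)) L_internode <- params$L_internode
  if (is.null(internodal_compartments)) {
    internodal_compartments <-
      default_compartment_count(params, L_internode)
  }
  if (is.null(node_lengths)) node_lengths <- params$L_node
  if (length(node_lengths) == 1L) {
    node_lengths <- rep(node_lengths, n_nodes)
  }
  if (length(node_lengths) != n_nodes) {
    stop("node_lengths must have length 1 or n_nodes", call. = FALSE)
  }
  if (any(!is.finite(node_lengths) | node_lengths <= 0)) {
    stop("node lengths must be positive", call. = FALSE)
  }

  seg <- internodal_segment_lengths(params, L_internode,
                                    internodal_compartments)

  radii <- lamella_radii(params$d_axon_internode, N_wraps,
                         params$periodicity, params$w_internode)

  # one internodal region: paranode | internode | paranode
  n_seg <- length(seg$lengths)
  region_kind <- seg$kind
  region_len <- seg$lengths

  kinds <- character(0); lens <- numeric(0); node_idx <- integer(0)
  for (i in seq_len(n_nodes)) {
    kinds <- c(kinds, "node")
    lens <- c(lens, node_lengths[i])
    node_idx <- c(node_idx, i)
    if (i < n_nodes) {
      kinds <- c(kinds, region_kind)
      lens <- c(lens, region_len)
      node_idx <- c(node_idx, rep(NA_integer_, n_seg))
    }
  }
  n <- length(kinds)
  is_node <- kinds == "node"
  diam <- ifelse(is_node, params$d_node, params$d_axon_internode)
  area <- pi * diam * lens
  c_mem <- params$c_ax * area * DENS2ABS

  # nodal channel scaling
  scale <- rep(1, n)
  if (channel_mode == "constant_number") {
    scale[is_node] <- params$L_node_ref / lens[is_node]
  }
  g_Na <- ifelse(is_node, params$g_Na, 0) * scale * area * DENS2ABS
  g_Ks <- ifelse(is_node, params$g_Ks, 0) * scale * area * DENS2ABS
  g_Nap <- ifelse(is_node, params$g_Nap, 0) * scale * area * DENS2ABS
  g_L_dens <- ifelse(is_node, params$g_L_node * scale,
                     params$g_L_internode)
  g_L <- g_L_dens * area * DENS2ABS

  c_my <- numeric(n); g_my <- numeric(n)
  sheathed <- !is_node
  c_my[sheathed] <- vapply(lens[sheathed], function(l)
    myelin_series(params$c_my, l, radii), 0)
  g_my[sheathed] <- vapply(lens[sheathed], function(l)
    myelin_series(params$g_my, l, radii), 0)

  w_periax <- rep(NA_real_, n)
  w_periax[kinds == "paranode"] <- params$w_paranode
  w_periax[kinds == "internode"] <- params$w_internode

  # axial half-resistances (Mohm): intracellular uses the local axon
  # cross-section; periaxonal uses the thin annulus pi*d*w.  Nodes have
  # no periaxonal space: the periaxonal pathway is grounded there, with
  # zero nodal half-resistance.
  h_ax <- params$rho_ax * (lens / 2) / (pi * diam^2 / 4) * RES2MOHM
  h_p <- rep(0, n)
  h_p[sheathed] <- params$rho_p * (lens[sheathed] / 2) /
    (pi * diam[sheathed] * w_periax[sheathed] * 1e-3) * RES2MOHM
  r_ax_next <- c(h_ax[-n] + h_ax[-1], NA_real_)
  r_p_next <- c(h_p[-n] + h_p[-1], NA_real_)

  chain <- data.frame(
    kind = kinds, length = lens, diam = diam, area = area,
    c_mem = c_mem, g_Na = g_Na, g_Ks = g_Ks, g_Nap = g_Nap, g_L = g_L,
    c_my = c_my, g_my = g_my, w_periax = w_periax,
    r_ax_next = r_ax_next, r_p_next = r_p_next,
    node_index = node_idx, stringsAsFactors = FALSE)
  structure(chain,
            params = params, n_nodes = as.integer(n_nodes),
            N_wraps = as.integer(N_wraps),
            L_internode = L_internode,
            channel_mode = channel_mode,
            class = c("compartment_chain", "data.frame"))
}

# Default compartment count for an internodal region of length L:
# interior at the preset's baseline resolution, paranodes exact.
default_compartment_count <- function(params, L_internode) {
  if (isTRUE(all.equal(L_internode, params$L_internode)) &&
      !is.null(params$internodal_compartments)) {
    return(params$internodal_compartments)
  }
  dx0 <- params$L_internode / params$internodal_compartments
  k <- max(1L, round(params$L_paranode / dx0))
  interior <- L_internode - 2 * params$L_paranode
  if (interior <= 0) {
    stop("internode length must exceed twice the paranode length",
         call. = FALSE)
  }
  2L * k + max(1L, round(interior / dx0))
}

# Per-region compartment lengths and kinds (paranode ends, internode
# interior).  Uniform grid when dx divides the paranode exactly.
internodal_segment_lengths <- function(params, L_internode, n_comp) {
  dx <- L_internode / n_comp
  k <- params$L_paranode / dx
  if (abs(k - round(k)) < 1e-9 && round(k) >= 1 &&
      n_comp - 2 * round(k) >= 1) {
    k <- as.integer(round(k))
    lens <- rep(dx, n_comp)
  } else {
    k <- max(1L, as.integer(round(k)))
    n_int <- n_comp - 2L * k
    if (n_int < 1) {
      stop("internodal_compartments too small to resolve the paranodes",
           call. = FALSE)
    }
    lens <- c(rep(params$L_paranode / k, k),
              rep((L_internode - 2 * params$L_paranode) / n_int, n_int),
              rep(params$L_paranode / k, k))
  }
  kind <- c(rep("paranode", k),
            rep("internode", length(lens) - 2L * k),
            rep("paranode", k))
  list(lengths = lens, kind = kind, k_paranode = k)
}

#' @export
print.compartment_chain <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Compartment chain: %d nodes, %d compartments, preset '%s'\n",
    attr(x, "n_nodes"), nrow(x), p$name))
  cat(sprintf("  total length %.1f um, %d myelin wraps, mode %s\n",
              sum(x$length), attr(x, "N_wraps"), attr(x, "channel_mode")))
  invisible(x)
}

#' @export
summary.compartment_chain <- function(object, ...) {
  k <- table(object$kind)
  res <- list(
    n_compartments = nrow(object),
    n_nodes = attr(object, "n_nodes"),
    counts = k,
    total_length_um = sum(object$length),
    total_area_um2 = sum(object$area),
    node_area_um2 = sum(object$area[object$kind == "node"]))
  class(res) <- "summary.compartment_chain"
  res
}

#' @export
print.summary.compartment_chain <- function(x, ...) {
  cat(sprintf("%d compartments (%d nodes); total length %.1f um, area %.1f um2\n",
              x$n_compartments, x$n_nodes, x$total_length_um,
              x$total_area_um2))
  print(x$counts)
  invisible(x)
}

#' Export a compartment chain as CSV
#'
#' One row per compartment, for inspection outside R.
#' @param chain A \code{compartment_chain}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  utils::write.csv(as.data.frame(chain), path, row.names = FALSE)
  invisible(path)
}

#' Membrane-area cost of tuning speed at the node versus the sheath
#'
#' Compares the membrane area that must be added or removed to change
#' conduction speed via node length against the area of adding or
#' removing whole myelin lamellae.  The node area change is
#' \code{pi * d_node * |L_a - L_b|}; the sheath area change is the area
#' of \code{|wraps_delta|} lamellae (two membranes each, at the outer
#' myelin circumference) along one internode.  If node shortening must
#' be compensated by sheath elongation, the sheath area change exceeds
#' the nodal one by a further factor
#' \code{2 * N_wraps * mean wrap radius / node radius} (mean of the
#' innermost and outermost lamella radii); \code{corrected_ratio}
#' divides this factor out.
#'
#' @param params A \code{\link{cable_params}} object.
#' @param node_length_a,node_length_b Node lengths (um) before/after.
#' @param wraps_delta Number of lamellae added (default 1).
#' @return List with \code{node_area_change}, \code{sheath_area_change}
#'   (um^2), \code{ratio}, \code{correction_factor},
#'   \code{corrected_ratio}.
#' @examples
#' membrane_area_ledger(cable_params("optic_nerve"), 1.02, 0.625)
#' @export
membrane_area_ledger <- function(params, node_length_a, node_length_b,
                                 wraps_delta = 1L) {
  stopifnot(inherits(params, "cable_params"))
  if (node_length_a <= 0 || node_length_b <= 0) {
    stop("node lengths must be positive", call. = FALSE)
  }
  dL <- abs(node_length_a - node_length_b)
  if (dL == 0) {
    stop("node lengths are equal: area ratio undefined", call. = FALSE)
  }
  node_area <- pi * params$d_node * dL
  d_outer <- params$d_axon_internode / params$g_ratio
  sheath_area <- abs(wraps_delta) * 2 * pi * d_outer * params$L_internode
  radii <- lamella_radii(params$d_axon_internode, params$N_wraps,
                         params$periodicity, params$w_internode)
  mean_radius <- (radii[1] + radii[length(radii)]) / 2
  corr <- 2 * params$N_wraps * mean_radius / (params$d_node / 2)
  list(node_area_change = node_area,
       sheath_area_change = sheath_area,
       ratio = sheath_area / node_area,
       correction_factor = corr,
       corrected_ratio = sheath_area / node_area / corr)
}

#' Fraction of membrane capacitance contributed by the node
#'
#' Over one repeating unit (one node plus one internodal region), the
#' internodal axolemma capacitance is in series with the
#' \code{2 * N_wraps} myelin membranes, so the effective internodal
#' capacitance is far below its axolemma value, and the short node
#' contributes a disproportionate share of the total.
#'
#' @param params A \code{\link{cable_params}} object.
#' @return Dimensionless fraction in (0, 1).
#' @examples
#' nodal_capacitance_fraction(cable_params("optic_nerve"))  # ~0.08
#' nodal_capacitance_fraction(cable_params("cortex"))       # ~0.14
#' @export
nodal_capacitance_fraction <- function(params) {
  stopifnot(inherits(params, "cable_params"))
  C_node <- params$c_ax * pi * params$d_node * params$L_node * DENS2ABS
  C_axol <- params$c_ax * pi * params$d_axon_internode *
    params$L_internode * DENS2ABS
  radii <- lamella_radii(params$d_axon_internode, params$N_wraps,
                         params$periodicity, params$w_internode)
  C_my <- myelin_series(params$c_my, params$L_internode, radii)
  C_int <- 1 / (1 / C_axol + 1 / C_my)
  C_node / (C_node + C_int)
}
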