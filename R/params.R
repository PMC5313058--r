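#' Electrical and geometrical parameters of a myelinated axon model
#'
#' Construct a validated parameter set for the double-cable axon model.
#' Two presets are shipped, \code{"optic_nerve"} and \code{"cortex"},
#' describing rat optic nerve and layer V cortical grey matter axons.
#' All fields use the mixed units conventional in the field: conductance
#' densities in mS/cm^2, capacitances in uF/cm^2, resistivities in
#' ohm.cm, potentials in mV, lengths and diameters in um, periaxonal
#' widths and the myelin periodicity in nm, and the paranodal spiral
#' cross-section in nm^2. Internal computations convert at the boundary.
#'
#' @param preset Name of a shipped preset (\code{"optic_nerve"} or
#'   \code{"cortex"}), or a path to a YAML file with the same fields.
#' @param ... Named fields overriding the preset, e.g. \code{L_node = 2}.
#'
#' @return An object of class \code{cable_params}: a named list with
#'   fields \code{g_Na}, \code{g_Ks}, \code{g_Nap}, \code{g_L_node},
#'   \code{g_L_internode}, \code{g_my}, \code{c_ax}, \code{c_my},
#'   \code{rho_ax}, \code{rho_p}, \code{E_r}, \code{E_Lk}, \code{E_Na},
#'   \code{E_K}, \code{d_node}, \code{L_node}, \code{L_paranode},
#'   \code{w_paranode}, \code{d_axon_internode}, \code{w_internode},
#'   \code{g_ratio}, \code{N_wraps}, \code{L_internode},
#'   \code{spiral_area}, \code{periodicity},
#'   \code{internodal_compartments} and \code{name}.  The field
#'   \code{L_node_ref} records the preset's mean node length, which the
#'   constant-channel-number scaling refers to (see
#'   \code{\link{scale_nodal_channels}}).
#'
#' @examples
#' p <- cable_params("optic_nerve")
#' p$L_internode  # 139.26 um
#' cortex_long_node <- cable_params("cortex", L_node = 3.7)
#' @export
cable_params <- function(preset = "optic_nerve", ...) {
  if (file.exists(preset)) {
    path <- preset
  } else {
    path <- system.file("extdata", "presets", paste0(preset, ".yaml"),
                        package = "ranvier")
    if (!nzchar(path)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(list_presets(), collapse = ", "), call. = FALSE)
    }
  }
  p <- yaml::read_yaml(path)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(p), "L_node_ref"))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- over
  }
  if (is.null(p$L_node_ref)) p$L_node_ref <- p$L_node
  validate_cable_params(p)
  structure(p, class = "cable_params")
}

#' @rdname cable_params
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "ranvier")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

validate_cable_params <- function(p) {
  pos <- c("g_Na", "g_Ks", "g_Nap", "g_L_node", "g_L_internode", "g_my",
           "c_ax", "c_my", "rho_ax", "rho_p", "d_node", "L_node",
           "L_paranode", "w_paranode", "d_axon_internode", "w_internode",
           "L_internode", "spiral_area", "periodicity", "L_node_ref")
  for (f in pos) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0) {
      stop("parameter '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  for (f in c("E_r", "E_Lk", "E_Na", "E_K")) {
    if (is.null(p[[f]]) || !is.finite(p[[f]])) {
      stop("parameter '", f, "' must be a finite potential (mV)",
           call. = FALSE)
    }
  }
  if (p$g_ratio <= 0 || p$g_ratio >= 1) {
    stop("g_ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  if (p$N_wraps < 1 || p$N_wraps != round(p$N_wraps)) {
    stop("N_wraps must be an integer >= 1", call. = FALSE)
  }
  if (!(p$E_Na > p$E_r && p$E_r > p$E_K)) {
    stop("potentials must be ordered E_Na > E_r > E_K", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.cable_params <- function(x, ...) {
  cat("Myelinated axon parameters (", x$name, ")\n", sep = "")
  cat(sprintf("  node:      d %.2f um, L %.2f um, gNa %g / gKs %g / gNap %g mS/cm2\n",
              x$d_node, x$L_node, x$g_Na, x$g_Ks, x$g_Nap))
  cat(sprintf("  internode: d %.2f um, L %.2f um, %d wraps (g-ratio %.2f)\n",
              x$d_axon_internode, x$L_internode, as.integer(x$N_wraps),
              x$g_ratio))
  cat(sprintf("  paranode:  L %.2f um, effective periaxonal width %.4g nm\n",
              x$L_paranode, x$w_paranode))
  cat(sprintf("  potentials: Er %g, ELk %g, ENa %g, EK %g mV\n",
              x$E_r, x$E_Lk, x$E_Na, x$E_K))
  invisible(x)
}

#' Write a parameter set to a YAML file
#'
#' @param params A \code{cable_params} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cable_params <- function(params, path) {
  stopifnot(inherits(params, "cable_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
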