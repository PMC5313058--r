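# Synthetic axon populations and confocal-like line profiles.
#
# The generator emulates the measured statistics of CNS node-length
# populations: a right-skewed between-axon distribution of axon mean
# node lengths, much tighter within-axon variation, internode lengths
# independent of node length, and summed nodal-marker intensity
# proportional to node length with multiplicative noise.

#' Hierarchical node-length population model
#'
#' Axon mean node lengths are drawn from a lognormal distribution
#' (node lengths are positive and right skewed) with the given
#' between-axon mean and standard deviation; node lengths along one
#' axon are normal around the axon mean with the within-axon s.d.,
#' truncated at \code{min_length}.  Defaults are calibrated to rat
#' callosal/cortical axons: population mean 1.50 um and pooled s.d.
#' 0.58 um with a within-axon s.d. of 0.25 um, so the between-axon
#' s.d. is sqrt(0.58^2 - 0.25^2) = 0.523 um; internodes average
#' 82.7 um, clipped to the observed 27-154 um range; nodal-marker
#' intensity is proportional to node length with 20 percent
#' multiplicative noise.
#'
#' @param mean_length Population mean node length (um).
#' @param between_sd Between-axon s.d. of axon mean node length (um).
#' @param within_sd Within-axon s.d. of node length (um).
#' @param min_length Truncation floor for node lengths (um).
#' @param nodes_per_axon Mean number of measured nodes per axon;
#'   counts are Poisson with this mean, truncated to >= 2.
#' @param internode_mean,internode_sd Internode length moments (um).
#' @param internode_range Clip bounds for internode lengths (um).
#' @param intensity_per_um Nodal-marker intensity per um node length
#'   (a.u.).
#' @param intensity_noise_sd S.d. of the lognormal multiplicative
#'   intensity noise.
#' @return Object of class \code{population_model}.
#' @export
population_model <- function(mean_length = 1.50,
                             between_sd = sqrt(0.58^2 - 0.25^2),
                             within_sd = 0.25,
                             min_length = 0.1,
                             nodes_per_axon = 6.7,
                             internode_mean = 82.7,
                             internode_sd = 34.5,
                             internode_range = c(27, 154),
                             intensity_per_um = 1000,
                             intensity_noise_sd = 0.2) {
  stopifnot(mean_length > 0, between_sd >= 0, within_sd >= 0,
            min_length > 0, nodes_per_axon >= 2,
            internode_mean > 0, internode_sd >= 0,
            internode_range[1] > 0,
            internode_range[2] > internode_range[1])
  structure(as.list(environment()), class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "Node-length population model: mean %.2f um (between-axon s.d. %.2f, within-axon s.d. %.2f)\n",
    x$mean_length, x$between_sd, x$within_sd))
  cat(sprintf("  internodes %.1f um (s.d. %.1f, clipped %g-%g um)\n",
              x$internode_mean, x$internode_sd, x$internode_range[1],
              x$internode_range[2]))
  invisible(x)
}

rlnorm_moments <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower
  }
  out
}

#' Sample a synthetic axon population
#'
#' @param model A \code{\link{population_model}}.
#' @param n_axons Number of axons.
#' @param seed Optional integer seed (a single shared RNG stream is
#'   used for the whole draw; identical seeds give identical output).
#' @return List of axon records, each a list with \code{axon_id},
#'   \code{axon_mean} (um), \code{node_lengths} (um),
#'   \code{internode_lengths} (um, one fewer than nodes) and
#'   \code{nodal_intensity} (a.u., proportional to node length with
#'   multiplicative noise).
#' @examples
#' pop <- sample_population(population_model(), 18, seed = 1)
#' length(pop)
#' @export
sample_population <- function(model, n_axons, seed = NULL) {
  stopifnot(inherits(model, "population_model"), n_axons >= 1)
  if (!is.null(seed)) set.seed(seed)
  means <- rlnorm_moments(n_axons, model$mean_length, model$between_sd)
  lapply(seq_len(n_axons), function(i) {
    k <- max(2L, stats::rpois(1, model$nodes_per_axon))
    lens <- rtrunc_norm(k, means[i], model$within_sd,
                        model$min_length)
    inl <- stats::rnorm(k - 1L, model$internode_mean,
                        model$internode_sd)
    inl <- pmin(pmax(inl, model$internode_range[1]),
                model$internode_range[2])
    noise <- exp(stats::rnorm(k, -model$intensity_noise_sd^2 / 2,
                              model$intensity_noise_sd))
    list(axon_id = i, axon_mean = means[i], node_lengths = lens,
         internode_lengths = inl,
         nodal_intensity = model$intensity_per_um * lens * noise)
  })
}

#' Flatten an axon population to a data frame
#'
#' @param pop Result of \code{\link{sample_population}}.
#' @return Data frame with columns \code{axon}, \code{node},
#'   \code{node_length}, \code{nodal_intensity}.
#' @export
population_to_df <- function(pop) {
  do.call(rbind, lapply(pop, function(a) {
    data.frame(axon = a$axon_id,
               node = seq_along(a$node_lengths),
               node_length = a$node_lengths,
               nodal_intensity = a$nodal_intensity)
  }))
}

#' Confocal rendering model for line profiles
#'
#' @param paranode_length Paranodal marker band length (um).
#' @param peak Paranodal band intensity (a.u.).
#' @param nodal_peak Nodal channel band intensity per um of node
#'   length is \code{nodal_peak} (flat band over the gap, so summed
#'   intensity is proportional to node length).
#' @param psf_sigma Gaussian point-spread-function s.d. (nm).
#' @param pixel Pixel size (nm); 52.7 nm is the acquisition setting
#'   used for along-axon node measurements.
#' @param noise_sd Additive Gaussian noise s.d. (a.u.).
#' @param background Constant background level (a.u.).
#' @return Object of class \code{render_model}.
#' @export
render_model <- function(paranode_length = 1.9, peak = 1000,
                         nodal_peak = 800, psf_sigma = 110,
                         pixel = 52.7, noise_sd = 0, background = 100) {
  stopifnot(pixel > 0, psf_sigma >= 0, paranode_length > 0, peak > 0,
            noise_sd >= 0, background >= 0)
  structure(as.list(environment()), class = "render_model")
}

# boxcar [a, b] of height h convolved with a Gaussian of s.d. sigma
blurred_band <- function(x, a, b, h, sigma) {
  if (sigma == 0) return(h * (x >= a & x <= b))
  h * (stats::pnorm((x - a) / sigma) - stats::pnorm((x - b) / sigma))
}

#' Render a confocal-like line profile of one node
#'
#' Two paranodal boxcar bands flank a gap of \code{node_length}; the
#' nodal channel fills the gap.  Bands are convolved with a Gaussian
#' PSF (analytically, via the error function), sampled at the pixel
#' size, and background plus optional additive noise are applied.
#'
#' @param node_length True node gap length (um).
#' @param render A \code{\link{render_model}}.
#' @return A \code{\link{line_profile}} with attribute
#'   \code{truth} (the generating node length, um).
#' @examples
#' pr <- render_profile(1.5, render_model())
#' node_length_from_profile(pr)  # ~1.5
#' @export
render_profile <- function(node_length, render = render_model()) {
  stopifnot(inherits(render, "render_model"), node_length > 0)
  sigma <- render$psf_sigma / 1e3   # nm -> um
  px <- render$pixel / 1e3
  half <- node_length / 2
  extent <- half + render$paranode_length + 4 * sigma + 0.3
  x <- seq(-extent, extent, by = px)
  para <- blurred_band(x, -half - render$paranode_length, -half,
                       render$peak, sigma) +
    blurred_band(x, half, half + render$paranode_length,
                 render$peak, sigma)
  nodal <- blurred_band(x, -half, half, render$nodal_peak, sigma)
  if (render$noise_sd > 0) {
    para <- para + stats::rnorm(length(x), 0, render$noise_sd)
    nodal <- nodal + stats::rnorm(length(x), 0, render$noise_sd)
  }
  out <- line_profile(x, pmax(para + render$background, 0),
                      pmax(nodal + render$background, 0))
  attr(out, "truth") <- node_length
  out
}

#' Write an end-to-end synthetic fixture to disk
#'
#' Samples an axon population, renders one line profile per node, and
#' writes \code{profiles/axon<A>_node<N>.csv}, \code{truth.csv} (axon,
#' node, true length, rendered file) and \code{manifest.json} (models
#' and seed).  Running the morphometry pipeline on the fixture
#' recovers the generating statistics.
#'
#' @param model A \code{\link{population_model}}.
#' @param render A \code{\link{render_model}}.
#' @param n_axons Number of axons.
#' @param seed Integer seed controlling the single RNG stream.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
end_to_end_fixture <- function(model, render, n_axons, seed, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  pop <- sample_population(model, n_axons, seed = seed)
  rows <- list()
  for (a in pop) {
    for (j in seq_along(a$node_lengths)) {
      pr <- render_profile(a$node_lengths[j], render)
      fn <- sprintf("axon%03d_node%02d.csv", a$axon_id, j)
      utils::write.csv(
        data.frame(position = pr$position, paranode = pr$paranode,
                   nodal = pr$nodal),
        file.path(dir, "profiles", fn), row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        axon = a$axon_id, node = j, true_length = a$node_lengths[j],
        nodal_intensity = a$nodal_intensity[j], file = fn)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(population = unclass(model), render = unclass(render),
         n_axons = n_axons, seed = seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Measure every profile of a fixture directory
#'
#' @param dir A directory written by \code{\link{end_to_end_fixture}}.
#' @return The truth table with added columns \code{measured_length}
#'   and \code{measured_intensity} (NA where unmeasurable).
#' @export
measure_fixture <- function(dir) {
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  truth$measured_length <- NA_real_
  truth$measured_intensity <- NA_real_
  for (i in seq_len(nrow(truth))) {
    pr <- read_line_profile(file.path(dir, "profiles", truth$file[i]))
    m <- tryCatch(node_length_from_profile(pr), error = function(e) NULL)
    if (!is.null(m)) {
      truth$measured_length[i] <- as.numeric(m)
      truth$measured_intensity[i] <-
        summed_nodal_intensity(pr, attr(m, "bounds"))
    }
  }
  truth
}
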