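# Node-length morphometry from confocal line profiles, and the
# along-axon versus between-axon variability analysis.

#' Confocal line profile across a node of Ranvier
#'
#' @param position Sample positions (um), uniformly spaced.
#' @param paranode Paranodal marker intensity (e.g. Caspr), one value
#'   per position.
#' @param nodal Optional nodal channel marker intensity (e.g. NaV1.6).
#' @return Object of class \code{line_profile}.
#' @export
line_profile <- function(position, paranode, nodal = NULL) {
  if (length(position) < 2L) stop("need at least 2 samples",
                                  call. = FALSE)
  d <- diff(position)
  if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d)) {
    stop("positions must be uniformly increasing", call. = FALSE)
  }
  if (length(paranode) != length(position)) {
    stop("paranode intensity length mismatch", call. = FALSE)
  }
  structure(list(position = position, paranode = paranode,
                 nodal = nodal, pixel_nm = mean(d) * 1e3),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf(
    "Line profile: %d samples, pixel %.1f nm, span %.2f um%s\n",
    length(x$position), x$pixel_nm, diff(range(x$position)),
    if (is.null(x$nodal)) "" else ", with nodal channel"))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, ...) {
  graphics::plot(x$position, x$paranode, type = "l",
                 xlab = "position (um)", ylab = "intensity (a.u.)", ...)
  if (!is.null(x$nodal)) {
    graphics::lines(x$position, x$nodal, lty = 2)
    graphics::legend("topright", c("paranode", "nodal"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Read a line profile from CSV/TSV
#'
#' Expects columns \code{position}, \code{paranode} and optionally
#' \code{nodal} (comma or tab separated).
#' @param path File path.
#' @return A \code{\link{line_profile}}.
#' @export
read_line_profile <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  line_profile(df$position, df$paranode,
               if ("nodal" %in% names(df)) df$nodal else NULL)
}

# modal background estimate: mean of the lowest decile of the signal
estimate_background <- function(v) {
  q <- stats::quantile(v, 0.1, names = FALSE)
  mean(v[v <= q])
}

local_maxima <- function(v) {
  n <- length(v)
  which(v > c(-Inf, v[-n]) & v >= c(v[-1], -Inf))
}

#' Node length from a paranodal intensity profile
#'
#' The node is delimited by the two flanking paranodal intensity
#' peaks.  For each paranode independently, the half-maximum is half
#' of that paranode's own background-subtracted peak intensity; the
#' node length is the distance between the two node-facing
#' half-maximum crossings, each found by linear interpolation between
#' samples.
#'
#' @param profile A \code{\link{line_profile}}.
#' @param background \code{"modal"} (mean of the lowest intensity
#'   decile), a number, or 0 to skip subtraction.
#' @param smooth If \code{TRUE}, a 3-point moving average is applied
#'   before peak finding (measurement uses the raw profile by
#'   default).
#' @return Node length (um), with attributes \code{bounds} (left and
#'   right crossing positions), \code{peaks} (peak positions) and
#'   \code{background}.
#' @examples
#' x <- seq(0, 6, by = 0.05)
#' y <- dnorm(x, 2, 0.3) + dnorm(x, 4, 0.3)
#' node_length_from_profile(line_profile(x, y), background = 0)
#' @export
node_length_from_profile <- function(profile, background = "modal",
                                     smooth = FALSE) {
  stopifnot(inherits(profile, "line_profile"))
  x <- profile$position
  v <- profile$paranode
  bg <- if (identical(background, "modal")) estimate_background(v)
        else as.numeric(background)
  v <- pmax(v - bg, 0)
  w <- if (smooth) stats::filter(v, rep(1 / 3, 3), sides = 2) else v
  w[is.na(w)] <- 0

  peaks <- local_maxima(as.numeric(w))
  peaks <- peaks[w[peaks] > 0]
  if (length(peaks) < 2L) {
    stop("unmeasurable profile: fewer than two paranodal peaks found",
         call. = FALSE)
  }
  # the two highest maxima separated by the deepest local minimum;
  # ties broken toward the outermost pair
  best <- NULL
  ord <- order(w[peaks], x[peaks])  # height asc, outer-breaking below
  cand <- peaks[rev(ord)]
  for (i in 1:(length(cand) - 1)) {
    for (j in (i + 1):length(cand)) {
      a <- min(cand[i], cand[j]); b <- max(cand[i], cand[j])
      valley <- min(w[a:b])
      score <- min(w[a], w[b]) - valley
      if (is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
           (b - a) > best$b - best$a)) {
        best <- list(a = a, b = b, score = score)
      }
    }
  }
  a <- best$a; b <- best$b
  if (best$score <= 0) {
    stop("unmeasurable profile: no node gap between paranodal peaks",
         call. = FALSE)
  }

  cross <- function(peak_idx, direction) {
    half <- w[peak_idx] / 2
    idx <- peak_idx
    repeat {
      nxt <- idx + direction
      if (nxt < 1 || nxt > length(w)) {
        stop("unmeasurable profile: no node-facing half-maximum ",
             "crossing", call. = FALSE)
      }
      if (w[nxt] < half && w[idx] >= half) {
        frac <- (w[idx] - half) / (w[idx] - w[nxt])
        return(x[idx] + frac * (x[nxt] - x[idx]))
      }
      idx <- nxt
      if ((direction > 0 && idx >= b) || (direction < 0 && idx <= a)) {
        stop("unmeasurable profile: paranodal signal does not fall ",
             "below half maximum inside the gap", call. = FALSE)
      }
    }
  }
  left <- cross(a, +1L)
  right <- cross(b, -1L)
  len <- right - left
  if (len <= 0) {
    stop("unmeasurable profile: crossings are not ordered",
         call. = FALSE)
  }
  attr(len, "bounds") <- c(left, right)
  attr(len, "peaks") <- c(x[a], x[b])
  attr(len, "background") <- bg
  len
}

#' Summed nodal-marker intensity over the node
#'
#' Background-subtracted sum of the nodal channel between the node
#' bounds; proportional to the number of nodal channels if their
#' density is uniform.
#'
#' @param profile A \code{\link{line_profile}} with a nodal channel.
#' @param node_bounds Length-2 vector (um), e.g. the \code{bounds}
#'   attribute of \code{\link{node_length_from_profile}}.
#' @param background As in \code{\link{node_length_from_profile}},
#'   applied to the nodal channel.
#' @return Summed intensity (a.u.).
#' @export
summed_nodal_intensity <- function(profile, node_bounds,
                                   background = "modal") {
  stopifnot(inherits(profile, "line_profile"))
  if (is.null(profile$nodal)) {
    stop("profile has no nodal channel", call. = FALSE)
  }
  v <- profile$nodal
  bg <- if (identical(background, "modal")) estimate_background(v)
        else as.numeric(background)
  v <- pmax(v - bg, 0)
  sel <- profile$position >= node_bounds[1] &
    profile$position <= node_bounds[2]
  sum(v[sel])
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean.
#' @param values Numeric vector (>= 2 values, positive mean).
#' @return Dimensionless CoV.
#' @export
cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be positive", call. = FALSE)
  stats::sd(values) / m
}

#' Along-axon versus between-axon node length variability
#'
#' Compares the coefficient of variation of node lengths along each
#' axon with the CoV pooled over all nodes of all axons.  The per-axon
#' reduction is \code{(1 - CoV_axon / CoV_pooled) * 100}; the mean
#' reduction, its standard error and a one-sample t-test against zero
#' are returned.  A large positive reduction means node lengths are
#' far more uniform along axons than across the population.
#'
#' @param axons Either a list of records (each with a
#'   \code{node_lengths} element) or a data frame with columns
#'   \code{axon} and \code{node_length}.
#' @return List with \code{cov_pooled}, \code{cov_per_axon},
#'   \code{reduction_pct} (per axon), \code{mean_reduction_pct},
#'   \code{sem_reduction_pct}, \code{p_value} and \code{n_axons}.
#' @export
along_vs_between_reduction <- function(axons) {
  if (is.data.frame(axons)) {
    axons <- lapply(split(axons$node_length, axons$axon),
                    function(v) list(node_lengths = v))
  }
  lens <- lapply(axons, `[[`, "node_lengths")
  keep <- vapply(lens, length, 0L) >= 2L
  if (any(!keep)) {
    warning(sum(!keep), " axon(s) with fewer than 2 nodes excluded")
    lens <- lens[keep]
  }
  if (length(lens) < 2L) {
    stop("need at least 2 axons with >= 2 nodes each", call. = FALSE)
  }
  pooled <- cv(unlist(lens))
  per <- vapply(lens, cv, 0)
  red <- (1 - per / pooled) * 100
  tt <- stats::t.test(red, mu = 0)
  list(cov_pooled = pooled, cov_per_axon = per, reduction_pct = red,
       mean_reduction_pct = mean(red),
       sem_reduction_pct = stats::sd(red) / sqrt(length(red)),
       p_value = tt$p.value, n_axons = length(red))
}

#' Ordinary least-squares slope with a t-test against zero
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @return List with \code{slope}, \code{se}, \code{p_value} (two-sided
#'   t-test on the slope) and the fitted \code{lm} object.
#' @export
regression_slope <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x)) {
    stop("need >= 3 paired points", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = cf["x", "Estimate"], se = cf["x", "Std. Error"],
       p_value = cf["x", "Pr(>|t|)"], fit = fit)
}
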