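#' Number of available locations for a line-buffer
#'
#' The survey design generates available locations in proportion to effort:
#' kilometres of transect walked (summed over repeat surveys) multiplied by 3.
#' A 4-km transect surveyed in 4 years gives 16 km x 3 = 48 locations.
#' Fractional expectations are rounded to the nearest integer, ties away from
#' zero (2.5 km x 3 = 7.5 -> 8).
#'
#' @param effort_km_total effort in kilometres (>= 0).
#' @param multiplier locations per km of effort (default 3).
#' @return integer count.
#' @export
n_available <- function(effort_km_total, multiplier = 3) {
  if (any(effort_km_total < 0)) stop("effort must be non-negative")
  as.integer(floor(effort_km_total * multiplier + 0.5))
}

#' Sample uniform points in a transect line-buffer
#'
#' Points are uniform over the rectangular buffer of half-width `half_width_m`
#' around the polyline: a segment is chosen with probability proportional to
#' its length, a position uniform along it, and a signed perpendicular offset
#' uniform on (-W, W). For the straight transects of the systematic design
#' this is exactly uniform over the buffer. The recorded `perp_distance_m` is
#' the absolute offset.
#'
#' @param n number of points (>= 0).
#' @param transect 2-column vertex matrix.
#' @param half_width_m buffer half-width (m).
#' @return data.frame with `x`, `y`, `perp_distance_m`.
#' @export
sample_in_buffer <- function(n, transect, half_width_m = 200) {
  if (n == 0) {
    return(data.frame(x = numeric(), y = numeric(),
                      perp_distance_m = numeric()))
  }
  segs <- diff(transect)
  len <- sqrt(rowSums(segs^2))
  si <- sample.int(length(len), n, replace = TRUE, prob = len)
  t <- stats::runif(n)
  off <- stats::runif(n, -half_width_m, half_width_m)
  ux <- segs[si, 1] / len[si]; uy <- segs[si, 2] / len[si]
  # unit normal (rotate tangent by +90 degrees)
  nx <- -uy; ny <- ux
  data.frame(
    x = transect[si, 1] + t * segs[si, 1] + off * nx,
    y = transect[si, 2] + t * segs[si, 2] + off * ny,
    perp_distance_m = abs(off))
}

#' Fit a half-normal detection function to perpendicular distances
#'
#' Detection probability in line-transect sampling declines with
#' perpendicular distance d as `g(d) = exp(-d^2 / (2 sigma^2))`, with
#' `g(0) = 1`. Untruncated (default), the maximum-likelihood scale has the
#' closed form `sigma_hat = sqrt(sum(d^2) / n)`; the function verifies a
#' 1-D numerical optimizer agrees. With `truncation = W` the likelihood is
#' normalized on `[0, W]` (distances beyond W were discarded upstream) and
#' sigma is found numerically.
#'
#' @param perp_distances numeric vector of distances (m); at least two must be
#'   strictly positive.
#' @param truncation `NULL` for the untruncated fit, or the truncation
#'   distance in metres.
#' @return object of class `halfnormal_detection`: list with `sigma_m`, `n`,
#'   `loglik`, `truncation`.
#' @export
fit_halfnormal <- function(perp_distances, truncation = NULL) {
  d <- perp_distances[!is.na(perp_distances)]
  if (sum(d > 0) < 2) {
    stop("need at least two strictly positive distances (degenerate fit)")
  }
  if (any(d < 0)) stop("distances must be non-negative")
  n <- length(d)
  nll <- function(sigma) {
    # density of |N(0, sigma^2)| truncated to [0, W]
    norm <- if (is.null(truncation)) 1 else
      2 * (stats::pnorm(truncation / sigma) - 0.5)
    -sum(-d^2 / (2 * sigma^2) - log(sigma) - 0.5 * log(2 * pi) + log(2) -
           log(norm))
  }
  closed <- sqrt(sum(d^2) / n)
  if (is.null(truncation)) {
    opt <- stats::optimize(nll, c(closed / 10, closed * 10))
    if (abs(opt$minimum - closed) > 1e-6 * closed) {
      stop("numerical optimizer disagrees with the closed-form MLE")
    }
    sigma <- closed
  } else {
    opt <- stats::optimize(nll, c(closed / 10, closed * 10), tol = 1e-10)
    sigma <- opt$minimum
  }
  structure(list(sigma_m = sigma, n = n, loglik = -nll(sigma),
                 truncation = truncation),
            class = "halfnormal_detection")
}

#' @export
print.halfnormal_detection <- function(x, ...) {
  cat(sprintf(
    "half-normal detection: sigma = %.2f m (n = %d, logLik = %.2f%s)\n",
    x$sigma_m, x$n, x$loglik,
    if (is.null(x$truncation)) "" else sprintf(", truncated at %g m",
                                               x$truncation)))
  invisible(x)
}

#' Detection probability at a perpendicular distance
#'
#' `g(d) = exp(-d^2 / (2 sigma^2))`: 1 on the line, strictly decreasing,
#' in (0, 1].
#'
#' @param d_m distance(s), metres (>= 0).
#' @param detection a `halfnormal_detection` or a numeric sigma.
#' @return detection probabilities.
#' @export
detection_probability <- function(d_m, detection) {
  if (any(d_m < 0)) stop("distances must be non-negative")
  sigma <- if (inherits(detection, "halfnormal_detection")) {
    detection$sigma_m
  } else detection
  exp(-d_m^2 / (2 * sigma^2))
}

#' Thin available points by detection probability
#'
#' Rejection step of the detection-adjusted availability procedure: each
#' candidate point gets a detection probability `O = g(d)` from its distance
#' to the line and an independent uniform draw `P`; it is kept when
#' `P < O` (strict). After thinning, available distances follow the same
#' truncated half-normal distribution as the observations.
#'
#' @param points data.frame with `perp_distance_m`.
#' @param detection a `halfnormal_detection` or numeric sigma.
#' @return `points` with columns `o_i` (detection probability), `p_i`
#'   (uniform draw) and `kept` (logical) appended; draws are stored so the
#'   thinning is fully reproducible.
#' @export
thin_by_detection <- function(points, detection) {
  points$o_i <- detection_probability(points$perp_distance_m, detection)
  points$p_i <- stats::runif(nrow(points))
  points$kept <- points$p_i < points$o_i
  points
}

#' Generate detection-adjusted available locations for a set of surveys
#'
#' The four-step procedure: (1) effort-proportional uniform points in each
#' survey's line-buffer (3 per km of effort, generated for every survey,
#' including surveys without used locations); (2) a half-normal detection
#' function fitted to the used-location distances (pooled across areas by
#' default, normalized on the buffer); (3) a detection probability per
#' candidate from its line distance; (4) rejection thinning. RNG substreams
#' are derived per survey from `seed`, so adding a survey does not perturb the
#' points of the others.
#'
#' @param transects a `transect_set`.
#' @param surveys full survey table (`survey_id`, `transect_id`, `area_id`,
#'   `effort_km`).
#' @param used_distances retained used-location perpendicular distances (m)
#'   for the detection fit; alternatively pass a fitted `detection`.
#' @param half_width_m buffer half-width (m).
#' @param multiplier available locations per km of effort.
#' @param seed integer seed.
#' @param detection optional pre-fitted `halfnormal_detection` (overrides
#'   `used_distances`).
#' @param truncation truncation for the detection fit; defaults to
#'   `half_width_m`.
#' @param ledger optional ledger to append to.
#' @return list with `points` (all candidates, with `survey_id`, `area_id`,
#'   `o_i`, `p_i`, `kept`), `available` (kept subset), `detection`, `ledger`.
#' @export
generate_availability <- function(transects, surveys, used_distances = NULL,
                                  half_width_m = 200, multiplier = 3,
                                  seed = 1, detection = NULL,
                                  truncation = half_width_m,
                                  ledger = new_ledger()) {
  if (is.null(detection)) {
    if (is.null(used_distances)) {
      stop("either used_distances or a fitted detection is required")
    }
    detection <- fit_halfnormal(used_distances, truncation = truncation)
  }
  pieces <- vector("list", nrow(surveys))
  for (i in seq_len(nrow(surveys))) {
    sv <- surveys[i, ]
    n <- n_available(sv$effort_km, multiplier)
    sub_seed <- (seed %% 65011) * 33013 + i  # per-survey substream, < 2^31
    pts <- with_seed(sub_seed, {
      p <- sample_in_buffer(n, transects$lines[[sv$transect_id]], half_width_m)
      thin_by_detection(p, detection)
    })
    if (nrow(pts)) {
      pts$survey_id <- sv$survey_id
      pts$area_id <- sv$area_id
      pts$transect_id <- sv$transect_id
    }
    pieces[[i]] <- pts
  }
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  pts <- do.call(rbind, pieces)
  ledger <- ledger_add(ledger, "Generated random locations",
                       available = nrow(pts),
                       transects = length(unique(pts$transect_id)),
                       areas = length(unique(pts$area_id)))
  avail <- pts[pts$kept, ]
  ledger <- ledger_add(ledger, "Adjusted random locations",
                       available = nrow(avail),
                       transects = length(unique(avail$transect_id)),
                       areas = length(unique(avail$area_id)))
  list(points = pts, available = avail, detection = detection,
       ledger = ledger)
}

#' Serialize a detection fit to a key-value text file
#'
#' @param detection a `halfnormal_detection`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_detection <- function(detection, path) {
  writeLines(c(
    sprintf("sigma_m %.10g", detection$sigma_m),
    sprintf("n %d", detection$n),
    sprintf("loglik %.10g", detection$loglik),
    sprintf("truncation %s",
            if (is.null(detection$truncation)) "none"
            else format(detection$truncation))), path)
  invisible(path)
}
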