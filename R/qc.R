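#' Perpendicular distance from a point to a transect polyline
#'
#' Minimum Euclidean distance from the point to any segment of the polyline,
#' with endpoint capping (distance to a segment endpoint where the foot of the
#' perpendicular falls outside the segment). Transects may bend; a straight
#' line is the two-vertex special case.
#'
#' @param point numeric length-2 (x, y) in metres.
#' @param polyline 2-column matrix of vertices (>= 2 rows).
#' @return distance in metres.
#' @export
perpendicular_distance <- function(point, polyline) {
  d <- dist_to_polyline(matrix(point, ncol = 2), polyline)
  d[1]
}

#' Vectorised point-to-polyline distances
#'
#' @param xy n x 2 matrix of points.
#' @param polyline 2-column vertex matrix.
#' @return numeric vector of length n.
#' @export
dist_to_polyline <- function(xy, polyline) {
  if (!is.matrix(polyline) || nrow(polyline) < 2) {
    stop("polyline needs at least 2 vertices")
  }
  seg_len2 <- rowSums(diff(polyline)^2)
  if (all(seg_len2 == 0)) stop("degenerate zero-length polyline")
  best <- rep(Inf, nrow(xy))
  for (s in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[s, ]; b <- polyline[s + 1L, ]
    ab2 <- seg_len2[s]
    if (ab2 == 0) {  # repeated vertex: plain point distance
      d2 <- (xy[, 1] - a[1])^2 + (xy[, 2] - a[2])^2
    } else {
      t <- ((xy[, 1] - a[1]) * (b[1] - a[1]) +
            (xy[, 2] - a[2]) * (b[2] - a[2])) / ab2
      t <- pmin(pmax(t, 0), 1)
      px <- a[1] + t * (b[1] - a[1]); py <- a[2] + t * (b[2] - a[2])
      d2 <- (xy[, 1] - px)^2 + (xy[, 2] - py)^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Is a point inside a transect line-buffer?
#'
#' The buffer covers `half_width_m` on each side of the line; the boundary is
#' inclusive (a point at exactly the half-width is inside).
#'
#' @param transect 2-column vertex matrix.
#' @param point numeric length-2 (x, y).
#' @param half_width_m buffer half-width, metres (default 200, the survey
#'   protocol's truncation distance).
#' @return logical.
#' @export
in_buffer <- function(transect, point, half_width_m = 200) {
  if (half_width_m <= 0) stop("half_width_m must be positive")
  perpendicular_distance(point, transect) <= half_width_m
}

#' Create an empty data-accounting ledger
#'
#' The ledger mirrors the study's data-management table: one row per action
#' with the used-location, survey, available-location, transect and area
#' counts after that action (`NA` where a count does not apply).
#'
#' @return zero-row data.frame of class `qc_ledger`.
#' @export
new_ledger <- function() {
  structure(
    data.frame(action = character(), used = integer(), surveys = integer(),
               available = integer(), transects = integer(), areas = integer(),
               stringsAsFactors = FALSE),
    class = c("qc_ledger", "data.frame"))
}

#' Append a row to a ledger
#'
#' @param ledger a `qc_ledger`.
#' @param action short description of the step.
#' @param used,surveys,available,transects,areas counts after the step.
#' @return the extended ledger.
#' @export
ledger_add <- function(ledger, action, used = NA, surveys = NA,
                       available = NA, transects = NA, areas = NA) {
  row <- data.frame(action = action, used = as.integer(used),
                    surveys = as.integer(surveys),
                    available = as.integer(available),
                    transects = as.integer(transects),
                    areas = as.integer(areas), stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(ledger), row),
            class = c("qc_ledger", "data.frame"))
}

# count helper for ledger rows
obs_counts <- function(obs, surveys) {
  sv <- surveys[surveys$survey_id %in% unique(obs$survey_id), ]
  c(used = nrow(obs), surveys = length(unique(obs$survey_id)),
    transects = length(unique(sv$transect_id)),
    areas = length(unique(sv$area_id)))
}

#' Apply the observation quality-control filters
#'
#' Two sequential filters on used locations, in the survey protocol's order:
#' 1. remove observations outside the 200-m line-buffer (geometric,
#'    computed perpendicular distance; boundary inclusive);
#' 2. remove observations whose reported perpendicular distance deviates from
#'    the computed one by strictly more than `max_deviation_m` (default 30 m,
#'    the vegetation-map resolution).
#'
#' Every input observation receives a `qc_status` of `retained`,
#' `removed_buffer` or `removed_deviation`, and `computed_perp_distance_m` is
#' filled in. Observations are never moved or corrected, only kept or removed.
#'
#' @param observations data.frame with `survey_id`, `x`, `y`,
#'   `reported_perp_distance_m`.
#' @param transects a `transect_set`.
#' @param surveys survey table joining `survey_id` to `transect_id`.
#' @param buffer_m buffer half-width (m).
#' @param max_deviation_m deviation cutoff (m); strictly greater is removed.
#' @param ledger optional existing ledger to append to.
#' @return list with `observations` (all rows, flagged), `retained` (subset),
#'   and `ledger`.
#' @export
apply_qc <- function(observations, transects, surveys,
                     buffer_m = 200, max_deviation_m = 30,
                     ledger = new_ledger()) {
  obs <- observations
  sv_tr <- surveys$transect_id[match(obs$survey_id, surveys$survey_id)]
  orphan <- is.na(sv_tr) | !(sv_tr %in% names(transects$lines))
  if (any(orphan)) {
    stop("observations with no matching transect: survey_id ",
         paste(unique(obs$survey_id[orphan]), collapse = ", "))
  }
  obs$computed_perp_distance_m <- NA_real_
  for (tid in unique(sv_tr)) {
    i <- which(sv_tr == tid)
    obs$computed_perp_distance_m[i] <-
      dist_to_polyline(cbind(obs$x[i], obs$y[i]), transects$lines[[tid]])
  }
  n0 <- obs_counts(obs, surveys)
  ledger <- ledger_add(ledger, "Imported data", used = n0["used"],
                       surveys = n0["surveys"], transects = n0["transects"],
                       areas = n0["areas"])

  obs$qc_status <- "retained"
  obs$qc_status[obs$computed_perp_distance_m > buffer_m] <- "removed_buffer"
  keep1 <- obs[obs$qc_status == "retained", ]
  n1 <- obs_counts(keep1, surveys)
  ledger <- ledger_add(ledger,
                       sprintf("Removed used locations > %g m", buffer_m),
                       used = n1["used"], surveys = n1["surveys"],
                       transects = n1["transects"], areas = n1["areas"])

  dev <- abs(obs$reported_perp_distance_m - obs$computed_perp_distance_m)
  bad_dev <- obs$qc_status == "retained" & dev > max_deviation_m
  obs$qc_status[bad_dev] <- "removed_deviation"
  keep2 <- obs[obs$qc_status == "retained", ]
  n2 <- obs_counts(keep2, surveys)
  ledger <- ledger_add(
    ledger, sprintf("Removed used locations > %g-m deviation", max_deviation_m),
    used = n2["used"], surveys = n2["surveys"],
    transects = n2["transects"], areas = n2["areas"])

  list(observations = obs, retained = keep2, ledger = ledger)
}

#' Drop surveys with no retained observations
#'
#' The used-location dataset excludes surveys without observations; this does
#' not touch the used locations themselves, and the full survey list stays in
#' force for availability generation (available locations are generated for
#' every survey, including those without used locations).
#'
#' @param observations retained observations (post-QC).
#' @param surveys full survey table.
#' @param ledger optional ledger to append to.
#' @return list with `surveys_used` (surveys carrying >= 1 observation),
#'   `surveys_all` (unchanged input, for availability generation), `ledger`.
#' @export
drop_empty_surveys <- function(observations, surveys, ledger = new_ledger()) {
  keep <- surveys$survey_id %in% unique(observations$survey_id)
  if (!any(keep)) warning("all surveys are empty: used-location set is empty")
  su <- surveys[keep, ]
  ledger <- ledger_add(ledger, "Removed surveys without used locations",
                       used = nrow(observations), surveys = nrow(su),
                       transects = length(unique(su$transect_id)),
                       areas = length(unique(su$area_id)))
  list(surveys_used = su, surveys_all = surveys, ledger = ledger)
}

#' Write observations or a ledger to CSV
#'
#' @param x data.frame (observations, surveys or ledger).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
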