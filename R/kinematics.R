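#' Kinematic scoring configuration
#'
#' Houses every operational threshold used to score a trajectory: the larval
#' body length, the 45-degree turn rule, the body-length-derived movement
#' threshold, and the sampling scheme. The movement threshold, when not given
#' explicitly, is derived from the body length as the chord traveled by the
#' head when the larva rotates 90 degrees about an axis at the body-length
#' midpoint: `2 * (L/2) * sin(45 deg) = L * sin(45 deg)`, which gives
#' approximately 2.3 mm for the default 3.25 mm larva. Head displacements at
#' or below this threshold are treated as body swirls without horizontal
#' locomotion, not as movements.
#'
#' @param body_length_mm Average larval body length in mm (default 3.25).
#' @param turn_threshold_deg Unsigned intersection angle, in degrees, that
#'   two successive tracking vectors must strictly exceed to score a turn
#'   (default 45; must lie in (0, 180)).
#' @param movement_threshold_mm Per-interval head displacement, in mm, that
#'   must be strictly exceeded to score a movement instance. Default `NULL`
#'   derives `body_length_mm * sin(pi/4)`.
#' @param sample_interval_s Sampling interval in seconds (default 1).
#' @param assay_duration_s Nominal assay duration in seconds (default 300,
#'   i.e. 5 minutes).
#' @param min_vector_mm Minimum displacement, in mm, for a tracking vector to
#'   have a defined direction (default 0.1). Shorter vectors are excluded
#'   from turn evaluation; must be smaller than the movement threshold.
#'
#' @return An object of class `"kinematics_config"`.
#' @examples
#' cfg <- kinematics_config()
#' cfg$movement_threshold_mm  # ~2.298 mm
#' @export
kinematics_config <- function(body_length_mm = 3.25,
                              turn_threshold_deg = 45,
                              movement_threshold_mm = NULL,
                              sample_interval_s = 1,
                              assay_duration_s = 300,
                              min_vector_mm = 0.1) {
  stopifnot(
    is.numeric(body_length_mm), length(body_length_mm) == 1L,
    is.finite(body_length_mm), body_length_mm > 0,
    is.numeric(turn_threshold_deg), length(turn_threshold_deg) == 1L,
    turn_threshold_deg > 0, turn_threshold_deg < 180,
    is.numeric(sample_interval_s), sample_interval_s > 0,
    is.numeric(assay_duration_s), assay_duration_s > 0,
    is.numeric(min_vector_mm), min_vector_mm >= 0
  )
  if (is.null(movement_threshold_mm)) {
    movement_threshold_mm <- movement_threshold(body_length_mm)
  }
  stopifnot(is.numeric(movement_threshold_mm), movement_threshold_mm > 0)
  if (min_vector_mm >= movement_threshold_mm) {
    stop("min_vector_mm must be smaller than movement_threshold_mm",
         call. = FALSE)
  }
  structure(
    list(
      body_length_mm = body_length_mm,
      turn_threshold_deg = turn_threshold_deg,
      movement_threshold_mm = movement_threshold_mm,
      sample_interval_s = sample_interval_s,
      assay_duration_s = assay_duration_s,
      min_vector_mm = min_vector_mm
    ),
    class = "kinematics_config"
  )
}

#' @export
print.kinematics_config <- function(x, ...) {
  cat("<kinematics_config>\n")
  cat(sprintf("  body length:        %.3f mm\n", x$body_length_mm))
  cat(sprintf("  turn threshold:     %.1f deg (strict)\n",
              x$turn_threshold_deg))
  cat(sprintf("  movement threshold: %.4f mm (strict)\n",
              x$movement_threshold_mm))
  cat(sprintf("  sampling:           every %.3g s over %.3g s\n",
              x$sample_interval_s, x$assay_duration_s))
  cat(sprintf("  min vector length:  %.3g mm\n", x$min_vector_mm))
  invisible(x)
}

#' Body-length-derived movement threshold
#'
#' The head's chord displacement when a larva of length `L` rotates 90
#' degrees about an axis at its body-length midpoint: the head sits at radius
#' `L/2`, so the chord of the quarter-circle is
#' `2 * (L/2) * sin(45 deg) = L * sin(45 deg)`. For the average body length
#' of 3.25 mm this is 2.298 mm, i.e. about 2.3 mm. Displacements not
#' exceeding this value are attributed to in-place body swirls rather than
#' horizontal locomotion.
#'
#' @param body_length_mm Larval body length in mm (non-negative).
#' @return The movement threshold in mm.
#' @examples
#' movement_threshold(3.25)  # 2.298097, rounds to 2.3
#' @export
movement_threshold <- function(body_length_mm) {
  if (!is.numeric(body_length_mm) || any(!is.finite(body_length_mm)) ||
      any(body_length_mm < 0)) {
    stop("body_length_mm must be finite and non-negative", call. = FALSE)
  }
  body_length_mm * sin(pi / 4)
}

# Numerical guard for the strict turn-angle comparison: an exactly-45-degree
# geometry must never be promoted to a turn by acos round-off.
ANGLE_TIE_EPS_DEG <- 1e-9

#' Per-interval tracking vectors of a trajectory
#'
#' One displacement vector per consecutive point pair. Vectors shorter than
#' `min_vector_mm` have no numerically meaningful direction and are flagged
#' `direction_defined = FALSE`; they are excluded from turn evaluation.
#'
#' @param traj A `"trajectory"` with at least 2 points.
#' @param cfg A [kinematics_config()].
#' @return Data frame with one row per interval: `dx_mm`, `dy_mm`,
#'   `length_mm`, `dt_s`, `direction_defined`.
#' @export
tracking_vectors <- function(traj, cfg = kinematics_config()) {
  validate_trajectory(traj)
  p <- traj$points
  if (nrow(p) < 2L) {
    stop(sprintf("larva '%s': at least 2 points required for tracking vectors",
                 traj$larva_id), call. = FALSE)
  }
  dx <- diff(p$x_mm)
  dy <- diff(p$y_mm)
  len <- sqrt(dx^2 + dy^2)
  data.frame(
    dx_mm = dx, dy_mm = dy, length_mm = len, dt_s = diff(p$t_s),
    direction_defined = len >= cfg$min_vector_mm
  )
}

# Unsigned intersection angles (degrees) between successive vector pairs;
# NA where either vector's direction is undefined. Clamped before acos for
# numerical safety at collinearity.
pair_angles_deg <- function(vec) {
  n <- nrow(vec)
  if (n < 2L) return(numeric(0))
  i <- seq_len(n - 1L)
  dot <- vec$dx_mm[i] * vec$dx_mm[i + 1L] + vec$dy_mm[i] * vec$dy_mm[i + 1L]
  denom <- vec$length_mm[i] * vec$length_mm[i + 1L]
  cosang <- pmin(1, pmax(-1, dot / denom))
  ang <- acos(cosang) * 180 / pi
  ang[!(vec$direction_defined[i] & vec$direction_defined[i + 1L])] <- NA_real_
  ang
}

#' Count turns in a trajectory
#'
#' A turn is scored whenever the unsigned intersection angle between two
#' successive tracking vectors strictly exceeds the turn threshold (45
#' degrees by default). Pairs involving a direction-undefined vector (length
#' below `min_vector_mm`) are skipped entirely; the angle across such a gap
#' is not evaluated.
#'
#' @param traj A `"trajectory"` with at least 3 points.
#' @param cfg A [kinematics_config()].
#' @return Non-negative integer turn count.
#' @examples
#' tr <- trajectory("L1", 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
#' count_turns(tr)  # one 90-degree turn
#' @export
count_turns <- function(traj, cfg = kinematics_config()) {
  validate_trajectory(traj)
  if (nrow(traj$points) < 3L) {
    stop(sprintf("larva '%s': at least 3 points required to score turns",
                 traj$larva_id), call. = FALSE)
  }
  ang <- pair_angles_deg(tracking_vectors(traj, cfg))
  sum(ang > cfg$turn_threshold_deg + ANGLE_TIE_EPS_DEG, na.rm = TRUE)
}

#' Count movement instances in a trajectory
#'
#' A movement instance is a per-interval head displacement strictly exceeding
#' the movement threshold (~2.3 mm for a 3.25 mm larva). Displacements at or
#' below the threshold are treated as in-place body swirls.
#'
#' @inheritParams count_turns
#' @return Non-negative integer movement count.
#' @export
count_movements <- function(traj, cfg = kinematics_config()) {
  vec <- tracking_vectors(traj, cfg)
  sum(vec$length_mm > cfg$movement_threshold_mm)
}

#' Average velocity over a trajectory
#'
#' Total path length (sum of consecutive displacement lengths) divided by the
#' observed track duration `t_last - t_first`.
#'
#' @param traj A `"trajectory"` with at least 2 points.
#' @return Average velocity in mm/s.
#' @examples
#' average_velocity(trajectory("L1", 0:1, x = c(0, 3), y = c(0, 4)))  # 5
#' @export
average_velocity <- function(traj) {
  validate_trajectory(traj)
  p <- traj$points
  if (nrow(p) < 2L) {
    stop(sprintf("larva '%s': at least 2 points required for velocity",
                 traj$larva_id), call. = FALSE)
  }
  elapsed <- p$t_s[nrow(p)] - p$t_s[1L]
  if (elapsed <= 0) {
    stop(sprintf("larva '%s': zero elapsed time", traj$larva_id),
         call. = FALSE)
  }
  sum(sqrt(diff(p$x_mm)^2 + diff(p$y_mm)^2)) / elapsed
}

#' Resting time of a trajectory
#'
#' The cumulative duration of sampling intervals whose head displacement does
#' not exceed the movement threshold — the binary complement of a movement
#' instance. For uniformly sampled tracks,
#' `resting_time + n_movements * sample_interval_s` equals the observed
#' duration exactly.
#'
#' @inheritParams count_turns
#' @return Resting time in seconds.
#' @export
resting_time <- function(traj, cfg = kinematics_config()) {
  vec <- tracking_vectors(traj, cfg)
  sum(vec$dt_s[vec$length_mm <= cfg$movement_threshold_mm])
}

#' Score one trajectory into the four behavioral metrics
#'
#' Computes turns, movement instances, average velocity (mm/s), and resting
#' time (s) on the same trajectory with the same configuration, giving the
#' complete per-assay behavioral characterization.
#'
#' @param traj A `"trajectory"` with at least 3 points.
#' @param cfg A [kinematics_config()].
#' @return An object of class `"behavior_summary"`: a list with
#'   `larva_id`, `treatment`, `dose`, `injection`, `n_turns`, `n_movements`,
#'   `avg_velocity_mm_s`, `resting_time_s`.
#' @examples
#' cfg <- kinematics_config()
#' tr <- trajectory("L1", 0:3, x = c(0, 3, 6, 6), y = c(0, 0, 0, 3))
#' summarize_trajectory(tr, cfg)
#' @export
summarize_trajectory <- function(traj, cfg = kinematics_config()) {
  validate_trajectory(traj)
  if (nrow(traj$points) < 3L) {
    stop(sprintf("larva '%s': at least 3 points required to summarize",
                 traj$larva_id), call. = FALSE)
  }
  vec <- tracking_vectors(traj, cfg)
  ang <- pair_angles_deg(vec)
  structure(
    list(
      larva_id = traj$larva_id,
      treatment = traj$treatment,
      dose = traj$dose,
      injection = traj$injection,
      n_turns = sum(ang > cfg$turn_threshold_deg + ANGLE_TIE_EPS_DEG,
                    na.rm = TRUE),
      n_movements = sum(vec$length_mm > cfg$movement_threshold_mm),
      avg_velocity_mm_s = sum(vec$length_mm) / sum(vec$dt_s),
      resting_time_s = sum(vec$dt_s[vec$length_mm <= cfg$movement_threshold_mm])
    ),
    class = "behavior_summary"
  )
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    "<behavior_summary> larva '%s': %d turns, %d movements, %.3f mm/s, %.1f s resting\n",
    x$larva_id, x$n_turns, x$n_movements, x$avg_velocity_mm_s,
    x$resting_time_s))
  invisible(x)
}

#' Score a collection of trajectories into a summary table
#'
#' Applies [summarize_trajectory()] to every trajectory. Trajectories with
#' fewer than 3 points cannot be scored and are skipped with a warning naming
#' the larva.
#'
#' @param trajs List of `"trajectory"` objects.
#' @param cfg A [kinematics_config()].
#' @return Data frame with one row per scored larva and columns
#'   `larva_id,treatment,dose,injection,n_turns,n_movements,avg_velocity_mm_s,resting_time_s`.
#' @export
summarize_tracks <- function(trajs, cfg = kinematics_config()) {
  rows <- lapply(trajs, function(tr) {
    if (nrow(tr$points) < 3L) {
      warning(sprintf("skipping larva '%s': fewer than 3 points",
                      tr$larva_id), call. = FALSE)
      return(NULL)
    }
    s <- summarize_trajectory(tr, cfg)
    data.frame(
      larva_id = s$larva_id, treatment = s$treatment, dose = s$dose,
      injection = s$injection, n_turns = s$n_turns,
      n_movements = s$n_movements, avg_velocity_mm_s = s$avg_velocity_mm_s,
      resting_time_s = s$resting_time_s, stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(
      larva_id = character(0), treatment = character(0), dose = numeric(0),
      injection = character(0), n_turns = integer(0),
      n_movements = integer(0), avg_velocity_mm_s = numeric(0),
      resting_time_s = numeric(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
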