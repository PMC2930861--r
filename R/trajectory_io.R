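#' Construct a larval trajectory
#'
#' A trajectory is one larva's time-ordered head positions together with its
#' treatment metadata. Positions are in mm with the arena center at (0, 0);
#' time is in seconds. Any pixel-to-mm calibration happens upstream, before
#' the data reach this package.
#'
#' @param larva_id Opaque larva label (character scalar).
#' @param t Numeric vector of sampling times in seconds; finite, non-negative,
#'   strictly increasing.
#' @param x,y Numeric vectors of head positions in mm; finite, same length as
#'   `t`.
#' @param treatment Group label, e.g. `"control"`, `"DEET"`, `"yeast"`;
#'   `NA` when unknown.
#' @param dose Dose as labeled in the experiment (v/v dilution or mg/ml);
#'   `NA` when not applicable.
#' @param injection One of `"none"`, `"buffer"`, `"nonspecific_sirna"`,
#'   `"target_sirna"`, or `NA`.
#'
#' @return An object of class `"trajectory"`: a list with elements
#'   `larva_id`, `points` (data frame with columns `t_s`, `x_mm`, `y_mm`),
#'   `treatment`, `dose`, `injection`.
#' @examples
#' tr <- trajectory("L1", t = 0:3, x = c(0, 1, 2, 2), y = c(0, 0, 0, 1))
#' n_points(tr)
#' @export
trajectory <- function(larva_id, t, x, y, treatment = NA_character_,
                       dose = NA_real_, injection = NA_character_) {
  larva_id <- as.character(larva_id)
  t <- as.numeric(t)
  x <- as.numeric(x)
  y <- as.numeric(y)
  obj <- structure(
    list(
      larva_id = larva_id,
      points = data.frame(t_s = t, x_mm = x, y_mm = y),
      treatment = as.character(treatment),
      dose = as.numeric(dose),
      injection = as.character(injection)
    ),
    class = "trajectory"
  )
  validate_trajectory(obj)
  obj
}

injection_levels <- c("none", "buffer", "nonspecific_sirna", "target_sirna")

#' Validate a trajectory object
#'
#' Checks the structural invariants: finite non-negative times strictly
#' increasing, finite coordinates, and a recognized injection label.
#'
#' @param traj A `"trajectory"` object.
#' @return `traj`, invisibly; stops with an informative error otherwise.
#' @export
validate_trajectory <- function(traj) {
  if (!inherits(traj, "trajectory")) {
    stop("not a trajectory object", call. = FALSE)
  }
  p <- traj$points
  if (length(traj$larva_id) != 1L || is.na(traj$larva_id) ||
      !nzchar(traj$larva_id)) {
    stop("trajectory must have a non-empty larva_id", call. = FALSE)
  }
  if (nrow(p) < 1L) {
    stop(sprintf("larva '%s': trajectory has no points", traj$larva_id),
         call. = FALSE)
  }
  if (!all(is.finite(p$t_s)) || any(p$t_s < 0)) {
    stop(sprintf("larva '%s': times must be finite and non-negative",
                 traj$larva_id), call. = FALSE)
  }
  if (!all(is.finite(p$x_mm)) || !all(is.finite(p$y_mm))) {
    stop(sprintf("larva '%s': coordinates must be finite", traj$larva_id),
         call. = FALSE)
  }
  if (nrow(p) > 1L && any(diff(p$t_s) <= 0)) {
    stop(sprintf("larva '%s': times must be strictly increasing",
                 traj$larva_id), call. = FALSE)
  }
  if (!is.na(traj$injection) && !traj$injection %in% injection_levels) {
    stop(sprintf("larva '%s': unknown injection label '%s'",
                 traj$larva_id, traj$injection), call. = FALSE)
  }
  invisible(traj)
}

#' @export
print.trajectory <- function(x, ...) {
  dur <- if (nrow(x$points) > 1L) diff(range(x$points$t_s)) else 0
  cat(sprintf(
    "<trajectory> larva '%s': %d points over %.1f s (treatment: %s, dose: %s, injection: %s)\n",
    x$larva_id, nrow(x$points), dur,
    ifelse(is.na(x$treatment), "-", x$treatment),
    ifelse(is.na(x$dose), "-", format(x$dose)),
    ifelse(is.na(x$injection), "-", x$injection)
  ))
  invisible(x)
}

#' Number of points in a trajectory
#'
#' @param traj A `"trajectory"` object.
#' @return Integer point count.
#' @export
n_points <- function(traj) {
  nrow(traj$points)
}

# Internal fast constructor: skips validation (callers guarantee invariants).
new_trajectory <- function(larva_id, t, x, y, treatment, dose, injection) {
  structure(
    list(
      larva_id = larva_id,
      points = data.frame(t_s = t, x_mm = x, y_mm = y),
      treatment = treatment, dose = dose, injection = injection
    ),
    class = "trajectory"
  )
}

canonical_columns <- c("larva_id", "t_s", "x_mm", "y_mm",
                       "treatment", "dose", "injection")

#' Read tracked larval trajectories from a CSV file
#'
#' Two dialects are supported. `"canonical_csv"` is this package's format,
#' with header `larva_id,t_s,x_mm,y_mm,treatment,dose,injection` (metadata
#' columns optional). `"points_export"` is a permissive convenience dialect
#' for bare tracker point exports with columns `frame,id,x,y`; frame numbers
#' are converted to seconds via `sample_interval_s` and no metadata is
#' attached.
#'
#' Rows with non-finite time or coordinates are dropped with a warning that
#' names the offending file lines. Duplicate timestamps within one larva are
#' a validation error naming that larva. Points are sorted by time within
#' each larva; no other reordering occurs.
#'
#' @param path Path to the CSV file.
#' @param dialect `"canonical_csv"` (default) or `"points_export"`.
#' @param sample_interval_s Seconds per frame, used only by the
#'   `"points_export"` dialect. Default 1.
#' @return A named list of `"trajectory"` objects (possibly empty), named by
#'   larva id, in first-appearance order.
#' @seealso [write_tracks()]
#' @export
read_tracks <- function(path, dialect = c("canonical_csv", "points_export"),
                        sample_interval_s = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("track file not found: '%s'", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (dialect == "points_export") {
    needed <- c("frame", "id", "x", "y")
    missing <- setdiff(needed, names(raw))
    if (length(missing)) {
      stop(sprintf("format error: missing mandatory column(s) %s in '%s'",
                   paste(sQuote(missing), collapse = ", "), path),
           call. = FALSE)
    }
    raw <- data.frame(
      larva_id = raw$id,
      t_s = as.character(suppressWarnings(as.numeric(raw$frame)) *
                           sample_interval_s),
      x_mm = raw$x, y_mm = raw$y,
      treatment = NA_character_, dose = NA_character_,
      injection = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    needed <- c("larva_id", "t_s", "x_mm", "y_mm")
    missing <- setdiff(needed, names(raw))
    if (length(missing)) {
      stop(sprintf("format error: missing mandatory column(s) %s in '%s'",
                   paste(sQuote(missing), collapse = ", "), path),
           call. = FALSE)
    }
    for (col in c("treatment", "dose", "injection")) {
      if (is.null(raw[[col]])) raw[[col]] <- NA_character_
    }
  }

  if (nrow(raw) == 0L) {
    warning(sprintf("'%s' contains a header but no data rows", path),
            call. = FALSE)
    return(structure(list(), names = character(0)))
  }

  t_s <- suppressWarnings(as.numeric(raw$t_s))
  x_mm <- suppressWarnings(as.numeric(raw$x_mm))
  y_mm <- suppressWarnings(as.numeric(raw$y_mm))
  bad <- !is.finite(t_s) | !is.finite(x_mm) | !is.finite(y_mm) |
    is.na(raw$larva_id) | !nzchar(raw$larva_id)
  if (any(bad)) {
    # +1 for the header line: data row i sits on file line i + 1
    warning(sprintf("dropping %d malformed row(s) in '%s' (file line%s %s)",
                    sum(bad), path, if (sum(bad) > 1L) "s" else "",
                    paste(which(bad) + 1L, collapse = ", ")),
            call. = FALSE)
    keep <- !bad
    raw <- raw[keep, , drop = FALSE]
    t_s <- t_s[keep]; x_mm <- x_mm[keep]; y_mm <- y_mm[keep]
    if (nrow(raw) == 0L) return(structure(list(), names = character(0)))
  }

  ids <- unique(raw$larva_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    sel <- raw$larva_id == id
    ti <- t_s[sel]
    if (anyDuplicated(ti)) {
      stop(sprintf("validation error: larva '%s' has duplicate timestamps",
                   id), call. = FALSE)
    }
    ord <- order(ti)
    meta <- raw[sel, , drop = FALSE][1L, ]
    dose <- suppressWarnings(as.numeric(meta$dose))
    tr <- new_trajectory(
      larva_id = id,
      t = ti[ord], x = x_mm[sel][ord], y = y_mm[sel][ord],
      treatment = if (is.na(meta$treatment) || !nzchar(meta$treatment))
        NA_character_ else meta$treatment,
      dose = dose,
      injection = if (is.na(meta$injection) || !nzchar(meta$injection))
        NA_character_ else meta$injection
    )
    validate_trajectory(tr)
    out[[id]] <- tr
  }
  out
}

# Full-precision decimal rendering so that write -> read round-trips doubles
# exactly; NA becomes the empty field.
fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else sprintf("%.17g", z)
  }, character(1))
  out
}

#' Write trajectories to the canonical CSV format
#'
#' Emits the header `larva_id,t_s,x_mm,y_mm,treatment,dose,injection`.
#' Numeric fields are written at full double precision so that
#' `read_tracks(write_tracks(x))` reproduces every stored value exactly;
#' `NA` metadata becomes an empty field and round-trips back to `NA`.
#'
#' @param trajs A list of `"trajectory"` objects (may be empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tracks()]
#' @export
write_tracks <- function(trajs, path) {
  stopifnot(is.list(trajs))
  rows <- lapply(trajs, function(tr) {
    validate_trajectory(tr)
    n <- nrow(tr$points)
    data.frame(
      larva_id = rep(tr$larva_id, n),
      t_s = fmt_num(tr$points$t_s),
      x_mm = fmt_num(tr$points$x_mm),
      y_mm = fmt_num(tr$points$y_mm),
      treatment = rep(ifelse(is.na(tr$treatment), "", tr$treatment), n),
      dose = rep(if (is.na(tr$dose)) "" else sprintf("%.17g", tr$dose), n),
      injection = rep(ifelse(is.na(tr$injection), "", tr$injection), n),
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      as.data.frame(matrix(character(0), ncol = 7)), canonical_columns)
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write tracks to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Write a per-larva behavior summary table to CSV
#'
#' @param summary_df Data frame as returned by [summarize_tracks()], with
#'   columns `larva_id,treatment,dose,injection,n_turns,n_movements,avg_velocity_mm_s,resting_time_s`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary_df, path) {
  utils::write.csv(summary_df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-larva behavior summary table from CSV
#'
#' @param path Path to a CSV written by [write_summary()].
#' @return Data frame with one row per larva.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("summary file not found: '%s'", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
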