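#' Behavioral kernel parameters for the trajectory simulator
#'
#' The simulator is a two-state (rest/move) correlated random walk at the
#' sampling resolution of the assay. Each 1-s step the larva is moving with
#' probability `p_move` (otherwise it rests in place); while moving, the step
#' length is gamma-distributed with the stated mean and coefficient of
#' variation, and the heading either takes a large deflection (strictly above
#' the 45-degree scoring threshold, random sign) with probability
#' `p_big_turn`, or small uniform wobble otherwise. Large deflections are
#' therefore scoreable turns by construction, and wobble never is.
#'
#' Defaults are tuned so control tracks produce non-degenerate movement
#' counts around the ~2.3 mm scoring threshold on a desk-scale run; they are
#' simulator defaults, not claims about real larvae.
#'
#' @param p_move Probability per step of being in the moving state (default
#'   0.6).
#' @param step_mean_mm Mean step length while moving, mm (default 2.0).
#' @param step_cv Coefficient of variation of step length (default 0.6;
#'   0 gives deterministic steps).
#' @param p_big_turn Probability per moving step of a heading deflection
#'   greater than 45 degrees (default 0.15).
#' @param wobble_deg Half-width of the small uniform heading noise, degrees;
#'   must stay strictly below 45 (default 20).
#' @return An object of class `"behavior_params"`.
#' @export
behavior_params <- function(p_move = 0.6, step_mean_mm = 2.0, step_cv = 0.6,
                            p_big_turn = 0.15, wobble_deg = 20) {
  stopifnot(
    is.numeric(p_move), p_move >= 0, p_move <= 1,
    is.numeric(step_mean_mm), step_mean_mm > 0,
    is.numeric(step_cv), step_cv >= 0,
    is.numeric(p_big_turn), p_big_turn >= 0, p_big_turn <= 1,
    is.numeric(wobble_deg), wobble_deg >= 0, wobble_deg < 45
  )
  structure(
    list(p_move = p_move, step_mean_mm = step_mean_mm, step_cv = step_cv,
         p_big_turn = p_big_turn, wobble_deg = wobble_deg),
    class = "behavior_params"
  )
}

#' Circular assay arena
#'
#' The 10-cm dish geometry: odorant source and larva release point sit on the
#' rim at diametrically opposite ends.
#'
#' @param diameter_mm Arena diameter in mm (default 100).
#' @param odor_xy Odorant position, length-2 numeric on the rim; default
#'   `(diameter/2, 0)`.
#' @param release_xy Larva release point on the rim, diametrically opposite
#'   the odorant; default `(-diameter/2, 0)`.
#' @return An object of class `"arena_spec"`.
#' @export
arena_spec <- function(diameter_mm = 100,
                       odor_xy = c(diameter_mm / 2, 0),
                       release_xy = -odor_xy) {
  stopifnot(is.numeric(diameter_mm), diameter_mm > 0,
            length(odor_xy) == 2L, length(release_xy) == 2L)
  r <- diameter_mm / 2
  tol <- 1e-6 * diameter_mm
  if (abs(sqrt(sum(odor_xy^2)) - r) > tol ||
      abs(sqrt(sum(release_xy^2)) - r) > tol) {
    stop("odor_xy and release_xy must lie on the arena rim", call. = FALSE)
  }
  if (abs(sqrt(sum((odor_xy - release_xy)^2)) - diameter_mm) > tol) {
    stop("odor_xy and release_xy must be diametrically opposite",
         call. = FALSE)
  }
  structure(
    list(diameter_mm = diameter_mm, odor_xy = as.numeric(odor_xy),
         release_xy = as.numeric(release_xy)),
    class = "arena_spec"
  )
}

#' Treatment effect on the behavioral kernel
#'
#' Encodes odorant class, dose, and RNAi-knockdown attenuation. The realized
#' modulation is `m = strength * log10(dose / dose_ref) * knockdown`, clamped
#' at 0 (doses at or below the reference behave as neutral). Repellent mode
#' scales turn propensity, movement propensity, and step length up by
#' `(1 + m)`; attractant mode scales them down by the same factor — matching
#' the directionality observed with repellents (more turns, movements,
#' velocity; less resting: direct klino-/orthokinesis) and attractants (the
#' reverse). `knockdown = 0` (fully silenced receptor) abolishes the response
#' entirely.
#'
#' @param mode `"neutral"`, `"attractant"`, or `"repellent"`.
#' @param dose Positive dose in the units of the experiment's labels.
#' @param dose_ref Positive reference dose at which the effect vanishes
#'   (default 1).
#' @param strength Non-negative modulation per unit log10 dose (default 0.5).
#' @param knockdown Signaling integrity between 0 and 1: 1 = intact,
#'   0 = fully silenced (default 1).
#' @return An object of class `"treatment_effect"`.
#' @export
treatment_effect <- function(mode = c("neutral", "attractant", "repellent"),
                             dose = 1, dose_ref = 1, strength = 0.5,
                             knockdown = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(dose), dose > 0, is.numeric(dose_ref), dose_ref > 0,
            is.numeric(strength), strength >= 0,
            is.numeric(knockdown), knockdown >= 0, knockdown <= 1)
  structure(
    list(mode = mode, dose = dose, dose_ref = dose_ref,
         strength = strength, knockdown = knockdown),
    class = "treatment_effect"
  )
}

P_CAP <- 0.99

#' Apply a treatment effect to baseline behavioral parameters
#'
#' @param baseline A [behavior_params()].
#' @param eff A [treatment_effect()].
#' @return A modulated `"behavior_params"`; the baseline itself when the
#'   realized modulation is zero (neutral mode, dose at/below reference, or
#'   full knockdown).
#' @examples
#' base <- behavior_params()
#' # repellent at 100x the reference dose with strength 0.5: multipliers x2
#' effective_params(base, treatment_effect("repellent", dose = 100,
#'                                         dose_ref = 1, strength = 0.5))
#' @export
effective_params <- function(baseline, eff) {
  stopifnot(inherits(baseline, "behavior_params"),
            inherits(eff, "treatment_effect"))
  m <- max(0, eff$strength * log10(eff$dose / eff$dose_ref)) * eff$knockdown
  if (eff$mode == "neutral" || m == 0) {
    return(baseline)
  }
  f <- 1 + m
  if (eff$mode == "repellent") {
    behavior_params(
      p_move = min(P_CAP, baseline$p_move * f),
      step_mean_mm = baseline$step_mean_mm * f,
      step_cv = baseline$step_cv,
      p_big_turn = min(P_CAP, baseline$p_big_turn * f),
      wobble_deg = baseline$wobble_deg
    )
  } else {
    behavior_params(
      p_move = baseline$p_move / f,
      step_mean_mm = baseline$step_mean_mm / f,
      step_cv = baseline$step_cv,
      p_big_turn = baseline$p_big_turn / f,
      wobble_deg = baseline$wobble_deg
    )
  }
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed from (design seed, group label, larva index);
# djb2-style string hash folded into [1, 2^31 - 2]. Doubles carry the
# arithmetic exactly (all intermediates < 2^53).
child_seed <- function(seed, label, index) {
  h <- 5381
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  s <- (as.numeric(seed) %% 2147483647) * 69069 + h * 97 + index * 101
  as.integer(s %% 2147483646) + 1L
}

#' Simulate one larval trajectory
#'
#' Two-state correlated random walk in a circular arena (see
#' [behavior_params()] for the kernel). The larva starts at the release
#' point; proposed positions falling outside the arena are reflected
#' radially back inside, and the heading is then realigned to the realized
#' displacement. The latent state sequence is returned alongside the
#' trajectory for ground-truth testing.
#'
#' @param params A [behavior_params()].
#' @param arena An [arena_spec()].
#' @param duration_s Assay duration in seconds (default 300); must be a
#'   multiple of `sample_interval_s`.
#' @param sample_interval_s Sampling interval in seconds (default 1).
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param start_xy Starting position, length-2 numeric inside the arena;
#'   defaults to the arena's release point on the rim.
#' @param larva_id,treatment,dose,injection Metadata attached to the
#'   trajectory.
#' @return List with `trajectory` (a `"trajectory"`) and `states`, a data
#'   frame with one row per step: `t_s` (time at the end of the step),
#'   `state` (`"rest"` or `"move"`), `latent_turn` (whether a large heading
#'   deflection was applied on this step), `step_mm` (the drawn step length;
#'   0 at rest).
#' @examples
#' sim <- simulate_trajectory(behavior_params(), seed = 1)
#' summarize_trajectory(sim$trajectory)
#' @export
simulate_trajectory <- function(params, arena = arena_spec(),
                                duration_s = 300, sample_interval_s = 1,
                                seed = NULL, start_xy = arena$release_xy,
                                larva_id = "larva1",
                                treatment = NA_character_, dose = NA_real_,
                                injection = NA_character_) {
  stopifnot(inherits(params, "behavior_params"), inherits(arena, "arena_spec"),
            duration_s > 0, sample_interval_s > 0,
            length(start_xy) == 2L,
            sum(start_xy^2) <= (arena$diameter_mm / 2)^2 * (1 + 1e-9))
  n_steps <- round(duration_s / sample_interval_s)
  if (abs(n_steps * sample_interval_s - duration_s) > 1e-9) {
    stop("duration_s must be a multiple of sample_interval_s", call. = FALSE)
  }
  with_seed(seed, {
    R <- arena$diameter_mm / 2
    moving <- stats::runif(n_steps) < params$p_move
    if (params$step_cv > 0) {
      shape <- 1 / params$step_cv^2
      lens <- stats::rgamma(n_steps, shape = shape,
                            scale = params$step_mean_mm / shape)
    } else {
      lens <- rep(params$step_mean_mm, n_steps)
    }
    big <- moving & (stats::runif(n_steps) < params$p_big_turn)
    # big deflections: uniform magnitude in (45, 180] deg, random sign;
    # otherwise wobble, uniform in +/- wobble_deg
    defl <- stats::runif(n_steps, -params$wobble_deg, params$wobble_deg)
    nbig <- sum(big)
    if (nbig) {
      defl[big] <- sample(c(-1, 1), nbig, replace = TRUE) *
        stats::runif(nbig, 45 + 1e-6, 180)
    }
    defl <- defl * pi / 180

    x <- numeric(n_steps + 1L)
    y <- numeric(n_steps + 1L)
    x[1L] <- start_xy[1L]
    y[1L] <- start_xy[2L]
    # initial heading: toward the arena center, so a rim start leads inward
    heading <- atan2(-y[1L], -x[1L])
    for (i in seq_len(n_steps)) {
      if (moving[i]) {
        heading <- heading + defl[i]
        xi <- x[i] + lens[i] * cos(heading)
        yi <- y[i] + lens[i] * sin(heading)
        r <- sqrt(xi^2 + yi^2)
        if (r > R) {
          # radial fold at the wall; clamp pathological overshoots
          fold <- max(0, (2 * R - r)) / r
          xi <- xi * fold
          yi <- yi * fold
          heading <- atan2(yi - y[i], xi - x[i])
        }
        x[i + 1L] <- xi
        y[i + 1L] <- yi
      } else {
        x[i + 1L] <- x[i]
        y[i + 1L] <- y[i]
      }
    }
    traj <- new_trajectory(
      larva_id = larva_id,
      t = seq(0, by = sample_interval_s, length.out = n_steps + 1L),
      x = x, y = y,
      treatment = treatment, dose = dose, injection = injection
    )
    states <- data.frame(
      t_s = seq(sample_interval_s, by = sample_interval_s,
                length.out = n_steps),
      state = ifelse(moving, "move", "rest"),
      latent_turn = big,
      step_mm = ifelse(moving, lens, 0),
      stringsAsFactors = FALSE
    )
    list(trajectory = traj, states = states)
  })
}

#' Build a simulation design
#'
#' @param baseline A [behavior_params()] shared by all groups.
#' @param groups List of group specs, each a list with `label` (unique
#'   character), `effect` (a [treatment_effect()]), and `n_larvae`
#'   (>= 1).
#' @param arena An [arena_spec()].
#' @param duration_s,sample_interval_s Assay timing (defaults 300 s at 1 Hz).
#' @param seed Integer master seed; per-larva seeds are derived
#'   deterministically from it, the group label, and the larva index, so
#'   results are independent of iteration order.
#' @return An object of class `"simulation_design"`.
#' @export
simulation_design <- function(baseline = behavior_params(), groups,
                              arena = arena_spec(), duration_s = 300,
                              sample_interval_s = 1, seed = 1L) {
  stopifnot(inherits(baseline, "behavior_params"),
            inherits(arena, "arena_spec"),
            is.list(groups), length(groups) >= 1L)
  labels <- vapply(groups, function(g) as.character(g$label), character(1))
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate group label(s): %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  }
  for (g in groups) {
    stopifnot(inherits(g$effect, "treatment_effect"),
              is.numeric(g$n_larvae), g$n_larvae >= 1)
  }
  n_steps <- round(duration_s / sample_interval_s)
  if (abs(n_steps * sample_interval_s - duration_s) > 1e-9) {
    stop("duration_s must be a multiple of sample_interval_s", call. = FALSE)
  }
  structure(
    list(baseline = baseline, groups = groups, arena = arena,
         duration_s = duration_s, sample_interval_s = sample_interval_s,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Simulate a full multi-group experiment
#'
#' Generates `n_larvae` trajectories per group with the group's effective
#' kernel parameters, labeled with the group metadata. Larva ids are
#' `<label>_<index>`. Child seeds derive from the design seed, group label,
#' and larva index, making the output reproducible and independent of
#' iteration order.
#'
#' @param design A [simulation_design()].
#' @return List with `trajectories` (named list of `"trajectory"`) and
#'   `truth`, a long data frame of latent states
#'   (`larva_id,t_s,state,latent_turn,step_mm`).
#' @examples
#' des <- simulation_design(groups = list(
#'   list(label = "control", effect = treatment_effect("neutral"),
#'        n_larvae = 2)
#' ), duration_s = 30, seed = 7)
#' sim <- simulate_experiment(des)
#' names(sim$trajectories)
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  trajs <- list()
  truth <- list()
  for (g in design$groups) {
    pars <- effective_params(design$baseline, g$effect)
    lab <- as.character(g$label)
    inj <- if (!is.null(g$injection)) as.character(g$injection)
           else NA_character_
    for (i in seq_len(g$n_larvae)) {
      id <- sprintf("%s_%02d", lab, i)
      sim <- simulate_trajectory(
        pars, arena = design$arena, duration_s = design$duration_s,
        sample_interval_s = design$sample_interval_s,
        seed = child_seed(design$seed, lab, i),
        larva_id = id, treatment = lab,
        dose = if (g$effect$mode == "neutral") NA_real_ else g$effect$dose,
        injection = inj
      )
      trajs[[id]] <- sim$trajectory
      st <- sim$states
      st$larva_id <- id
      truth[[id]] <- st[, c("larva_id", "t_s", "state", "latent_turn",
                            "step_mm")]
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(trajectories = trajs, truth = truth)
}

#' Probability that a simulated step scores as a movement instance
#'
#' Closed form for the per-interval movement probability of the simulator:
#' the step must be in the moving state and its gamma-distributed length
#' must exceed the movement threshold, i.e.
#' `p_move * P(Gamma(mean, cv) > threshold)` via the gamma survival
#' function. Used for kernel-identity checks against scored simulator
#' output.
#'
#' @param params A [behavior_params()].
#' @param threshold_mm Movement threshold in mm.
#' @return Probability between 0 and 1.
#' @export
expected_movement_fraction <- function(params, threshold_mm) {
  stopifnot(inherits(params, "behavior_params"), threshold_mm >= 0)
  if (params$step_cv > 0) {
    shape <- 1 / params$step_cv^2
    surv <- stats::pgamma(threshold_mm, shape = shape,
                          scale = params$step_mean_mm / shape,
                          lower.tail = FALSE)
  } else {
    surv <- as.numeric(params$step_mean_mm > threshold_mm)
  }
  params$p_move * surv
}
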