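# Independent brute-force scorer: plain point-by-point loop, angles from
# atan2(|cross|, dot) rather than acos of the normalized dot product. Kept
# deliberately naive so it cannot share bugs with the vectorized scorers.
oracle_score <- function(traj, cfg = kinematics_config()) {
  p <- traj$points
  n <- nrow(p)
  turns <- 0L
  movements <- 0L
  path <- 0
  rest <- 0
  pdx <- NA_real_
  pdy <- NA_real_
  prev_defined <- FALSE
  for (i in 2:n) {
    dx <- p$x_mm[i] - p$x_mm[i - 1L]
    dy <- p$y_mm[i] - p$y_mm[i - 1L]
    dt <- p$t_s[i] - p$t_s[i - 1L]
    len <- sqrt(dx^2 + dy^2)
    path <- path + len
    if (len > cfg$movement_threshold_mm) {
      movements <- movements + 1L
    } else {
      rest <- rest + dt
    }
    defined <- len >= cfg$min_vector_mm
    if (i > 2L && defined && prev_defined) {
      cross <- pdx * dy - pdy * dx
      dot <- pdx * dx + pdy * dy
      ang_deg <- atan2(abs(cross), dot) * 180 / pi
      if (ang_deg > cfg$turn_threshold_deg + 1e-9) turns <- turns + 1L
    }
    pdx <- dx
    pdy <- dy
    prev_defined <- defined
  }
  list(
    n_turns = turns,
    n_movements = movements,
    avg_velocity_mm_s = path / (p$t_s[n] - p$t_s[1L]),
    resting_time_s = rest
  )
}

# Random piecewise trajectory exercising rests, sub-min_vector jitter, and
# free steps; independent of the package's simulator.
random_trajectory <- function(n_steps = 300, id = "rnd") {
  u <- stats::runif(n_steps)
  len <- ifelse(u < 0.3, 0,
                ifelse(u < 0.45, stats::runif(n_steps, 0, 0.15),
                       stats::runif(n_steps, 0, 5)))
  theta <- stats::runif(n_steps, 0, 2 * pi)
  trajectory(id,
             t = 0:n_steps,
             x = cumsum(c(0, len * cos(theta))),
             y = cumsum(c(0, len * sin(theta))))
}

# Textbook sums-of-squares one-way ANOVA decomposition.
anova_oracle <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  n_tot <- length(values)
  grand <- mean(values)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n_tot - k))
  list(F = f, df_between = k - 1L, df_within = n_tot - k,
       p_value = stats::pf(f, k - 1, n_tot - k, lower.tail = FALSE))
}

# Simulate one group with the package API and score it; used by the
# replicate-based statistical checks.
simulated_group_metric <- function(params, n_larvae, metric, seed_base,
                                   arena = arena_spec(), duration_s = 300) {
  vapply(seq_len(n_larvae), function(i) {
    sim <- simulate_trajectory(params, arena = arena,
                               duration_s = duration_s,
                               seed = seed_base + i)
    summarize_trajectory(sim$trajectory)[[metric]]
  }, numeric(1))
}

# Per-larva summary data frame for a control-vs-treatment style replicate.
simulated_summary_df <- function(group_params, n_larvae, seed_base,
                                 duration_s = 300) {
  rows <- list()
  g_idx <- 0L
  for (lab in names(group_params)) {
    g_idx <- g_idx + 1L
    for (i in seq_len(n_larvae)) {
      sim <- simulate_trajectory(group_params[[lab]],
                                 duration_s = duration_s,
                                 seed = seed_base + g_idx * 1000L + i,
                                 larva_id = sprintf("%s_%d", lab, i),
                                 treatment = lab)
      s <- summarize_trajectory(sim$trajectory)
      rows[[length(rows) + 1L]] <- data.frame(
        larva_id = s$larva_id, treatment = lab, n_turns = s$n_turns,
        n_movements = s$n_movements,
        avg_velocity_mm_s = s$avg_velocity_mm_s,
        resting_time_s = s$resting_time_s, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
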