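#' Measure epidermal thickness
#'
#' Partitions the lateral box into columns (default pitch one cell diameter),
#' takes per column the top of the highest cell (\code{z + R}) minus the
#' local membrane surface (mean particle \code{z + Rm} in that column), and
#' averages over columns containing cells. The measure is membrane-relative:
#' a cell stack that rigidly follows the undulation yields the same thickness
#' as the flat-membrane stack. A single resting cell layer on a flat membrane
#' measures exactly \code{2R}: top \code{(R + Rm) + R} minus surface
#' \code{Rm}.
#'
#' @param state an \code{ifesim_tissue} (at least one cell).
#' @param params an \code{ifesim_params}.
#' @param pitch lateral column pitch (defaults to the cell diameter).
#' @return mean thickness (length units).
#' @export
measure_thickness <- function(state, params, pitch = 2 * params$R) {
  if (length(state$id) == 0)
    stop("thickness undefined: no cells in the state", call. = FALSE)
  out <- cpp_thickness(state_to_cpp(state), membrane_to_cpp(state$membrane),
                       params_to_cpp(params), pitch)
  out$mean
}

#' Run the adhesion-perturbation protocol
#'
#' For each seed: burn in to homeostasis, then fork the state into two arms
#' sharing the post-switch random substream (the saved RNG state), so the
#' arms differ only by the progenitor adhesion strength: the control arm
#' keeps \code{Kd} at its homeostatic value, the perturbed arm switches
#' \code{Kd} to \code{Kd_perturbed} at the fork. Each arm records a
#' thickness series whose ratio is normalized to 1 at the switch.
#'
#' @param params an \code{ifesim_params} (the control \code{Kd}).
#' @param mspec an \code{ifesim_membrane_spec}; each run perturbs the
#'   undulation phase so ensemble members have different membrane shapes.
#' @param seeds integer vector of run seeds.
#' @param burn_days burn-in horizon per run (days).
#' @param post_days post-switch horizon (days).
#' @param Kd_perturbed the weakened adhesion strength.
#' @param record_every_days sampling interval for the series.
#' @param stem_fraction passed to \code{\link{seed_initial_cells}}.
#' @return a list of per-run lists with elements \code{control} and
#'   \code{perturbed}, each an \code{ifesim_series} data frame
#'   (time_days, thickness, ratio, arm, seed), plus the final states.
#' @export
run_protocol <- function(params, mspec = membrane_spec(), seeds = 1:5,
                         burn_days = 50, post_days = 30, Kd_perturbed = 2.0,
                         record_every_days = 0.25, stem_fraction = 0.2) {
  stopifnot(length(seeds) >= 1, post_days > 0)
  lapply(seeds, function(seed) {
    ms <- mspec
    ms$phase <- (seed %% 7) * ms$wavelength / 7  # vary membrane shape
    st0 <- burn_in(params, ms, days = burn_days, seed = seed,
                   stem_fraction = stem_fraction)
    st0$record <- NULL
    st0$events <- empty_events()
    rng <- .Random.seed
    arm <- function(p, label) {
      .Random.seed <<- rng
      st <- run_sim(st0, p, days = post_days,
                    record_every_days = record_every_days)
      list(series = thickness_series(st, p, label, seed), state = st)
    }
    ctl <- arm(params, "control")
    prm <- params
    prm$Kd <- Kd_perturbed
    per <- arm(prm, "perturbed")
    list(seed = seed, control = ctl$series, perturbed = per$series,
         control_state = ctl$state, perturbed_state = per$state)
  })
}

#' Thickness series of a recorded run
#'
#' @param state an \code{ifesim_tissue} with a recorded series.
#' @param params an \code{ifesim_params}.
#' @param arm label (\code{"control"} or \code{"perturbed"}).
#' @param seed the run seed (metadata).
#' @return a data frame of class \code{ifesim_series}: time_days (from the
#'   start of the recording), thickness, ratio (thickness over its value at
#'   the start, exactly 1 at the first sample), arm, seed.
#' @export
thickness_series <- function(state, params, arm = "control", seed = NA) {
  rec <- state$record
  stopifnot(!is.null(rec), nrow(rec) >= 1)
  t0 <- rec[1, "time"]
  d <- data.frame(time_days = to_days(rec[, "time"] - t0, params),
                  thickness = rec[, "thickness"],
                  ratio = rec[, "thickness"] / rec[1, "thickness"],
                  arm = arm, seed = seed)
  class(d) <- c("ifesim_series", class(d))
  d
}

#' Ensemble average of thickness-ratio series
#'
#' Pointwise mean and standard error of the ratio across runs of one arm.
#'
#' @param series a list of \code{ifesim_series} sharing arm and time grid.
#' @return a data frame (time_days, mean_ratio, se_ratio, n_runs, arm); the
#'   standard error is NA for a single run.
#' @export
ensemble_average <- function(series) {
  stopifnot(length(series) >= 1)
  arms <- vapply(series, function(s) as.character(s$arm[1]), "")
  if (length(unique(arms)) != 1)
    stop("cannot average across arms: ", paste(unique(arms), collapse = ", "),
         call. = FALSE)
  tg <- series[[1]]$time_days
  for (s in series)
    if (!isTRUE(all.equal(s$time_days, tg)))
      stop("ensemble members do not share a time grid", call. = FALSE)
  m <- sapply(series, function(s) s$ratio)
  m <- matrix(m, nrow = length(tg))
  n <- ncol(m)
  data.frame(time_days = tg,
             mean_ratio = rowMeans(m),
             se_ratio = if (n >= 2) apply(m, 1, stats::sd) / sqrt(n)
                        else NA_real_,
             n_runs = n,
             arm = arms[1])
}

#' Transient-response metrics of an ensemble summary
#'
#' Peak thickness ratio after the switch, its timing, the final ratio, and
#' the recovery fraction \code{(peak - final) / (peak - 1)} (how much of the
#' transient excess has decayed by the end; defined only when the ratio
#' actually rose above 1).
#'
#' @param summary an ensemble summary from \code{\link{ensemble_average}}.
#' @return a list: peak_ratio, time_to_peak_days, final_ratio,
#'   recovery_fraction (NA when peak_ratio <= 1).
#' @export
transient_metrics <- function(summary) {
  i <- which.max(summary$mean_ratio)
  peak <- summary$mean_ratio[i]
  fin <- summary$mean_ratio[nrow(summary)]
  rec <- if (peak > 1) (peak - fin) / (peak - 1) else NA_real_
  list(peak_ratio = peak,
       time_to_peak_days = summary$time_days[i],
       final_ratio = fin,
       recovery_fraction = rec)
}

#' Division-axis statistics
#'
#' Classifies completed basal divisions by the angle between the realized
#' division axis and the local basement-membrane plane (fitted through the
#' three membrane particles nearest the division site): angles at or above
#' the threshold count as asymmetric (perpendicular) divisions, the rest as
#' symmetric (parallel). Percentages sum to exactly 100.
#'
#' @param events an event-log data frame (see \code{\link{event_log}}) or an
#'   \code{ifesim_tissue}.
#' @param membrane an \code{ifesim_membrane}.
#' @param angle_threshold_deg dichotomization threshold in degrees (0, 90).
#' @param kinds parent kinds to include (defaults to basal divisions).
#' @return a list: percent_ACD, percent_SCD, n_events, angles_deg.
#' @export
division_axis_stats <- function(events, membrane, angle_threshold_deg = 45,
                                kinds = c("stem", "daughter")) {
  stopifnot(angle_threshold_deg > 0, angle_threshold_deg < 90)
  if (inherits(events, "ifesim_tissue")) events <- event_log(events)
  kcode <- match(kinds, KIND_LEVELS)
  e <- events[events$type == "div_complete" & events$kind %in% kcode, ,
              drop = FALSE]
  if (nrow(e) == 0)
    return(list(percent_ACD = NA_real_, percent_SCD = NA_real_,
                n_events = 0L, angles_deg = numeric(0)))
  angles <- vapply(seq_len(nrow(e)), function(r) {
    pt <- c(e$x[r], e$y[r], e$z[r])
    axis <- c(e$v1[r], e$v2[r], e$v3[r])
    n_hat <- local_membrane_normal(pt, membrane)
    asin(min(1, abs(sum(axis * n_hat)) / sqrt(sum(axis^2)))) * 180 / pi
  }, 0.0)
  acd <- 100 * sum(angles >= angle_threshold_deg) / length(angles)
  list(percent_ACD = acd, percent_SCD = 100 - acd,
       n_events = length(angles), angles_deg = angles)
}

# unit normal of the plane through the three membrane particles nearest a
# point (periodic lateral metric); falls back to the next-nearest particle
# when the three are collinear
local_membrane_normal <- function(pt, membrane) {
  dx <- membrane$pos[, 1] - pt[1]
  dy <- membrane$pos[, 2] - pt[2]
  dx <- dx - membrane$Lx * round(dx / membrane$Lx)
  dy <- dy - membrane$Ly * round(dy / membrane$Ly)
  dz <- membrane$pos[, 3] - pt[3]
  ord <- order(dx^2 + dy^2 + dz^2)
  p1 <- c(dx[ord[1]], dy[ord[1]], dz[ord[1]])
  p2 <- c(dx[ord[2]], dy[ord[2]], dz[ord[2]])
  for (k in 3:min(length(ord), 8)) {
    p3 <- c(dx[ord[k]], dy[ord[k]], dz[ord[k]])
    n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
           (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
           (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 1e-9) {
      n <- n / nn
      if (n[3] < 0) n <- -n
      return(n)
    }
  }
  c(0, 0, 1)
}

#' Write a thickness series or ensemble summary as CSV
#'
#' @param x a data frame (series or summary).
#' @param path file path.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
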