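#' Update calcium levels
#'
#' A suprabasal cell in contact with at least one cornified cell is excited
#' to the calcium level \code{c_exc}, reflecting the high calcium observed
#' beneath the stratum corneum; otherwise its calcium decays exponentially at
#' rate \code{k_ca}. Basal and cornified cells hold calcium at zero. This is
#' the package's minimal excite-and-decay surrogate for the upstream calcium
#' dynamics; it implements exactly the contact-triggered excitation the model
#' requires, nothing more.
#'
#' @param state an \code{ifesim_tissue}.
#' @param params an \code{ifesim_params}.
#' @param dt time increment.
#' @return the updated state.
#' @export
update_calcium <- function(state, params, dt = params$dt) {
  touch <- cpp_contact_cornified(state_to_cpp(state), params_to_cpp(params))
  sup <- state$kind == KIND_SUPRABASAL
  state$calcium[sup & touch] <- params$c_exc
  idx <- sup & !touch
  state$calcium[idx] <- state$calcium[idx] * exp(-params$k_ca * dt)
  state$calcium[!sup] <- 0
  state
}

#' Advance the differentiation degree
#'
#' Each suprabasal cell's differentiation degree grows as
#' \code{dS/dt = s_base * (1 + lam_ca * calcium)}: a baseline clock
#' accelerated by calcium. S is non-decreasing; basal cells hold S = 0.
#'
#' @inheritParams update_calcium
#' @return the updated state.
#' @export
update_differentiation <- function(state, params, dt = params$dt) {
  sup <- state$kind == KIND_SUPRABASAL
  state$S[sup] <- state$S[sup] +
    dt * params$s_base * (1 + params$lam_ca * state$calcium[sup])
  state
}

#' Cornify threshold-reaching suprabasal cells
#'
#' Every suprabasal cell with \code{S >= S_star} (threshold inclusive)
#' terminally differentiates into a cornified cell: mechanically ordinary,
#' no anchoring, no division, calcium pinned at zero. Logged as a
#' cornification event.
#'
#' @inheritParams update_calcium
#' @return the updated state.
#' @export
cornify <- function(state, params) {
  idx <- which(state$kind == KIND_SUPRABASAL & state$S >= params$S_star)
  for (i in idx) {
    state$kind[i] <- KIND_CORNIFIED
    state$calcium[i] <- 0
    state <- append_event(state, EV_CORNIFY, state$id[i], kind = KIND_CORNIFIED,
                          pos = state$pos[i, ], v = c(state$birth[i], 0, 0))
  }
  state
}

#' Desquamate exposed cornified cells
#'
#' A cornified cell is exposed when no other cell's center lies strictly
#' higher within lateral contact range. Each exposed cornified cell is
#' removed with probability \code{1 - exp(-desq_rate * dt)} per step
#' (draws in ascending id order); removals are logged with the cell's birth
#' time, so birth-to-shedding residence times can be read off the event log.
#'
#' @inheritParams update_calcium
#' @return the updated state.
#' @export
desquamate <- function(state, params, dt = params$dt) {
  ex <- cpp_exposed(state_to_cpp(state), params_to_cpp(params))
  idx <- which(ex)
  if (!length(idx)) return(state)
  u <- stats::runif(length(idx))
  gone <- idx[u < 1 - exp(-params$desq_rate * dt)]
  if (!length(gone)) return(state)
  for (i in gone) {
    state <- append_event(state, EV_DESQ, state$id[i], kind = KIND_CORNIFIED,
                          pos = state$pos[i, ], v = c(state$birth[i], 0, 0))
  }
  keep <- setdiff(seq_along(state$id), gone)
  state$id <- state$id[keep]
  state$kind <- state$kind[keep]
  state$pair <- state$pair[keep]
  state$pos <- state$pos[keep, , drop = FALSE]
  state$cycle <- state$cycle[keep]
  state$S <- state$S[keep]
  state$calcium <- state$calcium[keep]
  state$birth <- state$birth[keep]
  state
}

#' Calibrate the turnover time
#'
#' Fixes the day-unit mapping from the division-period identity
#' \code{day_unit = (T_cycle + 1/gamma) / target_division_days} and tunes the
#' baseline differentiation rate \code{s_base} so that the measured mean
#' birth-to-desquamation time at homeostasis matches
#' \code{target_turnover_days}. The desquamation rate is held at its default:
#' it must stay supercritical (surface removal capacity above the division
#' flux) or the cornified stack grows without bound, so the thickness of the
#' viable layer — controlled by \code{s_base} — is the effective knob.
#' Turnover is, to good approximation, affine in \code{1/s_base}, so a
#' secant iteration on \code{1/s_base} converges in very few evaluations.
#' Each evaluation runs a fresh homeostatic simulation and averages the
#' lifetimes of cells born in an early post-burn-in window and shed before
#' the horizon.
#'
#' @param params an \code{ifesim_params} (its \code{s_base} is the starting
#'   guess).
#' @param mspec an \code{ifesim_membrane_spec} for the calibration patch.
#' @param target_division_days target mean inter-division period (days).
#' @param target_turnover_days target mean birth-to-desquamation time (days).
#' @param budget maximum number of simulation evaluations.
#' @param tol relative tolerance on the achieved turnover.
#' @param seed RNG seed for the calibration runs.
#' @param burn_days,measure_days,horizon_days evaluation-run layout: cells
#'   born within \code{measure_days} after \code{burn_days} are tracked until
#'   \code{horizon_days}.
#' @param stem_fraction passed to \code{\link{seed_initial_cells}}.
#' @return a list with the calibrated \code{params}, the \code{achieved}
#'   turnover (days), the number of \code{evaluations}, a \code{converged}
#'   flag and the evaluation \code{trace} (s_base vs measured days).
#' @export
calibrate_turnover <- function(params, mspec = membrane_spec(),
                               target_division_days = 3,
                               target_turnover_days = 28,
                               budget = 4, tol = 0.10, seed = 1,
                               burn_days = 30, measure_days = 12,
                               horizon_days = 85, stem_fraction = 0.2) {
  params$day_unit <- (params$T_cycle + 1 / params$gamma) / target_division_days
  measure <- function(s_base) {
    p <- params
    p$s_base <- s_base
    set.seed(seed)
    mem <- generate_membrane(mspec)
    st <- seed_initial_cells(mem, p, stem_fraction)
    st <- run_sim(st, p, days = horizon_days, record_every_days = 0)
    mean_turnover_days(st, p, born_after_days = burn_days,
                       born_before_days = burn_days + measure_days)
  }
  s1 <- params$s_base
  t1 <- measure(s1)
  trace <- data.frame(s_base = s1, turnover_days = t1)
  n_eval <- 1
  best_s <- s1
  best_t <- t1
  while (n_eval < budget &&
         (!is.finite(best_t) ||
          abs(best_t - target_turnover_days) > tol * target_turnover_days)) {
    # secant step in x = 1/s_base (turnover ~ affine in x)
    if (nrow(trace) == 1 || !all(is.finite(trace$turnover_days))) {
      s_new <- best_s * if (is.finite(best_t) &&
                            best_t > target_turnover_days) 1.5 else 0.67
    } else {
      i2 <- order(abs(trace$turnover_days - target_turnover_days))[1:2]
      x <- 1 / trace$s_base[i2]
      y <- trace$turnover_days[i2]
      if (diff(y) == 0) break
      x_new <- x[1] + (target_turnover_days - y[1]) * diff(x) / diff(y)
      if (!is.finite(x_new) || x_new <= 0) x_new <- x[1] * 1.5
      s_new <- 1 / x_new
    }
    t_new <- measure(s_new)
    trace <- rbind(trace, data.frame(s_base = s_new, turnover_days = t_new))
    n_eval <- n_eval + 1
    if (is.finite(t_new) && (!is.finite(best_t) ||
        abs(t_new - target_turnover_days) < abs(best_t - target_turnover_days))) {
      best_s <- s_new
      best_t <- t_new
    }
  }
  params$s_base <- best_s
  converged <- is.finite(best_t) &&
    abs(best_t - target_turnover_days) <= tol * target_turnover_days
  if (!converged)
    warning("turnover calibration did not converge within budget; achieved ",
            signif(best_t, 4), " days", call. = FALSE)
  list(params = params, achieved = best_t, evaluations = n_eval,
       converged = converged, trace = trace)
}

#' Mean birth-to-desquamation time from an event log
#'
#' Averages the lifetimes (desquamation time minus birth time) of shed cells
#' whose birth fell inside a window, so that truncation by the simulation
#' horizon stays negligible.
#'
#' @param state an \code{ifesim_tissue} after a run.
#' @param params an \code{ifesim_params}.
#' @param born_after_days,born_before_days birth-time window (days).
#' @return mean lifetime in days (NaN if no qualifying events).
#' @export
mean_turnover_days <- function(state, params, born_after_days = 0,
                               born_before_days = Inf) {
  e <- state$events
  d <- e[e[, "type"] == EV_DESQ, , drop = FALSE]
  born <- to_days(d[, "v1"], params)
  keep <- born >= born_after_days & born < born_before_days
  mean(to_days(d[keep, "time"] - d[keep, "v1"], params))
}
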