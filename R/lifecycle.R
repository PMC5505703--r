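# internal: append one event row (columns as EVENT_COLS)
append_event <- function(state, type, id1 = 0, id2 = 0, id3 = 0, kind = 0,
                         pos = c(0, 0, 0), v = c(0, 0, 0)) {
  row <- c(type, state$time, id1, id2, id3, kind, pos[1], pos[2], pos[3],
           v[1], v[2], v[3])
  state$events <- rbind(state$events, row)
  rownames(state$events) <- NULL
  state
}

#' Advance the cell-cycle clocks
#'
#' Reproducible cells — stem cells and membrane-attached committed
#' progenitors — accumulate cycle time; suprabasal and cornified cells carry
#' no clock.
#'
#' @param state an \code{ifesim_tissue}.
#' @param params an \code{ifesim_params}.
#' @param dt time increment (defaults to the integration step).
#' @return the updated state.
#' @export
advance_cycle <- function(state, params, dt = params$dt) {
  rep_ <- state$kind %in% c(KIND_STEM, KIND_DAUGHTER)
  state$cycle[rep_] <- state$cycle[rep_] + dt
  state
}

#' Sample which cells start dividing this step
#'
#' A cell whose cycle clock has passed \code{T_cycle} (and which is not in an
#' active division pair) enters the stochastic division phase: per step it
#' starts dividing with probability \code{1 - exp(-gamma * dt)}, so the
#' post-eligibility waiting time is exponential with mean \code{1/gamma}.
#' Draws consume the R random stream in ascending cell-id order.
#'
#' @inheritParams advance_cycle
#' @return integer vector of cell ids that start dividing.
#' @export
sample_division_starts <- function(state, params, dt = params$dt) {
  elig <- (state$kind %in% c(KIND_STEM, KIND_DAUGHTER)) &
    state$pair == 0L & state$cycle >= params$T_cycle
  ids <- state$id[elig]
  if (!length(ids)) return(integer(0))
  u <- stats::runif(length(ids))
  ids[u < 1 - exp(-params$gamma * dt)]
}

#' Begin a division
#'
#' The parent is deleted and two children are created at its exact position
#' with radius R (their overlap is permitted: the mutual contact force is
#' suppressed while the pair is active and replaced by the elastic dumbbell
#' potential). The stored initial axis — the force direction at zero
#' separation — is uniform on the sphere by default, or uniform in the
#' lateral plane with \code{division_axis = "in_plane"} (see
#' \code{\link{model_params}}). Fates: a stem parent yields one stem and one
#' committed-progenitor child; a progenitor parent yields two progenitors.
#' Children's cycle clocks start at zero.
#'
#' @param state an \code{ifesim_tissue}.
#' @param cell_id id of the dividing cell (must be eligible and unpaired).
#' @param params an \code{ifesim_params}.
#' @return the updated state.
#' @export
begin_division <- function(state, cell_id, params) {
  i <- match(cell_id, state$id)
  if (is.na(i)) stop("no cell with id ", cell_id, call. = FALSE)
  if (state$pair[i] != 0L)
    stop("cell ", cell_id, " is already in an active division pair",
         call. = FALSE)
  if (!(state$kind[i] %in% c(KIND_STEM, KIND_DAUGHTER)))
    stop("cell ", cell_id, " is not a reproducible kind", call. = FALSE)
  if (identical(params$division_axis, "in_plane")) {
    ph <- 2 * pi * stats::runif(1)
    axis <- c(cos(ph), sin(ph), 0)
  } else {
    u1 <- stats::runif(1)
    u2 <- stats::runif(1)
    zz <- 2 * u1 - 1
    ph <- 2 * pi * u2
    sq <- sqrt(max(0, 1 - zz^2))
    axis <- c(sq * cos(ph), sq * sin(ph), zz)
  }
  pid <- state$next_pair
  c1 <- state$next_id
  c2 <- state$next_id + 1L
  pk <- state$kind[i]
  pp <- state$pos[i, ]
  state <- append_event(state, EV_DIV_START, cell_id, c1, c2, pk, pp,
                        c(state$birth[i], 0, 0))
  kinds <- if (pk == KIND_STEM) c(KIND_STEM, KIND_DAUGHTER)
           else c(KIND_DAUGHTER, KIND_DAUGHTER)
  keep <- -i
  state$id <- c(state$id[keep], c1, c2)
  state$kind <- c(state$kind[keep], kinds)
  state$pair <- c(state$pair[keep], pid, pid)
  state$pos <- rbind(state$pos[keep, , drop = FALSE], pp, pp)
  rownames(state$pos) <- NULL
  state$cycle <- c(state$cycle[keep], 0, 0)
  state$S <- c(state$S[keep], 0, 0)
  state$calcium <- c(state$calcium[keep], 0, 0)
  state$birth <- c(state$birth[keep], state$time, state$time)
  state$pairs$id <- c(state$pairs$id, pid)
  state$pairs$c1 <- c(state$pairs$c1, c1)
  state$pairs$c2 <- c(state$pairs$c2, c2)
  state$pairs$t0 <- c(state$pairs$t0, state$time)
  state$pairs$ax <- c(state$pairs$ax, axis[1])
  state$pairs$ay <- c(state$pairs$ay, axis[2])
  state$pairs$az <- c(state$pairs$az, axis[3])
  state$pairs$pkind <- c(state$pairs$pkind, pk)
  state$next_id <- c2 + 1L
  state$next_pair <- pid + 1L
  state
}

#' Grow division pairs and finalize completed ones
#'
#' Each active pair's natural length is \code{l = alpha * (t - t0)}, capped
#' at \code{2R}. A pair reaching \code{2R} is completed: the pair is removed,
#' the mutual contact force is restored, and a division event is logged with
#' the realized axis (the normalized separation vector at completion).
#'
#' @inheritParams advance_cycle
#' @return the updated state.
#' @export
grow_and_complete_pairs <- function(state, params) {
  if (!length(state$pairs$id)) return(state)
  l <- params$alpha * (state$time - state$pairs$t0)
  done <- which(l >= 2 * params$R)
  for (q in done) {
    i <- match(state$pairs$c1[q], state$id)
    j <- match(state$pairs$c2[q], state$id)
    axis <- c(state$pairs$ax[q], state$pairs$ay[q], state$pairs$az[q])
    mid <- c(0, 0, 0)
    if (!is.na(i) && !is.na(j)) {
      dvec <- minimal_image_displacement(state$pos[i, ], state$pos[j, ], state)
      r <- sqrt(sum(dvec^2))
      if (r > 1e-12) axis <- dvec / r
      mid <- state$pos[j, ] + dvec / 2
      state$pair[c(i, j)] <- 0L
    }
    state <- append_event(state, EV_DIV_COMPLETE, state$pairs$c1[q],
                          state$pairs$c2[q], 0, state$pairs$pkind[q],
                          mid, axis)
  }
  if (length(done)) {
    keep <- setdiff(seq_along(state$pairs$id), done)
    state$pairs <- lapply(state$pairs, function(v) v[keep])
  }
  state
}

#' Detach over-stretched committed progenitors
#'
#' Every committed progenitor whose center distance to the nearest membrane
#' particle exceeds the detachment threshold \code{\link{r_star}} is
#' reclassified as suprabasal: S and calcium start at 0, the cycle clock is
#' discarded, and the transition is logged. Detachment is irreversible —
#' suprabasal cells never revert to a basal kind — and stem cells are never
#' reclassified.
#'
#' @inheritParams advance_cycle
#' @return the updated state.
#' @export
update_attachment <- function(state, params) {
  d_idx <- which(state$kind == KIND_DAUGHTER)
  if (!length(d_idx)) return(state)
  nm <- nearest_membrane_particle(state$pos[d_idx, , drop = FALSE],
                                  state$membrane)
  off <- d_idx[nm$distance > r_star(params)]
  for (i in off) {
    state$kind[i] <- KIND_SUPRABASAL
    state$S[i] <- 0
    state$calcium[i] <- 0
    state$cycle[i] <- 0
    state <- append_event(state, EV_DETACH, state$id[i], kind = KIND_DAUGHTER,
                          pos = state$pos[i, ], v = c(state$birth[i], 0, 0))
  }
  state
}
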