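#' @useDynLib ifesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# cell kind codes shared with the C++ engine
KIND_STEM <- 1L
KIND_DAUGHTER <- 2L
KIND_SUPRABASAL <- 3L
KIND_CORNIFIED <- 4L

KIND_LEVELS <- c("stem", "daughter", "suprabasal", "cornified")

# event type codes shared with the C++ engine
EV_DIV_START <- 1L
EV_DIV_COMPLETE <- 2L
EV_DETACH <- 3L
EV_CORNIFY <- 4L
EV_DESQ <- 5L
EV_LEVELS <- c("div_start", "div_complete", "detach", "cornify", "desq")

EVENT_COLS <- c("type", "time", "id1", "id2", "id3", "kind",
                "x", "y", "z", "v1", "v2", "v3")

empty_events <- function() {
  m <- matrix(numeric(0), ncol = length(EVENT_COLS))
  colnames(m) <- EVENT_COLS
  m
}

empty_pairs <- function() {
  list(id = integer(0), c1 = integer(0), c2 = integer(0),
       t0 = numeric(0), ax = numeric(0), ay = numeric(0), az = numeric(0),
       pkind = integer(0))
}

#' Construct a tissue state
#'
#' The full simulation state: time, the laterally periodic box (inherited
#' from the membrane), per-cell arrays, active division pairs, and the
#' append-only event log. Cells are stored in ascending-id order; new cells
#' are appended with increasing ids, so storage order and id order coincide
#' for the whole run (the engine relies on this for reproducible
#' random-draw ordering).
#'
#' @param pos \code{n x 3} matrix of cell centers.
#' @param kind integer codes or character kinds
#'   (\code{"stem","daughter","suprabasal","cornified"}).
#' @param membrane an \code{ifesim_membrane}.
#' @param params an \code{ifesim_params} (radii are taken from it).
#' @param cycle,S,calcium,birth optional per-cell vectors (defaults 0).
#' @param time simulation time of the state.
#' @return an object of class \code{ifesim_tissue}.
#' @export
tissue_state <- function(pos, kind, membrane, params,
                         cycle = NULL, S = NULL, calcium = NULL,
                         birth = NULL, time = 0) {
  pos <- rbind(pos)
  n <- nrow(pos)
  if (is.character(kind)) kind <- match(kind, KIND_LEVELS)
  kind <- as.integer(kind)
  stopifnot(length(kind) == n, all(kind %in% 1:4))
  zero <- function(v) if (is.null(v)) numeric(n) else {
    stopifnot(length(v) == n); as.numeric(v)
  }
  # wrap lateral coordinates into [0, L)
  pos[, 1] <- pos[, 1] %% membrane$Lx
  pos[, 2] <- pos[, 2] %% membrane$Ly
  st <- list(time = time, Lx = membrane$Lx, Ly = membrane$Ly,
             membrane = membrane,
             id = seq_len(n), pos = unname(pos), kind = kind,
             cycle = zero(cycle), S = zero(S), calcium = zero(calcium),
             birth = zero(birth), pair = integer(n),
             pairs = empty_pairs(),
             next_id = n + 1L, next_pair = 1L,
             events = empty_events())
  class(st) <- "ifesim_tissue"
  st
}

#' Number of cells and counts by kind
#'
#' @param state an \code{ifesim_tissue}.
#' @return named integer vector over the four kinds plus \code{total}.
#' @export
cell_counts <- function(state) {
  k <- tabulate(state$kind, nbins = 4L)
  c(stats::setNames(k, KIND_LEVELS), total = length(state$kind))
}

#' Event log as a data frame
#'
#' Events: \code{div_start} (id1 parent, id2/id3 children, v1 parent birth
#' time, kind = parent kind), \code{div_complete} (id1/id2 children, v1..v3
#' realized axis, x/y/z pair midpoint, kind = parent kind), \code{detach},
#' \code{cornify} and \code{desq} (id1 cell, v1 its birth time).
#'
#' @param state an \code{ifesim_tissue}.
#' @return a data frame with a readable \code{type} column.
#' @export
event_log <- function(state) {
  e <- as.data.frame(state$events)
  e$type <- factor(EV_LEVELS[e$type], levels = EV_LEVELS)
  e
}

#' @export
print.ifesim_tissue <- function(x, ...) {
  cc <- cell_counts(x)
  cat(sprintf("ifesim tissue: t = %.2f, box %g x %g, %d cells (%s), %d active pairs, %d events\n",
              x$time, x$Lx, x$Ly, cc[["total"]],
              paste(sprintf("%s %d", KIND_LEVELS, cc[1:4]), collapse = ", "),
              length(x$pairs$id), nrow(x$events)))
  invisible(x)
}

#' Write a cell snapshot as CSV
#'
#' Columns: id, kind, x, y, z, radius, cycle, S, calcium, birth, pair.
#'
#' @param state an \code{ifesim_tissue}.
#' @param path file path.
#' @param params an \code{ifesim_params} (for the radius column).
#' @export
write_cells_csv <- function(state, path, params) {
  d <- data.frame(id = state$id, kind = KIND_LEVELS[state$kind],
                  x = state$pos[, 1], y = state$pos[, 2], z = state$pos[, 3],
                  radius = params$R, cycle = state$cycle, S = state$S,
                  calcium = state$calcium, birth = state$birth,
                  pair = state$pair)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: pack state for the C++ engine
state_to_cpp <- function(state) {
  list(time = state$time, Lx = state$Lx, Ly = state$Ly,
       id = state$id, pos = state$pos, kind = state$kind,
       cycle = state$cycle, S = state$S, calcium = state$calcium,
       birth = state$birth, pair = state$pair,
       p_id = state$pairs$id, p_c1 = state$pairs$c1, p_c2 = state$pairs$c2,
       p_t0 = state$pairs$t0, p_ax = state$pairs$ax, p_ay = state$pairs$ay,
       p_az = state$pairs$az, p_kind = state$pairs$pkind,
       next_id = state$next_id, next_pair = state$next_pair)
}

# internal: unpack engine output into the state, appending new events
state_from_cpp <- function(out, state) {
  state$time <- out$time
  state$id <- as.integer(out$id)
  state$pos <- out$pos
  state$kind <- as.integer(out$kind)
  state$cycle <- out$cycle
  state$S <- out$S
  state$calcium <- out$calcium
  state$birth <- out$birth
  state$pair <- as.integer(out$pair)
  state$pairs <- list(id = as.integer(out$p_id), c1 = as.integer(out$p_c1),
                      c2 = as.integer(out$p_c2), t0 = out$p_t0,
                      ax = out$p_ax, ay = out$p_ay, az = out$p_az,
                      pkind = as.integer(out$p_kind))
  state$next_id <- as.integer(out$next_id)
  state$next_pair <- as.integer(out$next_pair)
  if (nrow(out$events) > 0) {
    colnames(out$events) <- EVENT_COLS
    state$events <- rbind(state$events, out$events)
  }
  state
}

# internal: parameters as the flat numeric list the engine expects
params_to_cpp <- function(params) {
  p <- unclass(params)
  p$lj_printed <- as.integer(identical(p$lj_form, "printed"))
  p$lj_form <- NULL
  p$axis_in_plane <- as.integer(identical(p$division_axis, "in_plane"))
  p$division_axis <- NULL
  p
}

# internal: membrane as the flat list the engine expects
membrane_to_cpp <- function(membrane) {
  list(pos = membrane$pos, Lx = membrane$Lx, Ly = membrane$Ly,
       nx = membrane$nx, ny = membrane$ny, sx = membrane$sx,
       sy = membrane$sy, Rm = membrane$Rm)
}
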