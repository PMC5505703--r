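#' Specification of the undulated basal membrane
#'
#' The basal membrane is a monolayer of densely packed immobile particles of
#' radius \code{Rm} on a regular lateral grid, with a product-of-sines height
#' profile \eqn{z = A \sin(2\pi x/\lambda)\sin(2\pi y/\lambda)}. The lateral
#' box is periodic, so \code{Lx} and \code{Ly} must be integer multiples of
#' the undulation wavelength. A flat membrane (\code{amp = 0}) is supported
#' for unit fixtures.
#'
#' @param Lx,Ly lateral box lengths.
#' @param spacing in-plane particle pitch; must be <= 2*Rm (dense packing).
#' @param amp undulation amplitude.
#' @param wavelength undulation wavelength.
#' @param phase lateral phase offset applied to the undulation (used by the
#'   ensemble runner to vary membrane shape between runs).
#' @param Rm membrane particle radius (kept with the spec so packing can be
#'   checked without a parameter object).
#' @return an object of class \code{ifesim_membrane_spec}.
#' @export
membrane_spec <- function(Lx = 20, Ly = 20, spacing = 2.0, amp = 1.0,
                          wavelength = 10, phase = 0, Rm = 1.0) {
  stopifnot(Lx > 0, Ly > 0, spacing > 0, amp >= 0, wavelength > 0, Rm > 0)
  if (spacing > 2 * Rm)
    stop("packing violation: spacing (", spacing, ") > 2*Rm (", 2 * Rm, ")",
         call. = FALSE)
  if (amp > 0) {
    for (L in c(Lx, Ly)) {
      k <- L / wavelength
      if (abs(k - round(k)) > 1e-9)
        stop("box length ", L, " is not an integer multiple of wavelength ",
             wavelength, "; undulation would break periodicity", call. = FALSE)
    }
  }
  s <- list(Lx = Lx, Ly = Ly, spacing = spacing, amp = amp,
            wavelength = wavelength, phase = phase, Rm = Rm)
  class(s) <- "ifesim_membrane_spec"
  s
}

#' Generate the basal-membrane particle monolayer
#'
#' Particles sit on a regular \code{nx = round(Lx/spacing)} by
#' \code{ny = round(Ly/spacing)} lateral grid (pitch adjusted to tile the
#' periodic box exactly) with the undulated height profile of the spec.
#' Generation is fully deterministic given the spec.
#'
#' @param spec an \code{ifesim_membrane_spec}.
#' @return an object of class \code{ifesim_membrane}: a list with the
#'   \code{m x 3} position matrix \code{pos}, the grid metadata, and the box.
#'   Particle ids are the row indices.
#' @export
generate_membrane <- function(spec) {
  stopifnot(inherits(spec, "ifesim_membrane_spec"))
  nx <- max(1L, as.integer(round(spec$Lx / spec$spacing)))
  ny <- max(1L, as.integer(round(spec$Ly / spec$spacing)))
  sx <- spec$Lx / nx
  sy <- spec$Ly / ny
  # row-major over y then x: id = (iy-1)*nx + ix
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  x <- (ix - 1) * sx
  y <- (iy - 1) * sy
  z <- if (spec$amp > 0) {
    spec$amp * sin(2 * pi * (x + spec$phase) / spec$wavelength) *
      sin(2 * pi * (y + spec$phase) / spec$wavelength)
  } else {
    rep(0, nx * ny)
  }
  m <- list(pos = cbind(x = x, y = y, z = z),
            Lx = spec$Lx, Ly = spec$Ly, nx = nx, ny = ny,
            sx = sx, sy = sy, Rm = spec$Rm, spec = spec)
  class(m) <- "ifesim_membrane"
  m
}

#' Minimal-image displacement in the laterally periodic box
#'
#' Returns \code{xi - xj} with the x and y components wrapped into
#' \code{(-L/2, L/2]}; z is never wrapped (the tissue is open above the
#' membrane).
#'
#' @param xi,xj 3-vectors (or matrices with 3 columns, recycled row-wise).
#' @param box a list or object carrying \code{Lx} and \code{Ly}.
#' @return displacement(s), same shape as the broadcast inputs.
#' @export
minimal_image_displacement <- function(xi, xj, box) {
  d <- rbind(xi) - rbind(xj)
  for (k in 1:2) {
    L <- if (k == 1) box$Lx else box$Ly
    d[, k] <- d[, k] - L * round(d[, k] / L)
    # map boundary -L/2 to +L/2 so the interval is (-L/2, L/2]
    at <- d[, k] == -L / 2
    d[, k][at] <- L / 2
  }
  if (nrow(d) == 1L) drop(d) else d
}

#' Nearest membrane particle to a point or cell
#'
#' Grid-accelerated lookup of the membrane particle minimizing the periodic
#' center distance; ties are broken by the lowest particle id. The
#' accelerated path is validated against exhaustive search in the test suite.
#'
#' @param pos a 3-vector, or an \code{n x 3} matrix of positions.
#' @param membrane an \code{ifesim_membrane}.
#' @return a list with integer \code{id} and numeric \code{distance}
#'   (vectors when \code{pos} is a matrix).
#' @export
nearest_membrane_particle <- function(pos, membrane) {
  p <- rbind(pos)
  p[, 1] <- p[, 1] %% membrane$Lx
  p[, 2] <- p[, 2] %% membrane$Ly
  res <- cpp_nearest_membrane(p, membrane$pos, membrane$Lx, membrane$Ly,
                              membrane$nx, membrane$ny, membrane$sx,
                              membrane$sy)
  list(id = as.integer(res$id), distance = res$dist)
}

#' Seed the initial basal-cell layer
#'
#' Places one basal cell per membrane site, directly above the particle at
#' center distance \code{R + Rm} (zero anchoring displacement for both
#' anchoring potentials). Each cell is a stem cell with probability
#' \code{stem_fraction}, otherwise a committed progenitor; cycle clocks are
#' initialized uniformly in \code{[0, T_cycle)} to desynchronize divisions.
#' Consumes the R random-number stream (use \code{set.seed} for
#' reproducibility).
#'
#' @param membrane an \code{ifesim_membrane}.
#' @param params an \code{ifesim_params}.
#' @param stem_fraction probability that a seeded cell is a stem cell.
#' @return an \code{ifesim_tissue} state at time 0 (see
#'   \code{\link{tissue_state}}).
#' @export
seed_initial_cells <- function(membrane, params, stem_fraction = 0.2) {
  stopifnot(stem_fraction > 0, stem_fraction <= 1)
  n <- nrow(membrane$pos)
  pos <- membrane$pos
  pos[, 3] <- pos[, 3] + params$R + params$Rm
  kind <- ifelse(stats::runif(n) < stem_fraction, KIND_STEM, KIND_DAUGHTER)
  cycle <- stats::runif(n, 0, params$T_cycle)
  tissue_state(pos = pos, kind = kind, cycle = cycle, membrane = membrane,
               params = params)
}

#' Write / read a particle table as CSV
#'
#' Plain-text serialization of membrane particles or cells
#' (id, kind, x, y, z, radius) so fixtures can be versioned as text.
#'
#' @param membrane an \code{ifesim_membrane}.
#' @param path file path.
#' @export
write_membrane_csv <- function(membrane, path) {
  d <- data.frame(id = seq_len(nrow(membrane$pos)), kind = "membrane",
                  x = membrane$pos[, 1], y = membrane$pos[, 2],
                  z = membrane$pos[, 3], radius = membrane$Rm)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
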