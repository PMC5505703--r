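#' Cell-cell contact force
#'
#' Short-range repulsive pair force between two spheres. With the default
#' contact cutoff (center distance \code{d = Ri + Rj}) the potential is the
#' sign-corrected, shifted-truncated form
#' \deqn{V(r) = \epsilon[\tfrac12 (d/r)^{12} - (d/r)^6] + \epsilon/2, \quad r \le d,}
#' zero beyond, which is purely repulsive and continuous (zero force at
#' \code{r = d}). With \code{contact_cutoff_factor > 1} the unshifted
#' potential, including its adhesive tail, is truncated at the cutoff.
#' \code{lj_form = "printed"} selects the sign-inverted variant retained for
#' comparison only.
#'
#' @param rvec displacement vector from cell j to cell i (\code{xi - xj}).
#' @param Ri,Rj radii of the two spheres.
#' @param params an \code{ifesim_params}.
#' @return the force on cell i (3-vector); the force on j is its negative.
#' @export
cell_cell_force <- function(rvec, Ri, Rj, params) {
  r <- sqrt(sum(rvec^2))
  if (r == 0) stop("degenerate overlap: zero separation outside a division pair",
                   call. = FALSE)
  d <- Ri + Rj
  if (r > params$contact_cutoff_factor * d) return(c(0, 0, 0))
  s2 <- (d / r)^2
  s6 <- s2^3
  s12 <- s6^2
  dV <- (6 * params$eps / r) * (s6 - s12)   # d/dr of eps(s12/2 - s6)
  if (identical(params$lj_form, "printed")) dV <- -dV
  -dV * rvec / r
}

# pair potential value (R reference used by tests)
cell_cell_potential <- function(r, Ri, Rj, params) {
  d <- Ri + Rj
  if (r > params$contact_cutoff_factor * d) return(0)
  s6 <- (d / r)^6
  s12 <- s6^2
  V <- if (identical(params$lj_form, "printed")) {
    params$eps * (s6 - 0.5 * s12)
  } else {
    params$eps * (0.5 * s12 - s6)
  }
  if (!identical(params$lj_form, "printed") &&
      params$contact_cutoff_factor == 1.0) V <- V + 0.5 * params$eps
  V
}

#' Stem-cell anchoring force
#'
#' Harmonic spring toward the nearest membrane particle with rest length
#' \code{R + Rm}: \eqn{V_m(r) = K_s/2\,[r - (R+R_m)]^2}. Unbounded, so stem
#' cells can never leave the membrane.
#'
#' @param cell_pos 3-vector, the stem cell center.
#' @param membrane an \code{ifesim_membrane}.
#' @param params an \code{ifesim_params}.
#' @return the force on the cell (3-vector).
#' @export
stem_anchor_force <- function(cell_pos, membrane, params) {
  nm <- nearest_membrane_particle(cell_pos, membrane)
  e <- minimal_image_displacement(cell_pos, membrane$pos[nm$id, ], membrane)
  r <- nm$distance
  u <- r - (params$R + params$Rm)
  -params$Ks * u * e / r
}

#' Committed-progenitor anchoring force
#'
#' Quartic spring toward the nearest membrane particle,
#' \eqn{V_m(r) = K_d/2\,[a u^2 - (b/2) u^4]} with \eqn{u = r - (R+R_m)} for
#' \eqn{r \le r^*} and zero beyond the detachment threshold
#' \eqn{r^* = R + R_m + a/b}. The potential (and hence the force) is
#' discontinuous at \eqn{r^*}, exactly as specified.
#'
#' @inheritParams stem_anchor_force
#' @return the force on the cell (3-vector).
#' @export
daughter_anchor_force <- function(cell_pos, membrane, params) {
  nm <- nearest_membrane_particle(cell_pos, membrane)
  r <- nm$distance
  if (r > r_star(params)) return(c(0, 0, 0))
  e <- minimal_image_displacement(cell_pos, membrane$pos[nm$id, ], membrane)
  u <- r - (params$R + params$Rm)
  -params$Kd * u * (params$a - params$b * u^2) * e / r
}

#' Division-pair elastic force
#'
#' While a division pair is active, the ordinary contact force between its
#' two members is suppressed and replaced by the elastic potential
#' \eqn{U = K'/2 (|x_j - x_k| - l(t))^2} with natural length
#' \eqn{l(t) = \alpha (t - t_0)}, capped at \code{2R}. At exactly zero
#' separation the force acts along the pair's stored initial axis.
#'
#' @param state an \code{ifesim_tissue}.
#' @param pair_id id of an active division pair.
#' @param params an \code{ifesim_params}.
#' @return a list with \code{F1}, \code{F2} (forces on the two children) and
#'   the current natural length \code{l}.
#' @export
division_pair_force <- function(state, pair_id, params) {
  q <- match(pair_id, state$pairs$id)
  if (is.na(q)) stop("no active division pair with id ", pair_id, call. = FALSE)
  i <- match(state$pairs$c1[q], state$id)
  j <- match(state$pairs$c2[q], state$id)
  l <- min(params$alpha * (state$time - state$pairs$t0[q]), 2 * params$R)
  dvec <- minimal_image_displacement(state$pos[i, ], state$pos[j, ], state)
  r <- sqrt(sum(dvec^2))
  e <- if (r > 1e-12) dvec / r else
    c(state$pairs$ax[q], state$pairs$ay[q], state$pairs$az[q])
  F1 <- -params$Kprime * (r - l) * e
  list(F1 = F1, F2 = -F1, l = l)
}

#' Total forces on all cells
#'
#' Sum, for every cell, of the contact forces from touching cells (division
#' partners suppressed) and the nearest membrane particle, the
#' kind-appropriate anchoring force (stem/daughter; none for suprabasal or
#' cornified cells), and any active division-pair force. Membrane particles
#' are immobile, so forces on them are never applied.
#'
#' @param state an \code{ifesim_tissue}.
#' @param params an \code{ifesim_params}.
#' @return an \code{n x 3} force matrix.
#' @export
total_forces <- function(state, params) {
  out <- cpp_forces(state_to_cpp(state), membrane_to_cpp(state$membrane),
                    params_to_cpp(params))
  out$F
}

#' Total potential energy of a state
#'
#' The potential whose exact negative gradient \code{\link{total_forces}}
#' returns: contact pair terms, membrane contact terms, anchoring terms and
#' division-pair elastic terms.
#'
#' @inheritParams total_forces
#' @return a single number.
#' @export
total_potential <- function(state, params) {
  cpp_potential(state_to_cpp(state), membrane_to_cpp(state$membrane),
                params_to_cpp(params))
}

#' One explicit-Euler integration step
#'
#' Overdamped update \code{pos <- pos + (dt/mu) * F} for every cell; membrane
#' particles are immobile; lateral coordinates are re-wrapped into the box;
#' time advances by \code{dt}. Per-step displacements are capped at
#' \code{max_step_disp} as a numerical guard; a non-finite coordinate raises
#' an error naming the offending cell and dt.
#'
#' @inheritParams total_forces
#' @return the updated \code{ifesim_tissue}.
#' @export
integrate_step <- function(state, params) {
  out <- cpp_run(state_to_cpp(state), membrane_to_cpp(state$membrane),
                 params_to_cpp(params), n_steps = 1L, record_every = 0L,
                 stages = 1L)
  state_from_cpp(out, state)
}
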