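#' Model parameters for the epidermis simulator
#'
#' Constructs the full parameter set of the model. Mechanical symbols follow
#' the standard center-based formulation: cells of radius \code{R} above a
#' monolayer of immobile membrane particles of radius \code{Rm}, overdamped
#' motion with friction \code{mu}, short-range repulsive pair interaction of
#' strength \code{eps}, a harmonic stem-cell anchor of stiffness \code{Ks},
#' a quartic committed-progenitor anchor of strength \code{Kd} with shape
#' coefficients \code{a} and \code{b} (detachment threshold
#' \eqn{r^* = R + R_m + a/b}), a division dumbbell spring \code{Kprime} whose
#' natural length grows at rate \code{alpha}, a deterministic cell-cycle
#' period \code{T_cycle} followed by a Poisson division hazard \code{gamma}.
#'
#' Simulator-level settings (integration step \code{dt}, the day-unit
#' calibration, the differentiation/calcium surrogate constants, the
#' desquamation rate and the contact cutoff) are exposed with documented
#' defaults; they are calibration knobs, not measured quantities.
#'
#' @param mu friction coefficient (model units).
#' @param R epidermal cell radius.
#' @param Rm membrane particle radius.
#' @param eps cell-cell interaction strength.
#' @param Ks stem-cell anchoring spring constant.
#' @param Kd committed-progenitor (daughter) anchoring strength; this is the
#'   knob the adhesion-perturbation experiment switches from 5.0 to 2.0.
#' @param a,b quartic anchoring coefficients; the detachment threshold is
#'   \code{R + Rm + a/b}.
#' @param Kprime division-pair spring constant.
#' @param gamma Poisson division rate (per model-time unit) once the cycle
#'   period has elapsed.
#' @param alpha growth rate of the division pair's natural length.
#' @param T_cycle deterministic cell-cycle period (model-time units).
#' @param dt explicit-Euler integration step.
#' @param day_unit model-time units per simulated day. The default calibrates
#'   the mean inter-division interval \code{T_cycle + 1/gamma} to 3 days.
#' @param S_star differentiation threshold at which a suprabasal cell
#'   cornifies.
#' @param s_base baseline differentiation rate dS/dt of suprabasal cells.
#' @param lam_ca calcium acceleration factor: dS/dt = s_base (1 + lam_ca * c).
#' @param c_exc calcium level imposed while touching a cornified cell.
#' @param k_ca calcium decay rate when not excited.
#' @param desq_rate removal hazard for surface-exposed cornified cells.
#' @param contact_cutoff_factor contact is center distance <= factor * (Ri+Rj);
#'   at the default 1.0 the pair potential is the shifted-truncated repulsive
#'   form, for larger values the unshifted potential (with its adhesive tail)
#'   is truncated at the cutoff.
#' @param lj_form \code{"repulsive"} (sign-corrected, default) or
#'   \code{"printed"} (the literal attractive-under-overlap form, retained for
#'   comparison only).
#' @param division_axis initial push direction of a division pair:
#'   \code{"isotropic"} (default, uniform on the sphere — the minimal
#'   assumption) or \code{"in_plane"} (uniform in the lateral plane, keeping
#'   newborn cells within the basal layer so that only crowding rotates
#'   pairs out of plane). The realized axis logged at completion is emergent
#'   under either choice.
#' @param max_step_disp cap on per-step displacement of any cell, a numerical
#'   guard against pathological overlaps (length units).
#'
#' @return an object of class \code{ifesim_params} (a validated named list).
#' @export
#' @examples
#' p <- model_params()
#' r_star(p)           # ~ 2.63085
#' to_days(p$T_cycle + 1 / p$gamma, p)  # 3 by construction
model_params <- function(mu = 1.0, R = 1.4, Rm = 1.0, eps = 1.0,
                         Ks = 25.0, Kd = 5.0, a = 0.0868, b = 0.376,
                         Kprime = 5.0, gamma = 0.00813, alpha = 0.14,
                         T_cycle = 100, dt = 0.01,
                         day_unit = (T_cycle + 1 / gamma) / 3,
                         S_star = 1.0, s_base = 0.00039, lam_ca = 3.0,
                         c_exc = 1.0, k_ca = 0.1, desq_rate = 0.05,
                         contact_cutoff_factor = 1.0,
                         lj_form = c("repulsive", "printed"),
                         division_axis = c("isotropic", "in_plane"),
                         max_step_disp = 0.7) {
  lj_form <- match.arg(lj_form)
  division_axis <- match.arg(division_axis)
  p <- list(mu = mu, R = R, Rm = Rm, eps = eps, Ks = Ks, Kd = Kd,
            a = a, b = b, Kprime = Kprime, gamma = gamma, alpha = alpha,
            T_cycle = T_cycle, dt = dt, day_unit = day_unit,
            S_star = S_star, s_base = s_base, lam_ca = lam_ca,
            c_exc = c_exc, k_ca = k_ca, desq_rate = desq_rate,
            contact_cutoff_factor = contact_cutoff_factor,
            lj_form = lj_form, division_axis = division_axis,
            max_step_disp = max_step_disp)
  class(p) <- "ifesim_params"
  validate_params(p)
  p
}

#' @rdname model_params
#' @export
make_default_params <- function() model_params()

validate_params <- function(p) {
  num <- setdiff(names(p), c("lj_form", "division_axis"))
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  pos <- c("mu", "R", "Rm", "eps", "Ks", "a", "b", "Kprime", "gamma",
           "alpha", "T_cycle", "dt", "day_unit", "S_star",
           "contact_cutoff_factor", "max_step_disp")
  for (nm in pos) if (p[[nm]] <= 0)
    stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  nonneg <- c("Kd", "s_base", "lam_ca", "c_exc", "k_ca", "desq_rate")
  for (nm in nonneg) if (p[[nm]] < 0)
    stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  if (!(p$lj_form %in% c("repulsive", "printed")))
    stop("lj_form must be 'repulsive' or 'printed'", call. = FALSE)
  if (!(p$division_axis %in% c("in_plane", "isotropic")))
    stop("division_axis must be 'in_plane' or 'isotropic'", call. = FALSE)
  # explicit-Euler stability guard on the stiffest spring
  stiff <- max(p$Ks, p$Kprime, p$Kd * p$a)
  if (stiff * p$dt / p$mu >= 0.5)
    stop("dt too large for stability: max(Ks, Kprime, Kd*a)*dt/mu = ",
         signif(stiff * p$dt / p$mu, 4), " >= 0.5", call. = FALSE)
  invisible(p)
}

#' Detachment threshold distance
#'
#' The center distance beyond which the quartic anchoring potential of a
#' committed progenitor vanishes and the cell may leave the basal layer:
#' \eqn{r^* = R + R_m + a/b}.
#'
#' @param params an \code{ifesim_params} object (or a list with R, Rm, a, b).
#' @return the threshold distance (length units).
#' @export
r_star <- function(params) {
  if (params$b == 0) stop("r_star undefined: b must be > 0", call. = FALSE)
  params$R + params$Rm + params$a / params$b
}

#' Convert simulation time to days
#'
#' Uses the day-unit calibration stored in the parameters. With the default
#' calibration, \code{day_unit = (T_cycle + 1/gamma)/3}, so the mean
#' inter-division interval of a continuously eligible cell maps to 3 days.
#'
#' @param t_sim time in model units (vectorized).
#' @param params an \code{ifesim_params} object.
#' @return time in days.
#' @export
to_days <- function(t_sim, params) {
  stopifnot(params$day_unit > 0)
  t_sim / params$day_unit
}

#' @export
print.ifesim_params <- function(x, ...) {
  cat("ifesim model parameters\n")
  cat(sprintf("  mechanics: mu=%g R=%g Rm=%g eps=%g Ks=%g Kd=%g a=%g b=%g (r*=%.5g)\n",
              x$mu, x$R, x$Rm, x$eps, x$Ks, x$Kd, x$a, x$b, r_star(x)))
  cat(sprintf("  division:  Kprime=%g alpha=%g T_cycle=%g gamma=%g\n",
              x$Kprime, x$alpha, x$T_cycle, x$gamma))
  cat(sprintf("  diff/ca:   S_star=%g s_base=%g lam_ca=%g c_exc=%g k_ca=%g desq_rate=%g\n",
              x$S_star, x$s_base, x$lam_ca, x$c_exc, x$k_ca, x$desq_rate))
  cat(sprintf("  numerics:  dt=%g day_unit=%.5g cutoff=%g lj_form=%s\n",
              x$dt, x$day_unit, x$contact_cutoff_factor, x$lj_form))
  invisible(x)
}

#' Read / write a parameter configuration file
#'
#' The configuration is one flat YAML mapping with exactly the fields of
#' \code{\link{model_params}}. Unknown keys are an error; missing keys take
#' the documented defaults.
#'
#' @param path file path.
#' @param params an \code{ifesim_params} object.
#' @return \code{read_config} returns an \code{ifesim_params};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(model_params))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(model_params, raw)
}

#' @rdname read_config
#' @export
write_config <- function(params, path) {
  x <- unclass(params)
  yaml::write_yaml(x, path, precision = 17L)  # bit-exact double round-trip
  invisible(path)
}
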