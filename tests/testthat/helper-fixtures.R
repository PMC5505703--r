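# small builders shared across the test files; everything is generated in
# code, no stored fixtures

flat_membrane <- function(Lx = 20, Ly = 20, spacing = 2, Rm = 1) {
  generate_membrane(membrane_spec(Lx = Lx, Ly = Ly, spacing = spacing,
                                  amp = 0, Rm = Rm))
}

wavy_membrane <- function(Lx = 20, Ly = 20, amp = 1, wavelength = 10,
                          phase = 0) {
  generate_membrane(membrane_spec(Lx = Lx, Ly = Ly, spacing = 2, amp = amp,
                                  wavelength = wavelength, phase = phase))
}

# a state with cells at given positions (rows) and kinds above a membrane
make_state <- function(pos, kind, membrane = flat_membrane(),
                       params = model_params(), ...) {
  tissue_state(pos = pos, kind = kind, membrane = membrane, params = params,
               ...)
}

# n cells with mixed kinds and non-trivial contacts, built so that every
# interaction sits away from the model's genuine discontinuities (the
# progenitor cutoff at r*, nearest-membrane-particle switches, and deep
# overlaps), where a central-difference oracle is meaningful:
# basal cells sit close over membrane particles, detached cells float above,
# and pairwise separations stay above 0.82 of the contact distance
random_state <- function(n = 20, seed = 1, membrane = flat_membrane(),
                         params = model_params()) {
  set.seed(seed)
  n_bas <- floor(n / 2)
  sites <- sample(nrow(membrane$pos), n_bas)
  bas <- membrane$pos[sites, , drop = FALSE] +
    cbind(runif(n_bas, -0.2, 0.2), runif(n_bas, -0.2, 0.2),
          params$R + params$Rm + runif(n_bas, -0.05, 0.1))
  up <- matrix(0, 0, 3)
  while (nrow(up) < n - n_bas) {
    cand <- c(runif(1, 0, membrane$Lx), runif(1, 0, membrane$Ly),
              runif(1, 3.6, 8))
    all_pos <- rbind(bas, up)
    d <- sqrt(pmin(abs(all_pos[, 1] - cand[1]),
                   membrane$Lx - abs(all_pos[, 1] - cand[1]))^2 +
              pmin(abs(all_pos[, 2] - cand[2]),
                   membrane$Ly - abs(all_pos[, 2] - cand[2]))^2 +
              (all_pos[, 3] - cand[3])^2)
    if (min(d) >= 0.82 * 2 * params$R) up <- rbind(up, cand)
  }
  kind <- c(sample(c("stem", "daughter"), n_bas, replace = TRUE),
            sample(c("suprabasal", "cornified"), n - n_bas, replace = TRUE))
  make_state(rbind(bas, up), kind, membrane, params)
}

# central finite difference of the total potential wrt every coordinate
numerical_forces <- function(state, params, h = 1e-6) {
  n <- length(state$id)
  F <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      sp <- state; sp$pos[i, k] <- sp$pos[i, k] + h
      sm <- state; sm$pos[i, k] <- sm$pos[i, k] - h
      F[i, k] <- -(total_potential(sp, params) -
                   total_potential(sm, params)) / (2 * h)
    }
  }
  F
}

# exhaustive nearest-membrane search (the oracle for the grid-accelerated
# lookup), including the lowest-id tie-break
brute_nearest <- function(pos, membrane) {
  pos <- rbind(pos)
  out_id <- integer(nrow(pos))
  out_d <- numeric(nrow(pos))
  for (r in seq_len(nrow(pos))) {
    dx <- pos[r, 1] - membrane$pos[, 1]
    dy <- pos[r, 2] - membrane$pos[, 2]
    dx <- dx - membrane$Lx * round(dx / membrane$Lx)
    dy <- dy - membrane$Ly * round(dy / membrane$Ly)
    dz <- pos[r, 3] - membrane$pos[, 3]
    d2 <- dx^2 + dy^2 + dz^2
    out_id[r] <- which(d2 == min(d2))[1]  # lowest id on ties
    out_d[r] <- sqrt(min(d2))
  }
  list(id = out_id, distance = out_d)
}
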