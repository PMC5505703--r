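p0 <- model_params()

test_that("cell-cell contact force matches hand-derived values", {
  d <- 2 * p0$R  # 2.8
  # at the truncation point r = d the force vanishes (potential minimum)
  expect_equal(cell_cell_force(c(d, 0, 0), p0$R, p0$R, p0),
               c(0, 0, 0), tolerance = 1e-12)
  # r = 0.9 d: repulsive magnitude (6 eps / r)(s^12 - s^6), s = 1/0.9
  f <- cell_cell_force(c(0, 0, 0.9 * d), p0$R, p0$R, p0)
  s <- 1 / 0.9
  expect_equal(f[3], (6 / (0.9 * d)) * (s^12 - s^6), tolerance = 1e-12)
  expect_equal(f[3], 3.950069, tolerance = 1e-5)
  expect_equal(f[1:2], c(0, 0))
  # beyond contact: zero
  expect_equal(cell_cell_force(c(1.2 * d, 0, 0), p0$R, p0$R, p0), c(0, 0, 0))
  # finite-difference cross-check of the pair potential
  h <- 1e-7
  r <- 0.93 * d
  fd <- -(cell_cell_potential(r + h, p0$R, p0$R, p0) -
          cell_cell_potential(r - h, p0$R, p0$R, p0)) / (2 * h)
  expect_equal(cell_cell_force(c(r, 0, 0), p0$R, p0$R, p0)[1], fd,
               tolerance = 1e-6)
  expect_error(cell_cell_force(c(0, 0, 0), p0$R, p0$R, p0), "degenerate")
})

test_that("printed pair-potential variant has the inverted sign", {
  pp <- model_params(lj_form = "printed")
  f_rep <- cell_cell_force(c(0, 0, 2.52), p0$R, p0$R, p0)
  f_prn <- cell_cell_force(c(0, 0, 2.52), p0$R, p0$R, pp)
  expect_equal(f_prn, -f_rep)
})

test_that("stem anchoring is an unbounded harmonic spring", {
  mem <- flat_membrane()
  # cell directly above particle 1 at stretch u = 0.5
  f <- stem_anchor_force(c(0, 0, 2.9), mem, p0)
  expect_equal(f, c(0, 0, -12.5), tolerance = 1e-9)   # Ks * u toward anchor
  # compression u = -0.2 pushes away
  f2 <- stem_anchor_force(c(0, 0, 2.2), mem, p0)
  expect_equal(f2, c(0, 0, 5.0), tolerance = 1e-9)
  # rest length: zero force
  expect_equal(stem_anchor_force(c(0, 0, 2.4), mem, p0), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("progenitor anchoring follows the quartic and cuts off at r*", {
  mem <- flat_membrane()
  u <- 0.2
  f <- daughter_anchor_force(c(0, 0, 2.4 + u), mem, p0)
  expect_equal(f[3], -p0$Kd * u * (p0$a - p0$b * u^2), tolerance = 1e-9)
  expect_equal(f[3], -0.07176, tolerance = 1e-4)  # = -Kd u (a - b u^2)
  # beyond the detachment threshold (u = 0.25 > a/b) the force is exactly zero
  expect_equal(daughter_anchor_force(c(0, 0, 2.4 + 0.25), mem, p0), c(0, 0, 0))
  expect_equal(daughter_anchor_force(c(0, 0, 2.4), mem, p0), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("division dumbbell force: natural length, overlap axis, Newton pairs", {
  mem <- flat_membrane()
  p <- p0
  st <- make_state(rbind(c(5, 5, 2.4)), "stem", mem, p)
  set.seed(3)
  st <- begin_division(st, 1L, p)
  pid <- st$pairs$id[1]
  # children coincide: force magnitude K' * l along the stored axis
  st$time <- 1.0  # l = alpha * 1 = 0.14
  f <- division_pair_force(st, pid, p)
  expect_equal(f$l, 0.14)
  expect_equal(sqrt(sum(f$F1^2)), p$Kprime * 0.14, tolerance = 1e-12)
  expect_equal(f$F1 + f$F2, c(0, 0, 0))
  axis <- c(st$pairs$ax[1], st$pairs$ay[1], st$pairs$az[1])
  expect_equal(f$F1 / sqrt(sum(f$F1^2)), axis, tolerance = 1e-9)
  # at separation equal to natural length the force vanishes
  i <- match(st$pairs$c1[1], st$id)
  st$pos[i, ] <- st$pos[i, ] + axis * 0.14
  f2 <- division_pair_force(st, pid, p)
  expect_equal(f2$F1, c(0, 0, 0), tolerance = 1e-12)
})

test_that("total force is the exact negative gradient of the total potential", {
  for (seed in c(1, 2, 3)) {
    st <- random_state(20, seed = seed, membrane = wavy_membrane())
    F <- total_forces(st, p0)
    Fn <- numerical_forces(st, p0)
    expect_equal(F, Fn, tolerance = 1e-6)
  }
  # and with an active division pair in the state
  st <- random_state(12, seed = 4)
  st$cycle[] <- 1e9
  set.seed(8)
  ids <- st$id[st$kind %in% 1:2][1]
  st <- begin_division(st, ids, p0)
  st$time <- st$time + 5   # l = 0.7
  # separate the children a little: the elastic potential is smooth away
  # from the zero-separation kink, where the stored axis takes over
  i <- match(st$pairs$c1[1], st$id)
  st$pos[i, ] <- st$pos[i, ] + c(0.08, 0.05, 0.11)
  expect_equal(total_forces(st, p0), numerical_forces(st, p0),
               tolerance = 1e-6)
})

test_that("constructed equilibria have (near) zero force", {
  mem <- flat_membrane()
  st <- make_state(rbind(c(0, 0, 2.4)), "stem", mem, p0)
  expect_lt(max(abs(total_forces(st, p0))), 1e-9)
  # isolated suprabasal cell: no anchor, no contacts
  st2 <- make_state(rbind(c(5, 5, 20)), "suprabasal", mem, p0)
  expect_equal(total_forces(st2, p0), matrix(0, 1, 3))
})

test_that("forces are invariant under rigid lateral translation (mod box)", {
  st <- random_state(25, seed = 6, membrane = wavy_membrane())
  F0 <- total_forces(st, p0)
  sh <- c(3.7, -5.1)
  st2 <- st
  st2$pos[, 1] <- (st2$pos[, 1] + sh[1]) %% st$Lx
  st2$pos[, 2] <- (st2$pos[, 2] + sh[2]) %% st$Ly
  st2$membrane$pos[, 1] <- (st2$membrane$pos[, 1] + sh[1]) %% st$Lx
  st2$membrane$pos[, 2] <- (st2$membrane$pos[, 2] + sh[2]) %% st$Ly
  expect_equal(total_forces(st2, p0), F0, tolerance = 1e-9)
})

test_that("overdamped descent: potential non-increasing, overlaps relax", {
  # jittered lattice with ~7% overlaps, mechanics only
  set.seed(10)
  g <- expand.grid(x = seq(1, 19, by = 2.6), y = seq(1, 19, by = 2.6))
  pos <- cbind(g$x + runif(nrow(g), -0.1, 0.1),
               g$y + runif(nrow(g), -0.1, 0.1),
               6 + runif(nrow(g), -0.3, 0.3))
  st <- make_state(pos, rep("suprabasal", nrow(pos)))
  V <- total_potential(st, p0)
  for (k in 1:100) {
    st <- integrate_step(st, p0)
    V2 <- total_potential(st, p0)
    expect_lte(V2, V + 1e-10)
    V <- V2
  }
  # two overlapping free cells end at separation >= contact distance
  st2 <- make_state(rbind(c(5, 5, 8), c(5, 5, 8 + 0.88 * 2 * p0$R)),
                    c("suprabasal", "suprabasal"))
  for (k in 1:2000) st2 <- integrate_step(st2, p0)
  expect_gte(abs(st2$pos[2, 3] - st2$pos[1, 3]), 2 * p0$R - 1e-6)
})

test_that("integration: closed-form single step and membrane immobility", {
  st <- make_state(rbind(c(5, 5, 8), c(5, 5, 8 + 0.9 * 2 * p0$R)),
                   c("suprabasal", "suprabasal"))
  fmag <- 3.950069
  st1 <- integrate_step(st, p0)
  expect_equal(st1$time, p0$dt)
  expect_equal(st1$pos[1, 3], 8 - p0$dt * fmag, tolerance = 1e-6)
  expect_equal(st1$pos[2, 3], 8 + 0.9 * 2 * p0$R + p0$dt * fmag,
               tolerance = 1e-6)
  # zero force: nothing moves
  stq <- make_state(rbind(c(2, 2, 30)), "cornified")
  stq1 <- integrate_step(stq, p0)
  expect_identical(stq1$pos, stq$pos)
  # membrane coordinates are bit-identical across many steps
  mem0 <- st$membrane$pos
  stm <- st
  for (k in 1:25) stm <- integrate_step(stm, p0)
  expect_identical(stm$membrane$pos, mem0)
})
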