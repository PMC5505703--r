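p0 <- model_params()

test_that("calcium excitation and decay follow the contact rule", {
  # suprabasal at 2.0 from a cornified cell (in contact), another isolated
  st <- make_state(rbind(c(5, 5, 8), c(5, 5, 10), c(15, 5, 8), c(15, 15, 2.4)),
                   c("suprabasal", "cornified", "suprabasal", "stem"))
  st$calcium <- c(0, 0, 0.5, 0.7)
  k_half <- log(2) / p0$k_ca   # dt giving one half-life
  st1 <- update_calcium(st, p0, dt = k_half)
  expect_equal(st1$calcium[1], p0$c_exc)      # excited by contact
  expect_equal(st1$calcium[2], 0)             # cornified pinned at zero
  expect_equal(st1$calcium[3], 0.25)          # halves per half-life
  expect_equal(st1$calcium[4], 0)             # basal pinned at zero
  # bounded: repeated updates never exceed c_exc or go negative
  for (k in 1:50) st1 <- update_calcium(st1, p0)
  expect_true(all(st1$calcium >= 0 & st1$calcium <= p0$c_exc))
})

test_that("calcium is top-weighted beneath the cornified layer", {
  # column: suprabasal stack with cornified cap; only the shell in contact
  # with the cap is excited
  pos <- rbind(c(5, 5, 3), c(5, 5, 5.5), c(5, 5, 8), c(5, 5, 10.5))
  st <- make_state(pos, c("suprabasal", "suprabasal", "suprabasal",
                          "cornified"))
  st <- update_calcium(st, p0)
  expect_gt(st$calcium[3], st$calcium[1])
  expect_equal(st$calcium[3], p0$c_exc)
  expect_equal(st$calcium[1], 0)
})

test_that("differentiation degree grows at the calcium-modulated rate", {
  st <- make_state(rbind(c(5, 5, 8), c(10, 5, 8), c(15, 5, 2.4)),
                   c("suprabasal", "suprabasal", "daughter"))
  st$calcium <- c(0, 1, 0)
  st1 <- update_differentiation(st, p0, dt = 2)
  expect_equal(st1$S[1], 2 * p0$s_base)                     # baseline
  expect_equal(st1$S[2], 2 * p0$s_base * (1 + p0$lam_ca))   # 4x at c = 1
  expect_equal(st1$S[3], 0)                                 # basal holds 0
  st2 <- update_differentiation(st1, p0)
  expect_true(all(st2$S >= st1$S))
})

test_that("cornification threshold is inclusive", {
  st <- make_state(rbind(c(5, 5, 8), c(10, 5, 8)),
                   c("suprabasal", "suprabasal"))
  st$S <- c(p0$S_star, 0.99 * p0$S_star)
  st1 <- cornify(st, p0)
  expect_equal(st1$kind, c(4L, 3L))
  ev <- event_log(st1)
  expect_equal(sum(ev$type == "cornify"), 1)
})

test_that("exposure rule: a capped cornified cell is protected", {
  st <- make_state(rbind(c(5, 5, 8), c(5, 5, 10.5), c(15, 5, 8)),
                   c("cornified", "cornified", "cornified"))
  ex <- ifesim:::cpp_exposed(ifesim:::state_to_cpp(st),
                             ifesim:::params_to_cpp(p0))
  expect_identical(as.logical(ex), c(FALSE, TRUE, TRUE))
  # desq_rate = 0: nothing is ever removed
  pz <- p0; pz$desq_rate <- 0
  set.seed(1)
  expect_identical(desquamate(st, pz)$id, st$id)
})

test_that("exposed cornified cells shed with mean residence 1/desq_rate", {
  # 7 x 7 isolated cornified cells (lateral spacing above contact range)
  g <- expand.grid(x = seq(0, 18, length.out = 7), y = seq(0, 18, length.out = 7))
  p <- p0; p$desq_rate <- 0.05
  dt <- 1
  set.seed(77)
  res <- c()
  for (rep in 1:10) {
    st <- make_state(cbind(g$x, g$y, 8), rep("cornified", nrow(g)))
    t <- 0
    while (length(st$id) && t < 60 / p$desq_rate) {
      t <- t + dt
      n_before <- length(st$id)
      st <- desquamate(st, p, dt)
      res <- c(res, rep(t, n_before - length(st$id)))
    }
  }
  expect_gte(length(res), 400)
  expect_equal(mean(res), 1 / p$desq_rate, tolerance = 0.12)
})

test_that("turnover shortens when differentiation accelerates", {
  # small patch, shortened horizon: doubling s_base must cut the measured
  # birth-to-shedding time (the monotonicity the calibration relies on)
  ms <- membrane_spec(Lx = 10, Ly = 10, spacing = 2, amp = 1, wavelength = 10)
  run_one <- function(s_base) {
    p <- model_params(s_base = s_base)
    set.seed(5)
    st <- seed_initial_cells(generate_membrane(ms), p, 0.2)
    st <- run_sim(st, p, days = 45, record_every_days = 0)
    mean_turnover_days(st, p, born_after_days = 12, born_before_days = 25)
  }
  t_slow <- run_one(0.0009)
  t_fast <- run_one(0.0018)
  expect_true(is.finite(t_slow) && is.finite(t_fast))
  expect_lt(t_fast, t_slow)
})

test_that("the day-unit identity of the calibration holds", {
  p <- model_params(s_base = 123)  # value irrelevant to the identity
  expect_equal((p$T_cycle + 1 / p$gamma) / 3, p$day_unit)
})
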