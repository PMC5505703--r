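p0 <- model_params()

test_that("cycle clocks advance only for reproducible cells", {
  st <- make_state(rbind(c(0, 0, 2.4), c(4, 0, 2.4), c(8, 0, 9), c(12, 0, 9)),
                   c("stem", "daughter", "suprabasal", "cornified"))
  st1 <- advance_cycle(st, p0)
  expect_equal(st1$cycle, c(p0$dt, p0$dt, 0, 0))
})

test_that("division starts follow the post-eligibility Poisson process", {
  st <- make_state(rbind(c(0, 0, 2.4)), "stem")
  st$cycle <- p0$T_cycle - p0$dt / 2
  # not yet eligible: no draw, no start even with certain hazard
  pg <- p0; pg$gamma <- 1e9
  set.seed(1)
  expect_length(sample_division_starts(st, pg), 0)
  st <- advance_cycle(st, pg)   # crosses the threshold
  set.seed(1)
  expect_identical(sample_division_starts(st, pg), 1L)
  # gamma = 0: eligible forever, never divides
  pz <- p0; pz$gamma <- 0
  set.seed(1)
  expect_length(sample_division_starts(st, pz), 0)
  # determinism: identical schedule under the same seed
  stm <- make_state(cbind(seq(0, 18, 2), 0, 2.4), rep("stem", 10))
  stm$cycle <- rep(p0$T_cycle, 10)
  ph <- p0; ph$gamma <- 50  # per-step start probability ~ 0.39
  set.seed(33); a <- sample_division_starts(stm, ph)
  set.seed(33); b <- sample_division_starts(stm, ph)
  expect_identical(a, b)
  expect_gt(length(a), 0)
})

test_that("post-eligibility waiting times are exponential with mean 1/gamma", {
  # pure sampling process: positions never move, only draws matter
  n <- 1000
  st <- make_state(cbind(runif(n, 0, 20), runif(n, 0, 20), 2.4),
                   rep("stem", n))
  st$cycle <- rep(p0$T_cycle, n)
  dt <- 0.5
  set.seed(2024)
  waits <- rep(NA_real_, n)
  t <- 0
  alive <- st
  while (anyNA(waits) && t < 30 / p0$gamma) {
    t <- t + dt
    ids <- sample_division_starts(alive, p0, dt)
    waits[ids] <- t
    if (length(ids)) {
      keep <- !(alive$id %in% ids)
      alive$id <- alive$id[keep]
      alive$kind <- alive$kind[keep]
      alive$cycle <- alive$cycle[keep]
      alive$pair <- alive$pair[keep]
      alive$pos <- alive$pos[keep, , drop = FALSE]
    }
  }
  waits <- waits[!is.na(waits)]
  expect_gte(length(waits), 995)
  expect_equal(mean(waits), 1 / p0$gamma, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate = p0$gamma))
  expect_gt(ks$p.value, 0.01)
})

test_that("begin_division: fates, counts, bookkeeping, contract errors", {
  st <- make_state(rbind(c(0, 0, 2.4), c(6, 0, 2.4)), c("stem", "daughter"))
  st$cycle <- c(200, 200)
  set.seed(4)
  st1 <- begin_division(st, 1L, p0)           # stem parent
  expect_equal(length(st1$id), 3)             # n -> n + 1
  kids <- st1$kind[st1$id %in% c(3L, 4L)]
  expect_setequal(kids, c(1L, 2L))            # exactly one stem child
  expect_true(all(st1$pos[2:3, 1] == 0))      # children at the parent position
  expect_equal(st1$cycle[2:3], c(0, 0))
  expect_equal(st1$pairs$id, 1L)
  expect_equal(sqrt(st1$pairs$ax^2 + st1$pairs$ay^2 + st1$pairs$az^2), 1,
               tolerance = 1e-12)
  # daughter parent: two daughters
  st2 <- begin_division(st1, 2L, p0)
  expect_equal(st2$kind[st2$id %in% c(5L, 6L)], c(2L, 2L))
  # a paired child cannot start a division
  expect_error(begin_division(st2, 5L, p0), "already in an active")
  expect_error(begin_division(st2, 99L, p0), "no cell")
})

test_that("division completes after exactly 2R/alpha time units", {
  expect_equal(2 * p0$R / p0$alpha, 20.0)   # closed form from the defaults
  st <- make_state(rbind(c(5, 5, 2.4)), "stem")
  set.seed(6)
  st <- begin_division(st, 1L, p0)
  pid <- st$pairs$id[1]
  st$time <- 10
  expect_equal(division_pair_force(st, pid, p0)$l, 1.4)   # l = alpha * t
  st <- grow_and_complete_pairs(st, p0)
  expect_length(st$pairs$id, 1)             # still active at t = 10
  st$time <- 20
  # separate the children so the realized axis is defined
  st$pos[1, ] <- c(5, 5, 2.4) - c(1.4, 0, 0)
  st$pos[2, ] <- c(5, 5, 2.4) + c(1.4, 0, 0)
  st <- grow_and_complete_pairs(st, p0)
  expect_length(st$pairs$id, 0)
  expect_true(all(st$pair == 0L))
  ev <- event_log(st)
  done <- ev[ev$type == "div_complete", ]
  expect_equal(nrow(done), 1)
  expect_equal(abs(c(done$v1, done$v2, done$v3)), c(1, 0, 0),
               tolerance = 1e-12)           # realized axis, unit length
  expect_error(division_pair_force(st, pid, p0), "no active")
})

test_that("detachment is exact at r* and never touches stem cells", {
  rs <- r_star(p0)
  st <- make_state(rbind(c(0, 0, 2.7), c(4, 0, 2.5), c(8, 0, 5.0)),
                   c("daughter", "daughter", "stem"))
  st1 <- update_attachment(st, p0)
  expect_equal(st1$kind, c(3L, 2L, 1L))   # 2.7 > r*; 2.5 < r*; stem immune
  expect_equal(st1$S[1], 0)
  ev <- event_log(st1)
  expect_equal(sum(ev$type == "detach"), 1)
  # boundary: conversion strictly beyond r*
  st2 <- make_state(rbind(c(0, 0, rs), c(4, 0, rs + 1e-9)),
                    c("daughter", "daughter"))
  st2 <- update_attachment(st2, p0)
  expect_equal(st2$kind, c(2L, 3L))
  # detachment is irreversible: a suprabasal cell near the membrane stays
  # suprabasal, and conversion resets the differentiation state
  st3 <- make_state(rbind(c(0, 0, 2.5), c(4, 0, 3)),
                    c("suprabasal", "daughter"))
  st3$S <- c(0.4, 0.4)
  st3 <- update_attachment(st3, p0)
  expect_equal(st3$kind, c(3L, 3L))
  expect_equal(st3$S, c(0.4, 0))   # converted cell starts S from zero
})

test_that("initial division axes are isotropic", {
  n <- 600
  st <- make_state(cbind(runif(n, 0, 20), runif(n, 0, 20), 2.4),
                   rep("stem", n))
  st$cycle <- rep(200, n)
  set.seed(99)
  axes <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    st1 <- begin_division(st, k, p0)
    q <- length(st1$pairs$id)
    axes[k, ] <- c(st1$pairs$ax[q], st1$pairs$ay[q], st1$pairs$az[q])
    st$next_id <- st$next_id   # st untouched; fresh draw per cell
  }
  rbar <- sqrt(sum(colMeans(axes)^2))
  expect_lt(rbar, 4 / sqrt(n))          # mean resultant length near 0
  expect_lt(abs(mean(axes[, 3])), 0.12) # no vertical bias
})

test_that("stem count is conserved and kind transitions form the legal DAG", {
  p <- model_params(T_cycle = 5, gamma = 0.2, alpha = 1.0, s_base = 0.05,
                    desq_rate = 1.0)
  set.seed(12)
  mem <- generate_membrane(membrane_spec())
  st <- seed_initial_cells(mem, p, 0.3)
  n_stem0 <- sum(st$kind == 1L)
  n0 <- length(st$id)
  st <- run_sim(st, p, days = 4, record_every_days = 0)  # ~30 model-time units
  expect_equal(sum(st$kind == 1L), n_stem0)
  ev <- event_log(st)
  # detachments always come from progenitors, sheds always from cornified
  expect_true(all(ev$kind[ev$type == "detach"] == 2L))
  expect_true(all(ev$kind[ev$type == "desq"] == 4L))
  # ledger conservation: final = initial + divisions - desquamations
  expect_equal(length(st$id),
               n0 + sum(ev$type == "div_start") - sum(ev$type == "desq"))
  expect_gt(sum(ev$type == "div_start"), 0)
})
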