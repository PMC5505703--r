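p0 <- model_params()

test_that("thickness: closed form for a single resting layer, flat or wavy", {
  p <- p0
  for (mem in list(flat_membrane(), wavy_membrane())) {
    set.seed(1)
    st <- seed_initial_cells(mem, p, 0.5)
    # one resting layer: top (R+Rm+R) minus surface Rm, i.e. exactly 2R,
    # when columns align with the membrane grid
    expect_equal(measure_thickness(st, p, pitch = 2), 2 * p$R,
                 tolerance = 1e-9)
  }
})

test_that("thickness rises when a cell is stacked on a column", {
  mem <- flat_membrane()
  set.seed(1)
  st <- seed_initial_cells(mem, p0, 0.5)
  th0 <- measure_thickness(st, p0, pitch = 2)
  st2 <- st
  st2$id <- c(st2$id, length(st2$id) + 1L)
  st2$kind <- c(st2$kind, 3L)
  st2$pos <- rbind(st2$pos, c(0, 0, 2.4 + 2 * p0$R))
  st2$cycle <- c(st2$cycle, 0); st2$S <- c(st2$S, 0)
  st2$calcium <- c(st2$calcium, 0); st2$birth <- c(st2$birth, 0)
  st2$pair <- c(st2$pair, 0L)
  th1 <- measure_thickness(st2, p0, pitch = 2)
  expect_equal(th1 - th0, 2 * p0$R / 100, tolerance = 1e-9)
  # no cells: undefined
  st0 <- st; st0$id <- integer(0)
  expect_error(measure_thickness(st0, p0), "no cells")
})

test_that("thickness series are normalized to 1 at their start", {
  p <- model_params(T_cycle = 5, gamma = 0.2, s_base = 0.02)
  set.seed(3)
  st <- seed_initial_cells(generate_membrane(membrane_spec()), p, 0.2)
  st <- run_sim(st, p, days = 1, record_every_days = 0.25)
  s <- thickness_series(st, p, arm = "control", seed = 3)
  expect_equal(s$ratio[1], 1)
  expect_equal(s$time_days[1], 0)
  expect_true(all(diff(s$time_days) > 0))
})

test_that("ensemble averaging: contracts and degenerate cases", {
  mk <- function(ratio, arm) {
    d <- data.frame(time_days = seq_along(ratio) - 1, thickness = ratio,
                    ratio = ratio, arm = arm, seed = 1)
    class(d) <- c("ifesim_series", class(d))
    d
  }
  a <- mk(c(1, 1.2, 1.1), "control")
  b <- mk(c(1, 1.0, 0.9), "control")
  s <- ensemble_average(list(a, b))
  expect_equal(s$mean_ratio, c(1, 1.1, 1.0))
  expect_equal(s$mean_ratio[1], 1)
  expect_equal(s$se_ratio[2], stats::sd(c(1.2, 1.0)) / sqrt(2))
  # identical members: zero spread
  s2 <- ensemble_average(list(a, a, a))
  expect_true(all(s2$se_ratio == 0))
  # single member: mean is the series, SE absent
  s1 <- ensemble_average(list(a))
  expect_equal(s1$mean_ratio, a$ratio)
  expect_true(all(is.na(s1$se_ratio)))
  # mixed arms refuse to average
  expect_error(ensemble_average(list(a, mk(c(1, 1, 1), "perturbed"))),
               "arms")
})

test_that("transient metrics on toy series", {
  mk <- function(ratio) data.frame(time_days = seq_along(ratio) - 1,
                                   mean_ratio = ratio)
  m <- transient_metrics(mk(c(1, 1.5, 1.1)))
  expect_equal(m$peak_ratio, 1.5)
  expect_equal(m$time_to_peak_days, 1)
  expect_equal(m$final_ratio, 1.1)
  expect_equal(m$recovery_fraction, 0.8)
  flat <- transient_metrics(mk(c(1, 1, 1)))
  expect_equal(flat$peak_ratio, 1)
  expect_true(is.na(flat$recovery_fraction))
})

test_that("division axes classify against the local membrane plane", {
  mem <- flat_membrane()
  mk_events <- function(axes) {
    n <- nrow(axes)
    data.frame(type = factor(rep("div_complete", n),
                             levels = ifesim:::EV_LEVELS),
               time = 1, id1 = 1, id2 = 2, id3 = 0, kind = 1,
               x = 5, y = 5, z = 2.4,
               v1 = axes[, 1], v2 = axes[, 2], v3 = axes[, 3])
  }
  # perpendicular to a flat membrane: 90 degrees, asymmetric
  ev <- mk_events(rbind(c(0, 0, 1)))
  s <- division_axis_stats(ev, mem)
  expect_equal(s$angles_deg, 90)
  expect_equal(s$percent_ACD, 100)
  # in the membrane plane: 0 degrees, symmetric
  s2 <- division_axis_stats(mk_events(rbind(c(1, 0, 0))), mem)
  expect_equal(s2$angles_deg, 0)
  expect_equal(s2$percent_SCD, 100)
  # threshold dichotomy and the exact-100 convention
  th <- 45 * pi / 180
  axes <- rbind(c(cos(th - 0.02), 0, sin(th - 0.02)),
                c(cos(th + 0.02), 0, sin(th + 0.02)),
                c(0, 0, 1))
  s3 <- division_axis_stats(mk_events(axes), mem)
  expect_equal(s3$percent_ACD, 100 * 2 / 3)
  expect_identical(s3$percent_ACD + s3$percent_SCD, 100)
  # no events: absent
  s4 <- division_axis_stats(mk_events(rbind(c(0, 0, 1)))[0, ], mem)
  expect_true(is.na(s4$percent_ACD))
})

test_that("protocol fork is pure: identical arms when Kd is unchanged", {
  ms <- membrane_spec(Lx = 10, Ly = 10, spacing = 2, amp = 1, wavelength = 10)
  p <- model_params(T_cycle = 20, gamma = 0.05)
  runs <- run_protocol(p, ms, seeds = 1, burn_days = 2, post_days = 2,
                       Kd_perturbed = p$Kd)   # no actual perturbation
  expect_identical(runs[[1]]$control$thickness,
                   runs[[1]]$perturbed$thickness)
  expect_identical(runs[[1]]$control_state$pos,
                   runs[[1]]$perturbed_state$pos)
  expect_equal(runs[[1]]$control$ratio[1], 1)
})
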