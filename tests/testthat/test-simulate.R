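test_that("fixed-step reference reproduces closed-form decays", {
  # no selection: stage-0 B-cells decay at d_B
  p <- no_selection_params()
  r <- rk4_reference(p, gc_seeding(), dt = 0.01, t_end = 1)
  expect_equal(unname(r$states[nrow(r$states), "B1_0"]), 50 * exp(-0.8),
               tolerance = 1e-9)

  # Tfh-only: pure exponential at d_G
  r2 <- rk4_reference(p, gc_seeding(B1_0 = 0, B2_0 = 0),
                      dt = 0.05, t_end = 10)
  expect_equal(unname(r2$states[nrow(r2$states), "G1"]), 5000 * exp(-0.1),
               tolerance = 1e-9)

  expect_error(rk4_reference(p, gc_seeding(), dt = -1, t_end = 1), "dt")
})

test_that("halving the RK4 step shrinks the error fourth-order", {
  p <- toy_params(2)
  sd <- gc_seeding()
  final_at <- function(dt) {
    r <- rk4_reference(p, sd, dt = dt, t_end = 2, store_every = 1e6)
    r$states[nrow(r$states), ]
  }
  ref <- final_at(0.0025)
  err <- function(dt) max(abs(final_at(dt) - ref))
  ratio <- err(0.04) / err(0.02)
  expect_gt(ratio, 10)
  expect_lt(ratio, 25)
})

test_that("adaptive and fixed-step integrations agree componentwise", {
  for (n in c(2L, 8L)) {
    p <- baseline_params(n)
    traj <- gc_simulate(p, gc_seeding(), solver_settings(t_max = 30))
    r <- rk4_reference(p, gc_seeding(), dt = 1e-3, t_end = 30,
                       store_every = 1000L)
    # the toy n = 2 center collapses within about a week, so the overlap of
    # stored day marks is short there
    tt <- common_times(traj$times, r$times)
    expect_gt(length(tt), 5)
    ia <- match(tt, round(traj$times, 6))
    ib <- match(tt, round(r$times, 6))
    expect_lt(rel_diff(traj$states[ia, ], r$states[ib, ]), 1e-5)
  }
})

test_that("trajectories satisfy structural invariants", {
  p <- baseline_params(8)
  traj <- gc_simulate(p)

  expect_identical(traj$times[1], 0)
  expect_true(all(diff(traj$times) > 0))
  # plasma pools have no loss term
  expect_true(all(diff(traj$states[, "P1"]) >= -1e-8))
  expect_true(all(diff(traj$states[, "P2"]) >= -1e-8))
  # built-in conservation check
  expect_lt(conservation_residual(traj), 1e-6)
  # no materially negative states
  expect_gt(min(traj$states), -1e-3)
})

test_that("conservation residual flags a corrupted trajectory", {
  p <- baseline_params(4)
  traj <- gc_simulate(p, gc_seeding(), toy_settings())
  expect_lt(conservation_residual(traj), 1e-6)

  # eta = f = 0: H stays zero, G is a pure exponential
  p0 <- gc_parameters(n = 4, eta = 0, f = 0)
  traj0 <- gc_simulate(p0, gc_seeding(), toy_settings())
  expect_lt(conservation_residual(traj0), 1e-8)

  # negative control: inject a 1% perturbation into the available pool
  bad <- traj
  k <- seq(11, length(bad$times))
  bad$states[k, "G1"] <- bad$states[k, "G1"] * 1.01
  expect_gt(conservation_residual(bad), 1e-3)
})

test_that("termination is detected where total B-cells cross the floor", {
  # no selection: total B = 100 exp(-0.8 t) crosses 1 at ln(100)/0.8
  p <- no_selection_params()
  traj <- gc_simulate(p, gc_seeding(), toy_settings(t_max = 20))
  expect_equal(traj$termination_time, log(100) / 0.8, tolerance = 1e-3)
  expect_equal(detect_termination(traj), log(100) / 0.8, tolerance = 1e-3)

  # baseline n=8 germinal center lives three weeks and a bit
  traj8 <- gc_simulate(baseline_params(8))
  expect_gt(traj8$termination_time, 22)
  expect_lt(traj8$termination_time, 25)

  # a horizon that ends before the collapse: sentinel + warning
  early <- gc_simulate(baseline_params(8), gc_seeding(),
                       solver_settings(t_max = 5))
  expect_false(early$terminated)
  expect_warning(tt <- detect_termination(early), "never fell below")
  expect_true(is.na(tt))

  expect_error(detect_termination(traj8, floor = -1), "positive")
})

test_that("raising the B-cell death rate never delays termination", {
  times <- vapply(c(0.7, 0.8, 0.9), function(db) {
    gc_simulate(gc_parameters(n = 8, d_B = db))$termination_time
  }, numeric(1))
  expect_true(all(diff(times) <= 0))
})

test_that("outcome summary classifies clonality from final plasma counts", {
  p <- baseline_params(8)
  traj <- gc_simulate(p)
  out <- summarize_run(traj)
  # comparable plasma output from both clones at sigma_c = 0.5 sigma
  expect_identical(out$clonality, "biclonal")
  expect_true(out$success_1 && out$success_2)
  expect_lt(abs(out$P1_final - out$P2_final) /
              max(out$P1_final, out$P2_final), 0.05)

  # threshold semantics on a synthetic trajectory
  fake <- traj
  fake$states[nrow(fake$states), c("P1", "P2")] <- c(150, 50)
  expect_identical(summarize_run(fake)$clonality, "monoclonal_broad")
  fake$states[nrow(fake$states), c("P1", "P2")] <- c(50, 150)
  expect_identical(summarize_run(fake)$clonality, "monoclonal_specific")
  fake$states[nrow(fake$states), c("P1", "P2")] <- c(150, 150)
  expect_identical(summarize_run(fake)$clonality, "biclonal")
  fake$states[nrow(fake$states), c("P1", "P2")] <- c(1, 2)
  expect_identical(summarize_run(fake)$clonality, "none")
})

test_that("tidy export covers every variable at every stored time", {
  p <- toy_params(2)
  traj <- gc_simulate(p, gc_seeding(), toy_settings(t_max = 5))
  df <- as.data.frame(traj)
  expect_identical(nrow(df), length(traj$times) * ncol(traj$states))
  expect_setequal(unique(df$variable), c("G", "H", "B", "P"))
  expect_setequal(unique(df$clone), c(1L, 2L))
  expect_identical(sort(unique(df$stage[df$variable == "B"])), 0:2)
  expect_true(all(is.na(df$stage[df$variable != "B"])))
  # round-trip one cell
  expect_equal(df$value[df$variable == "B" & df$clone == 1 &
                          df$stage == 0 & df$time == 0], 50)

  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(df))
})
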