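test_that("selection-ratio sweep brackets the bisection threshold", {
  p <- baseline_params(8)
  grid <- seq(0.20, 0.30, by = 0.01)
  sweep <- sweep_sigma_ratio(p, ratios = grid)
  expect_identical(names(sweep),
                   c("ratio", "P1_final", "P2_final", "clonality",
                     "termination_time"))
  succ <- sweep$P1_final > 100
  expect_true(any(succ) && any(!succ))
  last_fail <- max(grid[!succ])
  first_succ <- min(grid[succ])

  th <- find_ratio_threshold(p, clone = 1, bracket = c(0.05, 0.5),
                             tol = 0.005)
  expect_gte(th, last_fail)
  expect_lte(th, first_succ)

  expect_error(sweep_sigma_ratio(p, ratios = c(0.5, 0.3)), "increasing")
  expect_error(sweep_sigma_ratio(p, ratios = c(-0.1, 0.5)), "positive")
  expect_error(find_ratio_threshold(p, bracket = c(0.4, 0.5)),
               "does not change")
})

test_that("sweeps are deterministic", {
  p <- baseline_params(8)
  a <- sweep_sigma_ratio(p, ratios = c(0.3, 0.6))
  b <- sweep_sigma_ratio(p, ratios = c(0.3, 0.6))
  expect_identical(a, b)
})

test_that("seeding fractions swap outcomes under the symmetry limit", {
  # eta = f = 0 and sigma_c = 0.5 sigma make the two clones exchangeable:
  # seeding x of clone 1 versus x of clone 2 must swap (P1, P2)
  p <- gc_parameters(n = 8, eta = 0, f = 0)
  sw <- sweep_seeding(p, fractions = c(0.3, 0.7))
  expect_equal(sw$P1_final[1], sw$P2_final[2], tolerance = 1e-6)
  expect_equal(sw$P2_final[1], sw$P1_final[2], tolerance = 1e-6)

  # equal seeding in the symmetry limit balances the plasma output exactly
  th <- find_seeding_threshold(p, criterion = "dominance",
                               bracket = c(0.2, 0.8), tol = 0.002)
  expect_equal(th, 0.5, tolerance = 0.005)

  expect_error(sweep_seeding(p, fractions = c(0, 0.5)), "inside")
  expect_error(sweep_seeding(p, fractions = 0.5, total_B = -1), "positive")
})

test_that("a biclonal band exists at intermediate selection ratios for n = 50", {
  out <- summarize_run(gc_simulate(baseline_params(50)))
  expect_identical(out$clonality, "biclonal")
})

test_that("forward-mutation sweep respects the simplex and reports deviations", {
  p <- toy_params(3)
  sw <- sweep_forward_mutation(p, p_grid = c(0.10, 0.15, 0.20),
                               settings = toy_settings(t_max = 40))
  expect_identical(names(sw),
                   c("p", "P1_final", "P2_final", "abs_diff", "clonality",
                     "termination_time"))
  expect_equal(sw$abs_diff, abs(sw$P1_final - sw$P2_final))
  # p = 0.20 with q = 0.5, d = 0.3 leaves zero backward probability: valid
  expect_false(any(is.na(sw$P1_final)))

  expect_error(sweep_forward_mutation(p, p_grid = c(0.1, 0.25)), "backward")
  expect_error(sweep_forward_mutation(p, p_grid = c(0.2, 0.1)), "increasing")
})

test_that("pre-plasma stage trace tracks the gateway stage of each clone", {
  p <- baseline_params(8)
  tr <- prepl_stage_trace(p, gc_seeding())
  expect_setequal(unique(tr$clone), c(1L, 2L))
  expect_true(all(tr$selection_rate >= 0))
  # stage n_c - 1 starts empty and is populated during the reaction
  first <- tr$cells[tr$time == 0]
  expect_equal(first, c(0, 0))
  expect_gt(max(tr$cells), 1)

  # selection rates: clone 1 reads both families, clone 2 only family 2
  t0 <- tr[tr$time == 0, ]
  expect_equal(t0$selection_rate[t0$clone == 1], p$sigma_c * 10000)
  expect_equal(t0$selection_rate[t0$clone == 2], p$sigma * 5000)

  # an unseeded clone never populates its gateway stage
  tr0 <- prepl_stage_trace(p, gc_seeding(B1_0 = 0, B2_0 = 100))
  expect_equal(max(abs(tr0$cells[tr0$clone == 1])), 0)
})
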