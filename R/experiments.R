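# Regime-map experiments: sweeps over the broadly reactive selection ratio,
# the initial seeding bias, and the forward-mutation probability, plus
# bisection search for the boundaries between plasma-cell outcome regimes.

# rebuild a gc_parameters object with selected fields replaced
modify_params <- function(params, ...) {
  upd <- list(...)
  pick <- function(nm) upd[[nm]] %||% params[[nm]]  # exact, no partial match
  gc_parameters(
    n = params$n,
    sigma = pick("sigma"),
    sigma_c = pick("sigma_c"),
    kernel = pick("kernel"),
    eta = pick("eta"),
    f = pick("f"),
    d_G = pick("d_G"),
    d_B = pick("d_B"),
    kappa = pick("kappa"),
    alpha_base = pick("alpha_base"),
    n_c = pick("n_c")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_outcome <- function(params, seeding, settings, success_threshold = 100) {
  summarize_run(gc_simulate(params, seeding, settings), success_threshold)
}

outcome_row <- function(out) {
  data.frame(P1_final = out$P1_final, P2_final = out$P2_final,
             clonality = out$clonality,
             termination_time = out$termination_time)
}

# bisection on a boolean indicator; the indicator must differ at the two
# bracket endpoints, and the invariant f(lo) != f(hi) is maintained
bisect_indicator <- function(f, bracket, tol) {
  lo <- bracket[1L]; hi <- bracket[2L]
  if (!(is.finite(lo) && is.finite(hi) && lo < hi)) {
    stop("`bracket` must be an increasing pair of finite values",
         call. = FALSE)
  }
  flo <- f(lo); fhi <- f(hi)
  if (flo == fhi) {
    stop("indicator does not change across the bracket [", lo, ", ", hi,
         "]; no boundary to bisect", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) == fhi) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Sweep the broadly reactive selection ratio
#'
#' Runs the model once per value of `sigma_c / sigma`, holding the
#' strain-specific rate `sigma` and all other parameters fixed, and records
#' the final plasma output of both clones.
#'
#' @param params A [gc_parameters()] object (its `sigma_c` is overridden by
#'   the grid).
#' @param ratios Strictly increasing grid of `sigma_c / sigma` values in
#'   (0, 1]. The default mirrors the regime-map panels: 0.02 to 1 in steps
#'   of 0.02.
#' @param seeding A [gc_seeding()] object (equal seeding by default).
#' @param settings A [solver_settings()] object.
#' @param success_threshold Plasma cells defining clone success.
#' @return A data frame with one row per ratio: `ratio`, `P1_final`,
#'   `P2_final`, `clonality`, `termination_time`.
#' @export
sweep_sigma_ratio <- function(params, ratios = seq(0.02, 1, by = 0.02),
                              seeding = gc_seeding(),
                              settings = solver_settings(),
                              success_threshold = 100) {
  if (any(ratios <= 0)) {
    stop("all `ratios` must be positive", call. = FALSE)
  }
  if (is.unsorted(ratios, strictly = TRUE)) {
    stop("`ratios` must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(ratios, function(r) {
    pr <- modify_params(params, sigma_c = r * params$sigma)
    outcome_row(run_outcome(pr, seeding, settings, success_threshold))
  })
  cbind(ratio = ratios, do.call(rbind, rows))
}

#' Critical selection ratio for clone success
#'
#' Bisects `sigma_c / sigma` on the indicator "final plasma count of `clone`
#' exceeds `success_threshold`" to locate a regime boundary: the onset of
#' broadly reactive plasma production (clone 1) or the extinction of
#' strain-specific production (clone 2).
#'
#' @inheritParams sweep_sigma_ratio
#' @param clone Which plasma population the indicator reads (1 or 2).
#' @param bracket Ratio interval `(lo, hi)`; the success status must differ
#'   at the two endpoints.
#' @param tol Bisection width at which to stop (default 0.005).
#' @return The boundary ratio (midpoint of the final bracket).
#' @export
find_ratio_threshold <- function(params, clone = 1, bracket = c(0.05, 0.5),
                                 tol = 0.005, seeding = gc_seeding(),
                                 settings = solver_settings(),
                                 success_threshold = 100) {
  stopifnot(clone %in% c(1, 2))
  field <- if (clone == 1) "P1_final" else "P2_final"
  f <- function(r) {
    pr <- modify_params(params, sigma_c = r * params$sigma)
    run_outcome(pr, seeding, settings)[[field]] > success_threshold
  }
  bisect_indicator(f, bracket, tol)
}

#' Sweep the initial clonal composition
#'
#' Distributes a fixed total of founder B-cells between the two clones
#' according to each fraction `B1(0)/Bt(0)` and records the final plasma
#' output. Tfh seeding is held equal between families.
#'
#' @inheritParams sweep_sigma_ratio
#' @param fractions Strictly increasing grid of clone-1 seeding fractions in
#'   the open interval (0, 1).
#' @param total_B Total founder B-cells split between the clones
#'   (default 100).
#' @param G1_0,G2_0 Available Tfh seeding per family (cells/ml).
#' @return A data frame with one row per fraction: `fraction`, `P1_final`,
#'   `P2_final`, `clonality`, `termination_time`.
#' @export
sweep_seeding <- function(params, fractions = seq(0.05, 0.95, by = 0.05),
                          total_B = 100, G1_0 = 5000, G2_0 = 5000,
                          settings = solver_settings(),
                          success_threshold = 100) {
  if (total_B <= 0) stop("`total_B` must be positive", call. = FALSE)
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("all `fractions` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("`fractions` must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(fractions, function(x) {
    sd <- gc_seeding(B1_0 = x * total_B, B2_0 = (1 - x) * total_B,
                     G1_0 = G1_0, G2_0 = G2_0)
    outcome_row(run_outcome(params, sd, settings, success_threshold))
  })
  cbind(fraction = fractions, do.call(rbind, rows))
}

#' Critical seeding fraction for dominance or clonality change
#'
#' Bisects the clone-1 seeding fraction on one of two indicators:
#' `"dominance"` (final P1 strictly exceeds final P2) or `"clonality"` (both
#' clones succeed, i.e. the germinal center is biclonal). The dominance
#' criterion locates where the broadly reactive plasma population takes over;
#' the clonality criterion locates where one clone's plasma output drops
#' below the success threshold.
#'
#' @inheritParams sweep_seeding
#' @param criterion `"dominance"` or `"clonality"`.
#' @param bracket Fraction interval across which the indicator changes.
#' @param tol Bisection width at which to stop (default 0.002).
#' @return The boundary fraction (midpoint of the final bracket).
#' @export
find_seeding_threshold <- function(params,
                                   criterion = c("dominance", "clonality"),
                                   bracket = c(0.001, 0.999), tol = 0.002,
                                   total_B = 100, G1_0 = 5000, G2_0 = 5000,
                                   settings = solver_settings(),
                                   success_threshold = 100) {
  criterion <- match.arg(criterion)
  f <- function(x) {
    sd <- gc_seeding(B1_0 = x * total_B, B2_0 = (1 - x) * total_B,
                     G1_0 = G1_0, G2_0 = G2_0)
    out <- run_outcome(params, sd, settings, success_threshold)
    if (criterion == "dominance") out$P1_final > out$P2_final
    else out$clonality == "biclonal"
  }
  bisect_indicator(f, bracket, tol)
}

#' Sweep the forward-mutation probability
#'
#' Runs the model once per value of `p`, holding the neutral and deleterious
#' probabilities fixed (the backward probability absorbs the change), and
#' records the final plasma output of both clones and their absolute
#' difference.
#'
#' @inheritParams sweep_sigma_ratio
#' @param p_grid Strictly increasing grid of forward-mutation probabilities.
#'   Every value must keep the backward probability
#'   `1 - p - q - d_del` non-negative. The default spans 0.10 to 0.20 in
#'   steps of 0.005.
#' @return A data frame with one row per `p`: `p`, `P1_final`, `P2_final`,
#'   `abs_diff`, `clonality`, `termination_time`.
#' @export
sweep_forward_mutation <- function(params,
                                   p_grid = seq(0.10, 0.20, by = 0.005),
                                   seeding = gc_seeding(),
                                   settings = solver_settings(),
                                   success_threshold = 100) {
  if (is.unsorted(p_grid, strictly = TRUE)) {
    stop("`p_grid` must be strictly increasing", call. = FALSE)
  }
  kr <- params$kernel
  if (any(p_grid + kr$q + kr$d_del > 1 + 1e-12)) {
    stop("grid contains p values for which the backward probability ",
         "1 - p - q - d_del would be negative", call. = FALSE)
  }
  rows <- lapply(p_grid, function(p) {
    pr <- modify_params(params,
                        kernel = mutation_kernel(p, kr$q, kr$d_del))
    outcome_row(run_outcome(pr, seeding, settings, success_threshold))
  })
  res <- cbind(p = p_grid, do.call(rbind, rows))
  res$abs_diff <- abs(res$P1_final - res$P2_final)
  res[, c("p", "P1_final", "P2_final", "abs_diff", "clonality",
          "termination_time")]
}

#' Time course of the last pre-plasma stage
#'
#' Extracts the stage `n_c - 1` population of each clone — the gateway stage
#' whose cells are one productive mutation away from plasma output — together
#' with each clone's instantaneous total selection rate
#' (`sigma_c (G1 + G2)` for clone 1, `sigma G2` for clone 2), for plotting
#' against time or against selection.
#'
#' @inheritParams sweep_sigma_ratio
#' @return A data frame with columns `time`, `clone`, `cells` (the
#'   stage `n_c - 1` population) and `selection_rate` (day^-1).
#' @export
prepl_stage_trace <- function(params, seeding = gc_seeding(),
                              settings = solver_settings()) {
  traj <- gc_simulate(params, seeding, settings)
  idx <- state_index(params$n)
  stage_col <- function(j) idx$B(j)[params$n_c]  # 1-based: stage n_c - 1
  g1 <- traj$states[, idx$G(1)]
  g2 <- traj$states[, idx$G(2)]
  rbind(
    data.frame(time = traj$times, clone = 1L,
               cells = traj$states[, stage_col(1)],
               selection_rate = params$sigma_c * (g1 + g2)),
    data.frame(time = traj$times, clone = 2L,
               cells = traj$states[, stage_col(2)],
               selection_rate = params$sigma * g2)
  )
}
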