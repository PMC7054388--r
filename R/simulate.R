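#' Integrator settings
#'
#' @param rel_tol,abs_tol Relative and absolute tolerances of the adaptive
#'   integrator. The tight defaults (1e-8 / 1e-10) keep the bisection-based
#'   regime boundaries insensitive to solver error at the 1e-3 level.
#' @param t_max Safety horizon in days. Plasma pools plateau once the B-cell
#'   population collapses, so 250 days comfortably covers every regime.
#' @param termination_floor Total B-cell count below which the germinal
#'   center is considered terminated (default 1 cell).
#' @param store_dt Spacing of stored output time points (days).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10, t_max = 250,
                            termination_floor = 1, store_dt = 0.1) {
  v <- as.numeric(c(rel_tol = rel_tol, abs_tol = abs_tol, t_max = t_max,
                    termination_floor = termination_floor,
                    store_dt = store_dt))
  names(v) <- c("rel_tol", "abs_tol", "t_max", "termination_floor",
                "store_dt")
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("all solver settings must be finite and positive", call. = FALSE)
  }
  structure(as.list(v), class = "solver_settings")
}

new_trajectory <- function(times, states, params, seeding, settings,
                           termination_time = NA_real_) {
  structure(
    list(times = times, states = states, params = params, seeding = seeding,
         settings = settings, termination_time = termination_time,
         terminated = is.finite(termination_time)),
    class = "gc_trajectory"
  )
}

#' @export
print.gc_trajectory <- function(x, ...) {
  cat("<gc_trajectory>  n =", x$params$n, " |", length(x$times),
      "time points over", format(max(x$times)), "days\n")
  if (x$terminated) {
    cat("  germinal center terminated at",
        format(round(x$termination_time, 3)), "days\n")
  } else {
    cat("  no termination detected within the horizon\n")
  }
  fin <- final_state(x)
  cat("  final plasma: P1 =", format(round(fin[["P1"]], 1)),
      " P2 =", format(round(fin[["P2"]], 1)), "\n")
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj A `gc_trajectory`.
#' @return Named numeric state vector at the last stored time point.
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "gc_trajectory"))
  traj$states[nrow(traj$states), ]
}

# total live B-cells (both clones, all stages) at every stored time
total_b_cells <- function(traj) {
  idx <- state_index(traj$params$n)
  rowSums(traj$states[, c(idx$B(1), idx$B(2)), drop = FALSE])
}

#' Simulate the germinal center reaction
#'
#' Integrates the model with an adaptive multistep solver
#' ([deSolve::ode()], method `lsoda`) from the seeded initial state until
#' either the germinal center terminates (total B-cells drop below
#' `settings$termination_floor` after the first day) or `settings$t_max` is
#' reached. The Tfh conservation law `G_j + H_j = G_j(0) exp(-d_G t)` is
#' verified on every stored point and an integration whose residual exceeds
#' 1e-6 relative is rejected as an error.
#'
#' @param params A [gc_parameters()] object.
#' @param seeding A [gc_seeding()] object.
#' @param settings A [solver_settings()] object.
#' @return A `gc_trajectory`: stored times, the state matrix (one named
#'   column per variable), the inputs, and the detected termination time.
#' @examples
#' \donttest{
#' traj <- gc_simulate(gc_parameters(n = 8))
#' traj$termination_time   # about 24 days at baseline
#' }
#' @export
gc_simulate <- function(params, seeding = gc_seeding(),
                        settings = solver_settings()) {
  stopifnot(inherits(params, "gc_parameters"),
            inherits(seeding, "gc_seeding"),
            inherits(settings, "solver_settings"))
  y0 <- initial_state(params, seeding)
  idx <- state_index(params$n)
  bidx <- c(idx$B(1), idx$B(2))
  floor_ <- settings$termination_floor

  # root: total B-cells cross the termination floor; masked during the first
  # day so the seeding transient cannot trigger it
  rootfun <- function(t, y, p) {
    if (t <= 1) return(1)
    sum(y[bidx]) - floor_
  }

  times <- unique(c(seq(0, settings$t_max, by = settings$store_dt),
                    settings$t_max))
  sol <- deSolve::ode(
    y = unname(y0), times = times, func = gc_rhs, parms = .with_alpha(params),
    method = "lsoda", rtol = settings$rel_tol, atol = settings$abs_tol,
    rootfunc = rootfun
  )
  diagn <- attributes(sol)
  if (!is.null(diagn$istate) && diagn$istate[1L] < 0) {
    stop("integration failed at t = ", max(sol[, 1L]),
         " (lsoda istate ", diagn$istate[1L], ")", call. = FALSE)
  }

  states <- sol[, -1L, drop = FALSE]
  colnames(states) <- state_names(params$n)
  troot <- diagn$troot
  termination <- if (!is.null(troot) && length(troot)) troot[1L] else NA_real_

  traj <- new_trajectory(sol[, 1L], states, params, seeding, settings,
                         termination)

  # scale-aware negativity guard: tiny undershoots are integrator noise,
  # anything larger means the run cannot be trusted
  neg_tol <- settings$abs_tol + settings$rel_tol * max(abs(states))
  if (min(states) < -100 * neg_tol) {
    stop("integration produced substantially negative state values (min ",
         signif(min(states), 3), ")", call. = FALSE)
  }

  resid <- conservation_residual(traj)
  if (resid > 1e-6) {
    stop("Tfh conservation residual ", signif(resid, 3),
         " exceeds 1e-6; integration rejected", call. = FALSE)
  }
  traj
}

#' Fixed-step classical Runge-Kutta reference trajectory
#'
#' Independent fourth-order fixed-step integration of the same right-hand
#' side, used to cross-validate the adaptive solver. The stepping loop is
#' self-contained (it shares only [gc_derivative()]'s maths with
#' [gc_simulate()]).
#'
#' @param params A [gc_parameters()] object.
#' @param seeding A [gc_seeding()] object.
#' @param dt Step size in days.
#' @param t_end Integration horizon in days.
#' @param store_every Keep every k-th step in the returned trajectory
#'   (the initial and final states are always kept).
#' @return A `gc_trajectory` (no termination detection is applied).
#' @export
rk4_reference <- function(params, seeding = gc_seeding(), dt, t_end,
                          store_every = 1L) {
  stopifnot(inherits(params, "gc_parameters"),
            inherits(seeding, "gc_seeding"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive step size", call. = FALSE)
  }
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  pr <- .with_alpha(params)
  y <- unname(initial_state(params, seeding))
  n_steps <- as.integer(ceiling(t_end / dt))
  store_every <- as.integer(store_every)
  out_t <- numeric(n_steps %/% store_every + 2L)
  out_y <- matrix(NA_real_, length(out_t), length(y))
  out_t[1L] <- 0; out_y[1L, ] <- y
  row <- 2L
  t <- 0
  for (s in seq_len(n_steps)) {
    h <- min(dt, t_end - t)
    k1 <- gc_rhs(t, y, pr)[[1L]]
    k2 <- gc_rhs(t + h / 2, y + h / 2 * k1, pr)[[1L]]
    k3 <- gc_rhs(t + h / 2, y + h / 2 * k2, pr)[[1L]]
    k4 <- gc_rhs(t + h, y + h * k3, pr)[[1L]]
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (s %% store_every == 0L || s == n_steps) {
      out_t[row] <- t
      out_y[row, ] <- y
      row <- row + 1L
    }
  }
  out_t <- out_t[seq_len(row - 1L)]
  out_y <- out_y[seq_len(row - 1L), , drop = FALSE]
  colnames(out_y) <- state_names(params$n)
  settings <- solver_settings(t_max = t_end)
  new_trajectory(out_t, out_y, params, seeding, settings)
}

#' Detect germinal center termination
#'
#' Finds the first time, after the initial seeding transient (t > 1 day), at
#' which the total B-cell population of both clones falls below `floor`,
#' interpolating linearly between stored time points.
#'
#' @param traj A `gc_trajectory`.
#' @param floor Total B-cell cutoff in cells (defaults to the trajectory's
#'   `termination_floor`).
#' @return Termination time in days, or `NA` with a warning if the population
#'   never drops below `floor` within the stored horizon.
#' @export
detect_termination <- function(traj, floor = traj$settings$termination_floor) {
  stopifnot(inherits(traj, "gc_trajectory"))
  if (!is.finite(floor) || floor <= 0) {
    stop("`floor` must be a positive cell count", call. = FALSE)
  }
  tot <- total_b_cells(traj)
  tt <- traj$times
  ok <- tt > 1
  # a root-stopped trajectory ends exactly on the floor; count that as below
  below <- ok & (tot < floor | abs(tot - floor) <= 1e-6 * floor)
  if (!any(below)) {
    warning("total B-cell population never fell below ", floor,
            " cells within the trajectory horizon")
    return(NA_real_)
  }
  i <- which(below)[1L]
  if (i == 1L || tot[i - 1L] < floor) return(tt[i])
  # linear interpolation across the crossing interval
  t0 <- tt[i - 1L]; t1 <- tt[i]
  y0 <- tot[i - 1L]; y1 <- tot[i]
  t0 + (floor - y0) * (t1 - t0) / (y1 - y0)
}

#' Maximum Tfh conservation-law violation
#'
#' The model moves Tfh cells between the available (`G`) and unavailable
#' (`H`) pools without creating or destroying them, so each family satisfies
#' `G_j(t) + H_j(t) = (G_j(0) + H_j(0)) exp(-d_G t)` exactly. This function
#' returns the largest relative deviation from that closed form over all
#' stored time points and both families; it is the package's built-in
#' integration quality check.
#'
#' @param traj A `gc_trajectory`.
#' @return Maximum relative deviation (dimensionless).
#' @export
conservation_residual <- function(traj) {
  stopifnot(inherits(traj, "gc_trajectory"))
  idx <- state_index(traj$params$n)
  decay <- exp(-traj$params$d_G * traj$times)
  worst <- 0
  for (j in 1:2) {
    tot <- traj$states[, idx$G(j)] + traj$states[, idx$H(j)]
    tot0 <- tot[1L]
    if (tot0 == 0) next
    worst <- max(worst, max(abs(tot - tot0 * decay)) / tot0)
  }
  worst
}

#' Summarize a germinal center run
#'
#' Reads the final plasma counts (plasma pools have no loss term, so the
#' final value is the maximum), classifies each clone as successful if it
#' produced more than `success_threshold` plasma cells, and labels the run's
#' clonality. Tiny negative values left by the integrator are clipped to 0.
#'
#' @param traj A `gc_trajectory`.
#' @param success_threshold Plasma cells required for a clone to count as
#'   successful (default 100).
#' @return An object of class `gc_outcome` with fields `P1_final`,
#'   `P2_final`, `termination_time`, `success_1`, `success_2` and `clonality`
#'   (one of `"none"`, `"monoclonal_broad"`, `"monoclonal_specific"`,
#'   `"biclonal"`).
#' @export
summarize_run <- function(traj, success_threshold = 100) {
  stopifnot(inherits(traj, "gc_trajectory"))
  if (length(traj$times) == 0L) stop("empty trajectory", call. = FALSE)
  fin <- final_state(traj)
  clip <- function(x) if (x < 0) 0 else x
  p1 <- clip(fin[["P1"]])
  p2 <- clip(fin[["P2"]])
  s1 <- p1 > success_threshold
  s2 <- p2 > success_threshold
  clonality <- if (s1 && s2) "biclonal"
  else if (s1) "monoclonal_broad"
  else if (s2) "monoclonal_specific"
  else "none"
  structure(
    list(P1_final = p1, P2_final = p2,
         termination_time = traj$termination_time,
         success_1 = s1, success_2 = s2, clonality = clonality,
         success_threshold = success_threshold),
    class = "gc_outcome"
  )
}

#' @export
print.gc_outcome <- function(x, ...) {
  cat("<gc_outcome> ", x$clonality, "\n")
  cat("  P1 (broadly reactive) =", format(round(x$P1_final, 1)),
      if (x$success_1) "[success]" else "", "\n")
  cat("  P2 (strain-specific)  =", format(round(x$P2_final, 1)),
      if (x$success_2) "[success]" else "", "\n")
  cat("  termination:",
      if (is.finite(x$termination_time))
        paste(format(round(x$termination_time, 2)), "days")
      else "not reached", "\n")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x A `gc_trajectory`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return A data frame with columns `time`, `variable` (`G`, `H`, `B`, `P`),
#'   `clone` (1 or 2), `stage` (mutational stage for `B` rows, `NA`
#'   otherwise) and `value`.
#' @export
as.data.frame.gc_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  n <- x$params$n
  nm <- colnames(x$states)
  variable <- sub("^([GHBP]).*", "\\1", nm)
  clone <- as.integer(sub("^[GHBP]([12]).*", "\\1", nm))
  stage <- rep(NA_integer_, length(nm))
  isb <- variable == "B"
  stage[isb] <- as.integer(sub("^B[12]_", "", nm[isb]))
  k <- length(x$times)
  data.frame(
    time = rep(x$times, times = length(nm)),
    variable = rep(variable, each = k),
    clone = rep(clone, each = k),
    stage = rep(stage, each = k),
    value = as.vector(x$states)
  )
}

#' Write a trajectory to a tidy CSV file
#'
#' @param traj A `gc_trajectory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
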