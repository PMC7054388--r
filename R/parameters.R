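#' Somatic hypermutation outcome probabilities
#'
#' At every Tfh-driven selection event a B-cell either advances one mutational
#' stage (forward, probability `p`), stays at its stage (neutral, `q`), dies
#' of a deleterious mutation (`d_del`), or regresses one stage (backward,
#' `1 - p - q - d_del`). The four probabilities must form a simplex.
#'
#' @param p Forward-mutation probability. Default 0.18.
#' @param q Neutral-mutation probability. Default 0.5.
#' @param d_del Deleterious-mutation probability. Default 0.3.
#'
#' @return An object of class `mutation_kernel`: a list with elements `p`,
#'   `q`, `d_del` and the derived backward probability `b`.
#' @examples
#' mutation_kernel()          # baseline: backward probability 0.02
#' mutation_kernel(p = 0.12)  # stronger bias against forward mutation
#' @export
mutation_kernel <- function(p = 0.18, q = 0.5, d_del = 0.3) {
  for (nm in c("p", "q", "d_del")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a single probability in [0, 1]", call. = FALSE)
    }
  }
  b <- 1 - p - q - d_del
  if (b < -1e-12) {
    stop("backward probability 1 - p - q - d_del = ", signif(b, 3),
         " is negative; p + q + d_del must not exceed 1", call. = FALSE)
  }
  structure(list(p = p, q = q, d_del = d_del, b = max(b, 0)),
            class = "mutation_kernel")
}

#' @export
print.mutation_kernel <- function(x, ...) {
  cat("<mutation_kernel>  forward p =", x$p, " neutral q =", x$q,
      " deleterious d =", x$d_del, " backward b =", signif(x$b, 6), "\n")
  invisible(x)
}

#' Stage threshold for plasma cell production
#'
#' B-cells output plasma cells only once they have accumulated `n_c = 2/3 n`
#' productive somatic hypermutations. Since 2n/3 is not an integer for most
#' `n`, the threshold is rounded up, so that at `n = 50` the last pre-plasma
#' stage is stage 33.
#'
#' @param n Total number of mutational stages (integer, at least 2).
#' @return Integer stage index `n_c` with `1 <= n_c <= n`.
#' @examples
#' plasma_threshold_stage(50)  # 34
#' plasma_threshold_stage(8)   # 6
#' @export
plasma_threshold_stage <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  as.integer(ceiling(2 * n / 3))
}

#' Per-stage proliferation (offspring) rate
#'
#' B-cells at later mutational stages replicate faster: the offspring number
#' rises linearly from `alpha_base` (8 per day, an 8-hour replication time)
#' towards twice that value. The schedule is `alpha_0 = alpha_base` and
#' `alpha_i = alpha_base * (1 + (i - 1)/n)` for `i >= 1`, so the first two
#' stages share the base rate and the terminal stage approaches
#' `2 * alpha_base` as `n` grows.
#'
#' @param i Stage index (scalar or vector), `0 <= i <= n`.
#' @param params A [gc_parameters()] object.
#' @return Offspring rate(s) in day^-1.
#' @examples
#' p <- gc_parameters(n = 8)
#' proliferation_rate(0:8, p)
#' @export
proliferation_rate <- function(i, params) {
  stopifnot(inherits(params, "gc_parameters"))
  if (any(i < 0 | i > params$n | i != round(i))) {
    stop("stage index must be an integer in [0, ", params$n, "]", call. = FALSE)
  }
  ifelse(i == 0, params$alpha_base,
         params$alpha_base * (1 + (i - 1) / params$n))
}

# full schedule alpha_0..alpha_n as a vector (internal)
alpha_schedule <- function(params) {
  proliferation_rate(0:params$n, params)
}

#' Germinal center model parameters
#'
#' Bundles every rate of the two-clone germinal center model. Defaults are
#' the baseline values: strain-specific selection rate
#' `sigma = 1.7e-4` ml cell^-1 day^-1, broadly reactive selection at half that
#' rate, Tfh availability exchange rates `eta = f = 1e-5` cell^-1 day^-1, Tfh
#' death `d_G = 0.01` day^-1 (100-day lifespan), B-cell death `d_B = 0.8`
#' day^-1 (30-hour lifespan), and plasma production rate `kappa = 1.2` day^-1.
#'
#' @param n Number of mutational stages (default 8; the many-stage regime
#'   uses 50).
#' @param sigma Per-Tfh strain-specific selection rate (ml cell^-1 day^-1).
#' @param sigma_c Per-Tfh broadly reactive selection rate; defaults to
#'   `0.5 * sigma`.
#' @param kernel A [mutation_kernel()].
#' @param eta Tfh loss-of-availability rate (cell^-1 day^-1).
#' @param f Tfh regain-of-availability rate (cell^-1 day^-1).
#' @param d_G Tfh death rate (day^-1).
#' @param d_B B-cell death rate (day^-1).
#' @param kappa Plasma cell production rate (day^-1).
#' @param alpha_base Base offspring number (day^-1).
#' @param n_c Plasma-production threshold stage; defaults to
#'   [plasma_threshold_stage()] of `n`. Override only to probe sensitivity to
#'   the rounding convention.
#'
#' @return An object of class `gc_parameters`.
#' @examples
#' gc_parameters()                       # baseline few-stage regime (n = 8)
#' gc_parameters(n = 50)                 # many-stage regime, n_c = 34
#' p <- gc_parameters(sigma_c = 0.76 * 1.7e-4)
#' @export
gc_parameters <- function(n = 8,
                          sigma = 1.7e-4,
                          sigma_c = 0.5 * sigma,
                          kernel = mutation_kernel(),
                          eta = 1e-5,
                          f = 1e-5,
                          d_G = 0.01,
                          d_B = 0.8,
                          kappa = 1.2,
                          alpha_base = 8,
                          n_c = plasma_threshold_stage(n)) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (!inherits(kernel, "mutation_kernel")) {
    stop("`kernel` must be a mutation_kernel object", call. = FALSE)
  }
  rates <- c(sigma = sigma, sigma_c = sigma_c, eta = eta, f = f, d_G = d_G,
             d_B = d_B, kappa = kappa, alpha_base = alpha_base)
  bad <- names(rates)[!is.finite(rates) | rates < 0]
  if (length(bad)) {
    stop("parameter(s) must be finite and non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(n_c) || length(n_c) != 1L || n_c != round(n_c) ||
      n_c < 1 || n_c > n) {
    stop("`n_c` must be an integer in [1, n]", call. = FALSE)
  }
  structure(
    list(n = n, n_c = as.integer(n_c), sigma = as.numeric(sigma),
         sigma_c = as.numeric(sigma_c), kernel = kernel,
         eta = as.numeric(eta), f = as.numeric(f), d_G = as.numeric(d_G),
         d_B = as.numeric(d_B), kappa = as.numeric(kappa),
         alpha_base = as.numeric(alpha_base)),
    class = "gc_parameters"
  )
}

#' @export
print.gc_parameters <- function(x, ...) {
  cat("<gc_parameters>  two-clone germinal center model\n")
  cat("  stages n =", x$n, " plasma threshold n_c =", x$n_c, "\n")
  cat("  selection: sigma =", format(x$sigma), " sigma_c =", format(x$sigma_c),
      sprintf(" (ratio %.4g)\n", x$sigma_c / x$sigma))
  cat("  Tfh: d_G =", x$d_G, " eta =", format(x$eta), " f =", format(x$f), "\n")
  cat("  B: d_B =", x$d_B, " kappa =", x$kappa,
      " alpha_0 =", x$alpha_base, "\n")
  print(x$kernel)
  invisible(x)
}

#' Initial seeding of the germinal center
#'
#' Founder B-cells of each clone enter at mutational stage 0; all later
#' stages, plasma pools and unavailable-Tfh pools start empty. The baseline
#' germinal center is seeded by 50 cells of each clone with 5000 available
#' Tfh cells/ml per family.
#'
#' @param B1_0,B2_0 Initial stage-0 cells of the broadly reactive (clone 1)
#'   and strain-specific (clone 2) B-cell clones.
#' @param G1_0,G2_0 Initial available Tfh cells/ml of families 1 and 2.
#' @return An object of class `gc_seeding`.
#' @examples
#' gc_seeding()                      # equal seeding, 50 + 50 cells
#' gc_seeding(B1_0 = 10, B2_0 = 90)  # biased towards the strain-specific clone
#' @export
gc_seeding <- function(B1_0 = 50, B2_0 = 50, G1_0 = 5000, G2_0 = 5000) {
  v <- as.numeric(c(B1_0 = B1_0, B2_0 = B2_0, G1_0 = G1_0, G2_0 = G2_0))
  names(v) <- c("B1_0", "B2_0", "G1_0", "G2_0")
  if (!all(is.finite(v)) || any(v < 0)) {
    stop("seeding values must be finite and non-negative", call. = FALSE)
  }
  structure(as.list(v), class = "gc_seeding")
}

#' @export
print.gc_seeding <- function(x, ...) {
  cat("<gc_seeding>  B1(0) =", x$B1_0, " B2(0) =", x$B2_0,
      " G1(0) =", x$G1_0, " G2(0) =", x$G2_0, "\n")
  invisible(x)
}
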