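#' Time derivative of the two-clone germinal center model
#'
#' Evaluates the right-hand side of the model at a given state. The broadly
#' reactive clone (1) is selected by both Tfh families at total rate
#' `sigma_c * (G1 + G2)`; the strain-specific clone (2) by family 2 only, at
#' rate `sigma * G2`. Each selection event advances a cell one stage with
#' probability `p` (producing `alpha_i` offspring in the receiving stage),
#' regresses it with probability `b` (again with the receiving stage's
#' `alpha`), stalls it (`q`) or kills it (`d_del`); the net stay/leave flux is
#' the `(q - 1)` term. All B-cells die at rate `d_B`. Stages at or beyond
#' `n_c` additionally lose cells to plasma differentiation at rate `kappa`,
#' while the plasma pool gains `alpha_k * kappa * B_k` (the proliferative
#' burst accompanies differentiation, so the gain carries the `alpha_k`
#' factor that the loss term does not). The terminal stage `n` has no forward
#' exit; its backward mutations recycle into stage `n` itself as well as
#' feeding the backward gain of stage `n - 1`. Available Tfh cells (`G`)
#' become unavailable (`H`) at rate `eta` per B-cell competing for them and
#' return at rate `f`; family 1 is engaged only by clone 1, family 2 by both
#' clones. Both Tfh pools decay at `d_G`, so each family obeys the closed
#' form `G_j + H_j = (G_j(0) + H_j(0)) * exp(-d_G * t)`.
#'
#' @param state Named numeric state vector as produced by [initial_state()].
#' @param params A [gc_parameters()] object.
#' @return Numeric vector of time derivatives, same length and order as
#'   `state`.
#' @examples
#' p <- gc_parameters(n = 8)
#' d <- gc_derivative(initial_state(p, gc_seeding()), p)
#' d[["G1"]]    # -52.5 cells/ml/day at baseline
#' @export
gc_derivative <- function(state, params) {
  stopifnot(inherits(params, "gc_parameters"))
  idx <- state_index(params$n)
  if (length(state) != idx$length) {
    stop("state has length ", length(state), " but n = ", params$n,
         " requires length ", idx$length, call. = FALSE)
  }
  dy <- gc_rhs(0, unname(state), params)[[1L]]
  names(dy) <- state_names(params$n)
  dy
}

# deSolve-compatible RHS: function(t, y, parms) -> list(dy).
# Autonomous system; t is unused.
gc_rhs <- function(t, y, parms) {
  n <- parms$n
  m <- n + 1L
  nc <- parms$n_c
  kr <- parms$kernel
  alpha <- .alpha_cache(parms)

  G1 <- y[1L]; H1 <- y[2L]
  B1 <- y[3L:(2L + m)]
  o <- m + 3L
  G2 <- y[o + 1L]; H2 <- y[o + 2L]
  B2 <- y[(o + 3L):(o + 2L + m)]

  s1 <- sum(B1); s2 <- sum(B2)

  dG1 <- -parms$d_G * G1 - parms$eta * G1 * s1 + parms$f * H1 * s1
  dH1 <- -parms$d_G * H1 + parms$eta * G1 * s1 - parms$f * H1 * s1
  dG2 <- -parms$d_G * G2 - G2 * parms$eta * (s1 + s2) +
    H2 * parms$f * (s1 + s2)
  dH2 <- -parms$d_G * H2 + G2 * parms$eta * (s1 + s2) -
    H2 * parms$f * (s1 + s2)

  S1 <- parms$sigma_c * (G1 + G2)  # total selection, broadly reactive clone
  S2 <- parms$sigma * G2           # total selection, strain-specific clone

  clone_rhs <- function(B, S) {
    # forward gain p*alpha_i*B_{i-1} (no influx into stage 0); backward gain
    # alpha_i*b*B_{i+1}, with the terminal stage recycling into itself
    fwd <- kr$p * alpha * c(0, B[seq_len(n)])
    bwd <- kr$b * alpha * c(B[2L:m], B[m])
    dB <- S * (fwd + (kr$q - 1) * B + bwd) - parms$d_B * B
    k <- (nc + 1L):m  # stages n_c..n (1-based)
    dB[k] <- dB[k] - parms$kappa * B[k]
    dP <- parms$kappa * sum(alpha[k] * B[k])
    list(dB = dB, dP = dP)
  }

  c1 <- clone_rhs(B1, S1)
  c2 <- clone_rhs(B2, S2)

  list(c(dG1, dH1, c1$dB, c1$dP, dG2, dH2, c2$dB, c2$dP))
}

# memoise the alpha schedule on the parameter object (computed once per call
# chain; gc_parameters objects are immutable lists)
.alpha_cache <- function(parms) {
  a <- attr(parms, ".alpha")
  if (is.null(a)) {
    a <- ifelse(0:parms$n == 0, parms$alpha_base,
                parms$alpha_base * (1 + ((0:parms$n) - 1) / parms$n))
  }
  a
}

# attach the cached schedule before handing parms to the integrator
.with_alpha <- function(parms) {
  attr(parms, ".alpha") <- .alpha_cache(parms)
  parms
}
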