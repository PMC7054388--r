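# State layout. The full model state is a named numeric vector of length
# 2(n+1) + 6 in the fixed order
#   G1, H1, B1_0 .. B1_n, P1, G2, H2, B2_0 .. B2_n, P2
# so that trajectories are portable across functions and CSV exports.

state_names <- function(n) {
  c("G1", "H1", paste0("B1_", 0:n), "P1",
    "G2", "H2", paste0("B2_", 0:n), "P2")
}

# index helpers; j is the clone (1 or 2)
state_index <- function(n) {
  m <- n + 1L
  off <- function(j) (j - 1L) * (m + 3L)
  list(
    G = function(j) off(j) + 1L,
    H = function(j) off(j) + 2L,
    B = function(j) off(j) + 2L + seq_len(m),   # stages 0..n
    P = function(j) off(j) + 3L + m,
    length = 2L * (m + 3L)
  )
}

#' Assemble the initial model state
#'
#' Places the seeded founder cells at stage 0 of each clone and the available
#' Tfh cells in the `G` pools; the unavailable pools `H`, all higher stages,
#' and both plasma pools start at zero.
#'
#' @param params A [gc_parameters()] object.
#' @param seeding A [gc_seeding()] object.
#' @return Named numeric state vector of length `2 * (n + 1) + 6`, ordered
#'   `G1, H1, B1_0..B1_n, P1, G2, H2, B2_0..B2_n, P2`.
#' @examples
#' initial_state(gc_parameters(n = 3), gc_seeding())
#' @export
initial_state <- function(params, seeding = gc_seeding()) {
  stopifnot(inherits(params, "gc_parameters"), inherits(seeding, "gc_seeding"))
  idx <- state_index(params$n)
  y <- numeric(idx$length)
  names(y) <- state_names(params$n)
  y[idx$G(1)] <- seeding$G1_0
  y[idx$G(2)] <- seeding$G2_0
  y[idx$B(1)[1]] <- seeding$B1_0
  y[idx$B(2)[1]] <- seeding$B2_0
  y
}
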