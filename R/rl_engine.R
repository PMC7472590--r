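#' Action value of an algorithmic state
#'
#' The bookkeeping primitive every annotation stage uses: an action value is
#' the reward plus the discounted next-state value, scaled by the transition
#' probability, \code{Q = (Rs + gamma * vNext) * P}. The stages of this
#' package are deterministic, so \code{P} is almost always 1 and \code{gamma}
#' takes values in \{0, 1, -1\} (or the searched grids of the direction
#' stage).
#'
#' @param Rs reward value (amplitude-scaled).
#' @param gamma next-state coefficient.
#' @param vNext next-state value V(s').
#' @param P transition probability in [0, 1].
#' @return The action value Q, vectorized over its arguments.
#' @examples
#' actionValue(3, 1, 2, 1)   # 5
#' actionValue(3, 0, 99, 1)  # 3: gamma = 0 drops the next state
#' @export
actionValue <- function(Rs, gamma, vNext, P = 1) {
  if (!all(is.finite(Rs), is.finite(gamma), is.finite(vNext), is.finite(P)))
    stop("actionValue: all inputs must be finite")
  if (any(P < 0 | P > 1))
    stop("actionValue: P must lie in [0, 1]")
  (Rs + gamma * vNext) * P
}

#' Two-point softmax policy
#'
#' Probability assigned to the optimized action value among the pair
#' \code{(Q, Qopt)} at temperature \code{alpha}:
#' \code{pi = exp(Qopt/alpha) / (exp(Q/alpha) + exp(Qopt/alpha))}.
#' Computed with max-subtraction; amplitude-scale action values with small
#' alpha overflow the naive exponentials.
#'
#' @param Q action value.
#' @param Qopt optimized (maximum) action value.
#' @param alpha temperature, must be > 0. The alpha = 0 convention (policy
#'   treated as 1) is applied by callers, not here.
#' @return Policy value in (0, 1).
#' @examples
#' softmaxPolicy(2, 2, 5)          # 0.5 by symmetry
#' softmaxPolicy(0, 1, 1)          # e/(1+e)
#' @export
softmaxPolicy <- function(Q, Qopt, alpha) {
  if (!all(is.finite(Q), is.finite(Qopt)) || !is.finite(alpha) || alpha <= 0)
    stop("softmaxPolicy: Q, Qopt must be finite and alpha > 0")
  a <- Q / alpha
  b <- Qopt / alpha
  m <- pmax(a, b)
  exp(b - m) / (exp(a - m) + exp(b - m))
}

# stable softmax over a pair at unit temperature; returns the two probabilities
softmaxPair <- function(q0, q1) {
  m <- max(q0, q1)
  e0 <- exp(q0 - m)
  e1 <- exp(q1 - m)
  c(e0, e1) / (e0 + e1)
}

#' Soft (entropy-regularized) state-value update
#'
#' \code{v' = pi * (Qopt - alpha * log(pi))}. With \code{pi = 1} and
#' \code{alpha = 0} the update reduces to the optimized action value, the
#' setting used at the QRS stopping time.
#'
#' @param pi policy value in (0, 1]; apply a policy floor before calling.
#' @param Qopt optimized action value.
#' @param alpha temperature coefficient (>= 0).
#' @return Updated state value v'(s).
#' @examples
#' updateStateValue(1, 7, 0)      # 7
#' updateStateValue(0.5, 4, 2)    # 2 + log(2)
#' @export
updateStateValue <- function(pi, Qopt, alpha) {
  if (any(!is.finite(pi)) || any(pi <= 0) || any(pi > 1))
    stop("updateStateValue: pi must lie in (0, 1]")
  pi * (Qopt - alpha * log(pi))
}

#' First-hit search of the softmax temperature
#'
#' Scans alpha over the grid \{0.5, 1.5, ..., 100.5\} (101 values) in order
#' and returns the first alpha whose updated state value -- softmax policy of
#' \code{(Q, Qopt)} fed through \code{\link{updateStateValue}} -- strictly
#' exceeds the action value \code{Q}. When no grid value exceeds it, 0 is
#' returned and callers treat the policy as 1.
#'
#' @param Q action value to exceed.
#' @param Qopt optimized action value.
#' @return The selected alpha (0.5 + k, k = 0..100), or 0.
#' @export
searchAlpha <- function(Q, Qopt) {
  if (!all(is.finite(Q), is.finite(Qopt)))
    stop("searchAlpha: Q and Qopt must be finite")
  for (alpha in seq(0.5, 100.5, by = 1)) {
    pi <- softmaxPolicy(Q, Qopt, alpha)
    v <- updateStateValue(pi, Qopt, alpha)
    if (v > Q) return(alpha)
  }
  0
}
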