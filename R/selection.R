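#' @describeIn SelectionConfig-class constructor.
#' @param mode selection mode.
#' @param beta inverse temperature for `GIBBS`.
#' @export
selectionConfig <- function(mode = c("PROPORTIONAL", "STRONG", "GIBBS"),
                            beta = 1) {
  mode <- match.arg(toupper(mode), c("PROPORTIONAL", "STRONG", "GIBBS"))
  new("SelectionConfig", mode = mode, beta = beta)
}

#' Survival probabilities of the stochastic selection modes
#'
#' `PROPORTIONAL`: p_i = s_i / sum(s); with an all-zero pool the mode falls
#' back to the uniform 1/(2N). `GIBBS`: p_i = exp(beta * s_i) / sum(exp(
#' beta * s)), computed with a max-shift so large beta cannot overflow;
#' beta = 0 is exactly uniform. `STRONG` is deterministic and has no
#' probability vector.
#'
#' @param scores non-negative fitness scores of the 2N pool.
#' @param mode `"PROPORTIONAL"` or `"GIBBS"`.
#' @param beta inverse temperature (`GIBBS` only), >= 0.
#' @return probability vector summing to 1.
#' @export
selectionProbs <- function(scores, mode = c("PROPORTIONAL", "GIBBS"),
                           beta = 1) {
  mode <- match.arg(mode)
  if (mode == "PROPORTIONAL") {
    if (any(scores < 0)) stop("proportional selection needs scores >= 0")
    tot <- sum(scores)
    if (tot == 0) rep(1 / length(scores), length(scores))
    else scores / tot
  } else {
    if (beta < 0) stop("beta must be >= 0")
    w <- beta * scores
    w <- exp(w - max(w))
    w / sum(w)
  }
}

#' Strong (truncation) selection
#'
#' Deterministically keeps the n highest-scoring pool members; each pool
#' member can be selected at most once. Ties are broken by stable pool
#' order, so the result is fully deterministic.
#'
#' @param scores fitness scores of the 2n pool members.
#' @param n number of survivors (pool must be exactly 2n).
#' @return integer indices of the survivors, in pool order.
#' @export
selectStrong <- function(scores, n) {
  if (length(scores) != 2L * n)
    stop(sprintf("pool size %d is not 2n = %d", length(scores), 2L * n))
  ord <- order(-scores)           # stable: ties keep pool order
  sort(ord[seq_len(n)])
}

#' Fitness-proportional selection
#'
#' n independent draws with replacement with probability proportional to
#' score, so the same pool member can survive multiple times. Uses the
#' current RNG state.
#'
#' @inheritParams selectStrong
#' @return integer indices of the survivors (possibly repeated).
#' @export
selectProportional <- function(scores, n) {
  if (length(scores) != 2L * n)
    stop(sprintf("pool size %d is not 2n = %d", length(scores), 2L * n))
  p <- selectionProbs(scores, "PROPORTIONAL")
  sample.int(length(scores), n, replace = TRUE, prob = p)
}

#' Gibbs (softmax) selection
#'
#' n weighted draws without replacement under the Gibbs distribution with
#' inverse temperature beta: beta = 0 is neutral drift (every pool member
#' equally likely to survive), beta around 1 resembles proportional
#' selection of the exponentiated scores, and beta above ~5 behaves like
#' strong deterministic selection. Sampling is without replacement -- each
#' pool member survives at most once, matching the strong-selection rule
#' the mode converges to as beta grows.
#'
#' @inheritParams selectStrong
#' @param beta inverse temperature, >= 0.
#' @return integer indices of the survivors, in draw order.
#' @export
selectGibbs <- function(scores, n, beta) {
  if (length(scores) != 2L * n)
    stop(sprintf("pool size %d is not 2n = %d", length(scores), 2L * n))
  if (beta < 0) stop("beta must be >= 0")
  ## Gumbel-top-k: taking the n largest beta*s_i + Gumbel(0,1) draws is
  ## exactly weighted sampling without replacement with weights e^{beta s},
  ## and never exponentiates the scores, so any beta is overflow-safe
  g <- -log(-log(stats::runif(length(scores))))
  order(-(beta * scores + g))[seq_len(n)]
}

#' @describeIn selectionConfig dispatch on a [SelectionConfig].
#' @param scores pool scores.
#' @param n survivors to choose.
#' @param config a `SelectionConfig`.
#' @export
selectSurvivors <- function(scores, n, config) {
  switch(config@mode,
         STRONG = selectStrong(scores, n),
         PROPORTIONAL = selectProportional(scores, n),
         GIBBS = selectGibbs(scores, n, config@beta))
}
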