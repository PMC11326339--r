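#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats runif rbinom rpois rexp qt sd cor fisher.test p.adjust
#' @importFrom utils head read.delim write.table
NULL

# logistic with overflow guard
sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# clip probabilities away from {0,1} before taking logs
clipProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Run expr under a temporary RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a base seed and a stream label; stays < 2^31.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %% 2147483647
}

stopIfNot <- function(cond, msg, class = "repurposeKG_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "error", "condition")))
  }
}

# Xavier-uniform draw: fan_in = fan_out = d convention, a = sqrt(6/(2 d)).
xavierUniform <- function(nrow, ncol, d = ncol) {
  a <- sqrt(6 / (2 * d))
  matrix(runif(nrow * ncol, -a, a), nrow = nrow, ncol = ncol)
}
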