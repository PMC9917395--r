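# Internal numerical helpers shared across the package.

# Row-wise log-sum-exp of a matrix, guarded against -Inf rows.
.row_logsumexp <- function(A) {
  m <- do.call(pmax, c(as.data.frame(A), list(na.rm = TRUE)))
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(A - m)))
}

# Evaluate a polynomial with coefficients in increasing order of power.
.polyval <- function(beta, x) {
  out <- rep(beta[1], length(x))
  if (length(beta) > 1L) {
    xp <- x
    for (k in 2:length(beta)) {
      out <- out + beta[k] * xp
      xp <- xp * x
    }
  }
  out
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

# Draw a sub-seed for a pipeline stage from a master seed, staying well
# inside the 32-bit integer range.
.stage_seed <- function(seed, stage_index) {
  (as.integer(seed) * 97L + stage_index * 1009L) %% 2147483L
}
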