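# Independent Mann-Whitney oracle: direct pair counting over every group
# assignment; shares no rank arithmetic with the implementation under test.
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x < y) + 0.5 * (x == y)
  min(u, length(a) * length(b) - u)
}

oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_obs <- oracle_u(a, b)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    ga <- pooled[idx[, j]]
    gb <- pooled[-idx[, j]]
    if (oracle_u(ga, gb) <= u_obs + 1e-9) hits <- hits + 1
  }
  hits / ncol(idx)
}
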