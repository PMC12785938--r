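# Independent oracles used by both the module tests and the acceptance
# suite. Deliberately naive implementations: exhaustive re-computation,
# classic Gram-Schmidt.

# brute-force SPXY: recompute the max-min rule exhaustively at every step
spxy_oracle <- function(X, y, n_cal) {
  n <- nrow(X)
  dx <- as.matrix(dist(X))
  dy <- abs(outer(y, y, "-"))
  d <- dx / max(dx) + dy / max(dy)
  pairs <- which(d == max(d), arr.ind = TRUE)
  pairs <- pairs[order(pmin(pairs[, 1], pairs[, 2]),
                       pmax(pairs[, 1], pairs[, 2])), , drop = FALSE]
  sel <- sort(unname(pairs[1, ]))
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    best <- rest[1]; bestd <- -Inf
    for (r in rest) {
      md <- min(d[r, sel])
      if (md > bestd + 1e-15) { bestd <- md; best <- r }
    }
    sel <- c(sel, best)
  }
  sort(sel)
}

# direct Gram-Schmidt oracle for the SPA projection chain
spa_chain_oracle <- function(X, start, kmax) {
  chain <- start
  basis <- list()
  for (step in seq_len(kmax - 1L)) {
    v <- X[, chain[length(chain)]]
    for (b in basis) v <- v - b * sum(b * v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) break
    basis <- c(basis, list(v / nv))
    norms <- sapply(seq_len(ncol(X)), function(j) {
      u <- X[, j]
      for (b in basis) u <- u - b * sum(b * u)
      sum(u^2)
    })
    norms[chain] <- -Inf
    if (max(norms) < 1e-10) break
    chain <- c(chain, which.max(norms))
  }
  chain
}
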