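# Independent oracles, deliberately written as plain exhaustive loops so they
# share no code with the package implementations they check.

# Between-class variance evaluated directly at one candidate threshold.
oracleOtsuCriterion <- function(counts, t) {
  levels <- 0:255
  n <- sum(counts)
  i0 <- levels <= t
  n0 <- sum(counts[i0]); n1 <- n - n0
  if (n0 == 0 || n1 == 0) return(NA_real_)
  w0 <- n0 / n; w1 <- n1 / n
  mu0 <- sum(counts[i0] * levels[i0]) / n0
  mu1 <- sum(counts[!i0] * levels[!i0]) / n1
  w0 * w1 * (mu0 - mu1)^2
}

# Kapur entropy-sum criterion at one candidate threshold.
oracleKapurCriterion <- function(counts, t) {
  p <- counts / sum(counts)
  i0 <- (0:255) <= t
  P0 <- sum(p[i0]); P1 <- sum(p[!i0])
  if (P0 == 0 || P1 == 0) return(NA_real_)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  ent(p[i0] / P0) + ent(p[!i0] / P1)
}

# Exhaustive search over all 256 candidates, smallest-t tie-break.
oracleThreshold <- function(counts, criterion) {
  vals <- vapply(0:255, function(t) criterion(counts, t), 0)
  t <- which.max(vals) - 1L
  list(threshold = t, value = vals[t + 1L], curve = vals)
}

# Queue-based flood-fill component labelling, independent of the Rcpp path.
oracleLabel <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  offsets <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || labels[r0, c0] != 0L) next
    lab <- lab + 1L
    queue <- list(c(r0, c0))
    labels[r0, c0] <- lab
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (d in offsets) {
        r <- cur[1L] + d[1L]; cc <- cur[2L] + d[2L]
        if (r < 1 || r > nr || cc < 1 || cc > nc) next
        if (mask[r, cc] && labels[r, cc] == 0L) {
          labels[r, cc] <- lab
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  labels
}

# Component sizes from the oracle labeller.
oracleComponentSizes <- function(mask, connectivity = 8) {
  labels <- oracleLabel(mask, connectivity)
  if (max(labels) == 0L) return(integer(0))
  tabulate(labels[labels > 0L])
}

# Spearman's rho computed from first principles: rank transform, then the
# product-moment formula.
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

randomHistogram <- function() {
  counts <- integer(256)
  k <- sample(2:12, 1)                      # occupied bins
  bins <- sample(0:255, k)
  counts[bins + 1L] <- sample(1:500, k, replace = TRUE)
  if (runif(1) < 0.3)                       # sometimes add a diffuse floor
    counts <- counts + rpois(256, 2)
  if (sum(counts > 0) < 2L) counts[c(3, 200)] <- c(5L, 7L)
  counts
}

randomMask <- function(nr = 48, nc = 48, density = 0.3) {
  matrix(runif(nr * nc) < density, nr, nc)
}

# Small, quick synthetic scene used across tests; any default overridable.
testSpec <- function(...) {
  args <- utils::modifyList(
    list(dims = c(128L, 128L), nNuclei = 25L, radiusRange = c(3, 5),
         speckCount = 8L, speckSizeRange = c(1, 10)),
    list(...))
  do.call(sceneSpec, args)
}
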