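# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so that they share no
# code path with the package implementation.

# brute-force double-loop CCG: count every pair difference and bin it
bruteForceCcg <- function(trainA, trainB, binMs = 0.4, maxLagMs = 200) {
  half <- round(maxLagMs / binMs)
  counts <- integer(2 * half + 1)
  for (ta in trainA) for (tb in trainB) {
    k <- round((tb - ta) * 1000 / binMs)
    if (abs(k) <= half) counts[k + half + 1] <- counts[k + half + 1] + 1L
  }
  counts
}

# literal Rosner GESD: iterative max deletion with the textbook critical
# values, returning the indices flagged as outliers
rosnerOracle <- function(x, alpha = 0.05, maxOutliers) {
  n <- length(x)
  idx <- seq_len(n)
  R <- lam <- numeric(maxOutliers)
  removed <- integer(maxOutliers)
  for (i in seq_len(maxOutliers)) {
    xi <- x[idx]
    dev <- abs(xi - mean(xi))
    j <- which.max(dev)
    R[i] <- dev[j] / sd(xi)
    removed[i] <- idx[j]
    idx <- idx[-j]
    nn <- n - i
    pcrit <- 1 - alpha / (2 * (nn + 1))
    tcrit <- qt(pcrit, nn - 1)
    lam[i] <- nn * tcrit / sqrt((nn - 1 + tcrit^2) * (nn + 1))
  }
  k <- if (any(R > lam)) max(which(R > lam)) else 0
  removed[seq_len(k)]
}

# exact Mann-Whitney two-sided p by full enumeration of group assignments
exactMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  uStat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- uStat(a, b)
  combs <- combn(n, na)
  us <- apply(combs, 2, function(ii) uStat(pooled[ii], pooled[-ii]))
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# homogeneous Poisson train on [0, duration]
poissonTrain <- function(rate, duration) {
  sort(runif(rpois(1, rate * duration), 0, duration))
}

# wrap a snippet matrix as a unit with one (arbitrary) spike per snippet
snipUnit <- function(id, snips, channel = 1L) {
  SortedUnit(id, seq_len(nrow(snips)), channel, snips)
}

# two orthonormal snippet "templates" used to build controlled PC clouds
orthoTemplates <- function(len = 32) {
  t1 <- sin(seq(0, pi, length.out = len)); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- sin(seq(0, 2 * pi, length.out = len)); t2 <- t2 / sqrt(sum(t2^2))
  list(t1 = t1, t2 = t2)
}
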