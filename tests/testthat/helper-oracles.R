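# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (per-base loops, exhaustive enumeration,
# direct likelihood maximization) and share no code with the implementation
# they check.

# Per-base average of segment means over the bases of [gs, ge] covered by
# any segment; 0 if no base is covered. Coordinates must be small.
oracle_gene_mean <- function(segs, gs, ge) {
  vals <- rep(NA_real_, ge - gs + 1)
  for (i in seq_len(nrow(segs))) {
    lo <- max(segs$start[i], gs)
    hi <- min(segs$end[i], ge)
    if (hi >= lo) vals[(lo:hi) - gs + 1] <- segs$segment_mean[i]
  }
  if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
}

# Per-base support counting over a toy chromosome of length L: maximal runs
# of bases covered by >=1 loss interval of every sample.
oracle_mcr <- function(loss_by_sample, L) {
  support <- integer(L)
  for (d in loss_by_sample) {
    covered <- logical(L)
    for (i in seq_len(nrow(d))) covered[d$start[i]:d$end[i]] <- TRUE
    support <- support + covered
  }
  full <- support == length(loss_by_sample)
  r <- rle(full)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Exhaustive-enumeration one-sided Wilcoxon rank-sum p-value,
# alternative: x stochastically greater. Requires no ties.
oracle_wilcoxon_greater <- function(x, y) {
  v <- c(x, y)
  stopifnot(!any(duplicated(v)))
  r <- rank(v)
  obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(v), length(x))
  null <- colSums(matrix(r[combos], nrow = length(x)))
  mean(null >= obs)
}

# Two-group log-rank chi-square from the observed-minus-expected sums.
oracle_logrank2 <- function(time, event, group) {
  group <- as.logical(group)
  ts <- sort(unique(time[event > 0]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event > 0)
    d1 <- sum(time == t & event > 0 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Direct numerical maximization of the Poisson interaction likelihood.
oracle_poisson_fit <- function(y, x, with_loss) {
  X <- cbind(1, x * with_loss, x * (!with_loss))
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - exp(eta) - lgamma(y + 1))
  }
  gr <- function(b) {
    mu <- exp(as.numeric(X %*% b))
    -as.numeric(t(X) %*% (y - mu))
  }
  o <- stats::optim(c(log(mean(y) + 0.1), 0, 0), nll, gr, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 2000))
  # restart until the gradient is tiny (BFGS alone can stall at ~1e-5)
  for (k in 1:5) {
    if (sqrt(sum(gr(o$par)^2)) < 1e-9) break
    o <- stats::optim(o$par, nll, gr, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  }
  list(beta = o$par, loglik = -o$value)
}

# Hand-computed Kruskal-Wallis statistic with tie correction.
oracle_kruskal <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
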