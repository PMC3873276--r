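# Shared fixtures and independent oracles used across the suite.

# tiny deterministic count matrix: 3 genes x 2 samples
toy_cm <- function() {
  counts <- matrix(c(10L, 0L, 5L, 20L, 2L, 8L), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  count_matrix(counts,
               c(gA = 1000, gB = 500, gC = 2000),
               data.frame(sample = c("s1", "s2"), genotype = "wt",
                          tissue = "leaf", stage = "L6", replicate = 1:2))
}

# RPKM of a single raw count vector
rpkm_vec <- function(counts, lengths) {
  counts / (lengths / 1e3) / (sum(counts) / 1e6)
}

# calibration RPKM columns (one replicate) of a simulate_atlas result,
# ordered by stage
calibration_rpkm <- function(sim, replicate = 1) {
  md <- sim$counts$metadata
  em <- rpkm(sim$counts)
  cols <- md$sample[md$replicate == replicate]
  out <- em[, cols, drop = FALSE]
  colnames(out) <- md$stage[md$replicate == replicate]
  out
}

# independent NB log-pmf written from the gamma-function form (not dnbinom)
nb_lpmf <- function(x, mu, phi) {
  if (phi < 1e-10) return(x * log(mu) - mu - lfactorial(x))
  r <- 1 / phi
  lgamma(x + r) - lgamma(r) - lfactorial(x) +
    r * log(r / (r + mu)) + x * log(mu / (r + mu))
}

# brute-force two-sided exact NB test: enumerate the conditional
# distribution of the group-A sum given the total
oracle_exact_nb_p <- function(sa, sb, na, nb, phi) {
  tot <- sa + sb
  if (tot == 0) return(1)
  mu <- tot / (na + nb)
  i <- 0:tot
  lp <- nb_lpmf(i, na * mu, phi / na) + nb_lpmf(tot - i, nb * mu, phi / nb)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[sa + 1] * (1 + 1e-10)])
}

# brute-force two-sided Wilcoxon rank-sum p by full enumeration of splits
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(pooled), m)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# exhaustive two-sided Fisher p for a 2x2 table via the hypergeometric tail
oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

# local maxima positions of a density curve above a relative height
density_maxima <- function(density, min_height = 0.1) {
  y <- density$values
  n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  density$grid[loc[y[loc] >= min_height * max(y)]]
}
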