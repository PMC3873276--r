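# Negative-binomial density/CDF that degrade gracefully to Poisson at phi ~ 0.
dnb_ <- function(x, mu, phi, log = FALSE) {
  if (phi < 1e-10) stats::dpois(x, mu, log = log)
  else stats::dnbinom(x, size = 1 / phi, mu = mu, log = log)
}
pnb_ <- function(q, mu, phi) {
  if (phi < 1e-10) stats::ppois(q, mu)
  else stats::pnbinom(q, size = 1 / phi, mu = mu)
}
qnb_ <- function(p, mu, phi) {
  if (phi < 1e-10) stats::qpois(p, mu)
  else stats::qnbinom(p, size = 1 / phi, mu = mu)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes between-library scaling factors by the TMM method: for each
#' library, per-gene log ratios (M-values) against a reference library are
#' trimmed (30% each tail on M, 5% each tail on absolute expression A; genes
#' with a zero in either library excluded) and averaged with inverse
#' asymptotic-variance weights. The reference is the library whose 75th
#' count percentile is closest to the mean across libraries. Factors are
#' rescaled to have geometric mean 1.
#'
#' @param cm a [count_matrix()] or a plain counts matrix.
#' @param logratio_trim fraction trimmed from each tail of the M-values.
#' @param abs_expr_trim fraction trimmed from each tail of the A-values.
#' @return named numeric vector of factors with attribute
#'   `reference_sample`; class `norm_factors`.
#' @export
tmm_factors <- function(cm, logratio_trim = 0.3, abs_expr_trim = 0.05) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))

  f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))

  factors <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    obs <- counts[, k]; rf <- counts[, ref]
    nO <- lib[k]; nR <- lib[ref]
    keep <- obs > 0 & rf > 0
    if (!any(keep))
      stop(sprintf("sample '%s' shares no nonzero genes with the reference",
                   colnames(counts)[k]))
    obs <- obs[keep]; rf <- rf[keep]
    M <- log2((obs / nO) / (rf / nR))
    A <- 0.5 * log2((obs / nO) * (rf / nR))
    w <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    if (max(abs(M)) < 1e-6) return(1)   # identical compositions
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_expr_trim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
    if (!is.finite(f)) f <- 0
    2^f
  }, numeric(1))

  factors <- factors / exp(mean(log(factors)))
  structure(stats::setNames(factors, colnames(counts)),
            reference_sample = colnames(counts)[ref],
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM normalization factors (reference:", attr(x, "reference_sample"), ")\n")
  print(round(unclass(x), 4))
  invisible(x)
}

# Quantile adjustment: map count x observed under NB(mu_in, phi) to the
# equivalent continuous quantile under NB(mu_out, phi), via the midpoint CDF
# and linear interpolation between integer quantiles. Identity when
# mu_in == mu_out.
q2q_nb <- function(x, mu_in, mu_out, phi) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (abs(mu_in[i] - mu_out[i]) < 1e-8 * (mu_in[i] + 1)) { out[i] <- x[i]; next }
    if (mu_in[i] <= 0) { out[i] <- 0; next }
    xi <- x[i]
    u <- (pnb_(xi, mu_in[i], phi) + pnb_(xi - 1, mu_in[i], phi)) / 2
    u <- min(max(u, 1e-12), 1 - 1e-12)
    q <- qnb_(u, mu_out[i], phi)
    Fq <- pnb_(q, mu_out[i], phi); Fq1 <- pnb_(q - 1, mu_out[i], phi)
    frac <- if (Fq > Fq1) (u - Fq1) / (Fq - Fq1) else 0.5
    out[i] <- max(q - 1 + frac, 0)
  }
  out
}

# Pseudo-counts at a common (geometric-mean) effective library size, given a
# working dispersion; group structure supplies per-gene expected proportions.
pseudo_counts <- function(counts, eff_lib, groups, phi) {
  N_out <- exp(mean(log(eff_lib)))
  if (max(abs(eff_lib - N_out)) < 1e-8 * N_out)
    return(list(pseudo = counts, common_lib = N_out))
  pseudo <- counts
  for (g in unique(groups)) {
    j <- which(groups == g)
    p_hat <- rowSums(counts[, j, drop = FALSE]) / sum(eff_lib[j])
    for (k in j) {
      mu_in <- p_hat * eff_lib[k]
      mu_out <- p_hat * N_out
      pseudo[, k] <- q2q_nb(counts[, k], mu_in, mu_out, phi)
    }
  }
  list(pseudo = pseudo, common_lib = N_out)
}

# Per-gene conditional log-likelihood of dispersion phi given group totals,
# for equal-library-size (pseudo) counts. Groups with a single replicate
# carry no information and are skipped. Vectorized over genes.
cond_loglik <- function(pseudo, groups, phi) {
  r <- 1 / max(phi, 1e-8)
  ll <- numeric(nrow(pseudo))
  for (g in unique(groups)) {
    j <- which(groups == g)
    n <- length(j)
    if (n < 2) next
    y <- pseudo[, j, drop = FALSE]
    z <- rowSums(y)
    ll <- ll + rowSums(lgamma(y + r)) + lgamma(n * r) -
      lgamma(z + n * r) - n * lgamma(r)
  }
  ll
}

#' Estimate common and tagwise negative-binomial dispersions
#'
#' Estimates the dispersion phi in the variance function `mu + phi * mu^2`
#' by maximizing the conditional likelihood given per-group totals on
#' quantile-adjusted (library-size-equalized) counts. The common estimate
#' maximizes the likelihood summed over genes; tagwise estimates maximize
#' each gene's own likelihood plus `prior_weight` times the per-gene average
#' likelihood across all genes, shrinking per-gene estimates toward the
#' common value — essential when only two replicates are available.
#'
#' @param cm a [count_matrix()] or counts matrix.
#' @param groups per-sample group labels (defaults to metadata genotype).
#' @param factors optional [tmm_factors()]; computed if `NULL`.
#' @param prior_weight shrinkage weight (in per-gene common-likelihood
#'   units); `Inf` returns the common estimate for every gene.
#' @param phi_max upper bound of the search interval.
#' @return list of class `dispersion_estimate`: `common` (scalar), `tagwise`
#'   (per-gene vector), `pseudo_counts`, `common_lib_size`.
#' @export
estimate_dispersion <- function(cm, groups = NULL, factors = NULL,
                                prior_weight = 10, phi_max = 10) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(groups)) {
    if (!inherits(cm, "count_matrix"))
      stop("groups must be given when cm is a plain matrix")
    groups <- cm$metadata$genotype
  }
  if (max(table(groups)) < 2)
    stop("all groups are singletons; dispersion is not estimable")
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff_lib <- colSums(counts) * as.numeric(factors)

  phi_work <- 0.1
  pc <- NULL
  for (iter in 1:2) {
    pc <- pseudo_counts(counts, eff_lib, groups, phi_work)
    opt <- stats::optimize(function(phi) sum(cond_loglik(pc$pseudo, groups, phi)),
                           interval = c(1e-4, phi_max), maximum = TRUE,
                           tol = 1e-6)
    phi_work <- opt$maximum
  }
  common <- phi_work

  # shared likelihood S(phi) = per-gene mean conditional log-likelihood,
  # splined on a log-phi grid for cheap evaluation inside per-gene optima
  grid <- exp(seq(log(1e-4), log(phi_max), length.out = 41))
  ll_grid <- vapply(grid, function(phi) cond_loglik(pc$pseudo, groups, phi),
                    numeric(nrow(counts)))
  S_fun <- stats::splinefun(log(grid), colMeans(ll_grid), method = "natural")

  if (is.infinite(prior_weight)) {
    tagwise <- rep(common, nrow(counts))
  } else {
    tagwise <- vapply(seq_len(nrow(counts)), function(i) {
      ll_i <- stats::splinefun(log(grid), ll_grid[i, ], method = "natural")
      stats::optimize(function(lphi) ll_i(lphi) + prior_weight * S_fun(lphi),
                      interval = log(c(1e-4, phi_max)), maximum = TRUE,
                      tol = 1e-4)$maximum
    }, numeric(1))
    tagwise <- exp(tagwise)
  }
  names(tagwise) <- rownames(counts)
  structure(list(common = common, tagwise = tagwise,
                 pseudo_counts = pc$pseudo, common_lib_size = pc$common_lib,
                 prior_weight = prior_weight),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("dispersion_estimate: common %.4f, tagwise range [%.4f, %.4f]\n",
              x$common, min(x$tagwise), max(x$tagwise)))
  invisible(x)
}

# Two-sided exact NB test p-value for one gene: condition on the total of the
# (library-equalized) group sums and add up the probabilities of all splits
# at most as likely as the observed one.
exact_nb_p <- function(sa, sb, na, nb, phi) {
  tot <- sa + sb
  if (tot == 0) return(1)
  mu <- tot / (na + nb)
  i <- 0:tot
  lp <- dnb_(i, na * mu, phi / na, log = TRUE) +
        dnb_(tot - i, nb * mu, phi / nb, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  if (pr[sa + 1] >= max(pr) * (1 - 1e-12)) return(1)  # modal split
  min(sum(pr[pr <= pr[sa + 1] * (1 + 1e-10)]), 1)
}

#' Exact negative-binomial test for pairwise differential expression
#'
#' For each gene, tests the two groups' expression difference with an exact
#' test under the negative-binomial model: counts are quantile-adjusted to a
#' common library size, group sums are rounded, and conditioning on the
#' total, the two-sided P-value is the summed probability of all splits as
#' or less likely than the one observed. The group sums are themselves
#' negative-binomial (a sum of n iid NB(mu, phi) variables is NB(n mu,
#' phi / n)), so the conditional distribution is computed by direct
#' enumeration over the total. Log fold changes come from normalized group
#' means with a pseudo-fraction of 0.125 per library.
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b genotype labels of the two groups (the reported
#'   log2 fold change is b over a).
#' @param factors optional [tmm_factors()]; computed if `NULL`.
#' @param dispersion scalar or per-gene dispersion vector (e.g. tagwise from
#'   [estimate_dispersion()]).
#' @return data.frame of class `de_result` with columns `gene_id`, `logFC`,
#'   `p_value`, `mean_a`, `mean_b` (normalized mean counts), `dispersion`;
#'   attribute `contrast`.
#' @export
exact_test <- function(cm, group_a, group_b, factors = NULL, dispersion = 0.1) {
  counts <- cm$counts
  groups <- cm$metadata$genotype
  ja <- which(groups == group_a); jb <- which(groups == group_b)
  if (length(ja) == 0 || length(jb) == 0)
    stop("both groups must be non-empty")
  sub <- counts[, c(ja, jb), drop = FALSE]
  subgroups <- rep(c("a", "b"), c(length(ja), length(jb)))
  if (is.null(factors)) factors <- tmm_factors(sub)
  fac <- if (!is.null(names(factors))) unclass(factors)[colnames(sub)]
         else as.numeric(factors)[seq_len(ncol(sub))]
  if (anyNA(fac)) stop("factors must cover both groups' samples")
  eff_lib <- colSums(sub) * as.numeric(fac)
  phi <- rep(dispersion, length.out = nrow(sub))

  pc <- pseudo_counts(sub, eff_lib, subgroups, stats::median(phi))
  sa <- round(rowSums(pc$pseudo[, subgroups == "a", drop = FALSE]))
  sb <- round(rowSums(pc$pseudo[, subgroups == "b", drop = FALSE]))
  na <- sum(subgroups == "a"); nb <- sum(subgroups == "b")

  p <- vapply(seq_len(nrow(sub)), function(i)
    exact_nb_p(sa[i], sb[i], na, nb, phi[i]), numeric(1))

  # normalized means with pseudo-fraction 0.125 per library
  prior <- 0.125 * eff_lib / mean(eff_lib)
  padded <- sweep(sub, 2, prior, "+")
  rate_a <- rowSums(padded[, subgroups == "a", drop = FALSE]) /
    sum(eff_lib[subgroups == "a"])
  rate_b <- rowSums(padded[, subgroups == "b", drop = FALSE]) /
    sum(eff_lib[subgroups == "b"])
  logFC <- log2(rate_b / rate_a)
  zero_both <- sa + sb == 0
  logFC[zero_both] <- 0

  mean_a <- rowMeans(sweep(sub[, subgroups == "a", drop = FALSE], 2,
                           eff_lib[subgroups == "a"] / mean(eff_lib), "/"))
  mean_b <- rowMeans(sweep(sub[, subgroups == "b", drop = FALSE], 2,
                           eff_lib[subgroups == "b"] / mean(eff_lib), "/"))

  structure(data.frame(gene_id = rownames(sub), logFC = logFC, p_value = p,
                       mean_a = mean_a, mean_b = mean_b, dispersion = phi,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"),
            contrast = c(group_a, group_b))
}

#' Call differential expression from fold-change and P-value thresholds
#'
#' A gene is called `up` when its log2 fold change is at least
#' `log2(fold_threshold)` and its P-value at most `p_threshold` (both
#' thresholds inclusive); `down` symmetrically; otherwise `ns`.
#'
#' @param results a [exact_test()] result (or any data.frame with `logFC`
#'   and `p_value`).
#' @param fold_threshold minimum fold change (default 2).
#' @param p_threshold maximum P-value (default 0.01).
#' @return character vector of calls in `{"up", "down", "ns"}`, named by
#'   gene id when available.
#' @export
de_filter <- function(results, fold_threshold = 2, p_threshold = 0.01) {
  if (fold_threshold <= 0 || p_threshold <= 0) stop("thresholds must be positive")
  lfc <- log2(fold_threshold)
  call <- ifelse(results$logFC >= lfc & results$p_value <= p_threshold, "up",
          ifelse(results$logFC <= -lfc & results$p_value <= p_threshold, "down",
                 "ns"))
  if (!is.null(results$gene_id)) names(call) <- results$gene_id
  call
}
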