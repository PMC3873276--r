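#' Two-tailed Wilcoxon rank sum test between two genotypes
#'
#' Wraps the two-sided Wilcoxon rank sum (Mann-Whitney) test with an explicit
#' exact/approximate policy: the null distribution is enumerated exactly when
#' the smaller sample has at most 10 observations and the pooled data carry
#' no ties; otherwise the normal approximation with tie-corrected variance
#' and continuity correction 0.5 is used.
#'
#' @param x,y numeric samples (both non-empty).
#' @param mode `"auto"` (the policy above), `"exact"`, or `"normal"`.
#' @return object of class `pheno_test`: list with `statistic` (W),
#'   `p_value`, `method`, `n` (per-group sizes), `stars`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = min(length(x), length(y)) <= 10 && !ties)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  p <- min(wt$p.value, 1)
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 method = "wilcoxon",
                 exact = use_exact,
                 n = c(length(x), length(y)),
                 stars = stars(p)),
            class = "pheno_test")
}

#' Kruskal-Wallis rank analysis of variance across genotypes
#'
#' H statistic with tie correction, referred to a chi-squared distribution
#' with k - 1 degrees of freedom. The fully degenerate case (all
#' observations identical, where the tie correction denominator vanishes) is
#' defined as H = 0, p = 1.
#'
#' @param groups list of at least 2 numeric samples.
#' @return object of class `pheno_test` (statistic = H).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  n <- lengths(groups)
  if (sum(n) < 3) stop("need at least 3 observations in total")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) {
    st <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(pooled, factor(rep(seq_along(groups), n)))
    st <- unname(kt$statistic); p <- kt$p.value
  }
  structure(list(statistic = st, p_value = p, method = "kruskal_wallis",
                 n = unname(n), stars = stars(p)),
            class = "pheno_test")
}

#' Significance stars for a P-value
#'
#' The banding used throughout the architecture figures: `***` for
#' P < 0.001, `**` for P < 0.01, `*` for P < 0.05 (all strict), `ns`
#' otherwise.
#'
#' @param p probability in \[0, 1\].
#' @return one of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
stars <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.pheno_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g %s (n = %s)\n",
              x$method, x$statistic, x$p_value, x$stars,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Summarize shoot-architecture traits by genotype, with rank-based tests
#'
#' For every trait: per-genotype mean, sample (n-1) standard deviation (NA,
#' not zero, for singleton groups) and n; all pairwise two-tailed Wilcoxon
#' rank sum tests between genotypes; and a Kruskal-Wallis test across all
#' genotypes (when there are at least two). Rows of the phenotype table with
#' a missing trait value (e.g. sympodial units that never formed) are
#' dropped per trait.
#'
#' @param pt a phenotype table: data.frame with a `genotype` column and
#'   numeric trait columns (as from [simulate_architecture()]).
#' @param traits trait column names; defaults to every numeric column.
#' @return list of class `trait_summary`: `summary` (data.frame: trait,
#'   genotype, mean, sd, n), `pairwise` (data.frame: trait, group_a,
#'   group_b, n_a, n_b, statistic, p_value, stars), `kruskal` (data.frame:
#'   trait, statistic, p_value, stars).
#' @export
trait_summary <- function(pt, traits = NULL) {
  if (is.null(traits))
    traits <- names(pt)[vapply(pt, is.numeric, logical(1))]
  genotypes <- unique(pt$genotype)
  if (length(genotypes) < 1) stop("phenotype table has no genotypes")

  summ <- do.call(rbind, lapply(traits, function(tr) {
    do.call(rbind, lapply(genotypes, function(g) {
      v <- pt[[tr]][pt$genotype == g]
      v <- v[!is.na(v)]
      data.frame(trait = tr, genotype = g,
                 mean = if (length(v) > 0) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n = length(v))
    }))
  }))

  pw <- NULL
  kw <- NULL
  if (length(genotypes) >= 2) {
    pairs <- utils::combn(genotypes, 2)
    pw <- do.call(rbind, lapply(traits, function(tr) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        a <- pt[[tr]][pt$genotype == pairs[1, j]]
        b <- pt[[tr]][pt$genotype == pairs[2, j]]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) == 0 || length(b) == 0) {
          wt <- list(statistic = NA_real_, p_value = NA_real_,
                     stars = NA_character_)
        } else {
          wt <- wilcoxon_rank_sum(a, b)
        }
        data.frame(trait = tr, group_a = pairs[1, j], group_b = pairs[2, j],
                   n_a = length(a), n_b = length(b),
                   statistic = wt$statistic, p_value = wt$p_value,
                   stars = wt$stars)
      }))
    }))
    kw <- do.call(rbind, lapply(traits, function(tr) {
      gl <- lapply(genotypes, function(g) {
        v <- pt[[tr]][pt$genotype == g]; v[!is.na(v)]
      })
      gl <- gl[lengths(gl) > 0]
      if (length(gl) < 2 || sum(lengths(gl)) < 3) {
        kt <- list(statistic = NA_real_, p_value = NA_real_,
                   stars = NA_character_)
      } else {
        kt <- kruskal_wallis(gl)
      }
      data.frame(trait = tr, statistic = kt$statistic, p_value = kt$p_value,
                 stars = kt$stars)
    }))
  }
  structure(list(summary = summ, pairwise = pw, kruskal = kw),
            class = "trait_summary")
}

#' @export
print.trait_summary <- function(x, ...) {
  cat("trait_summary\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\npairwise Wilcoxon rank sum tests:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
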