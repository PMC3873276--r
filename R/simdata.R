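#' @keywords internal
"_PACKAGE"

# Negative-binomial draw with variance mu + phi * mu^2; phi = 0 is Poisson.
rnb <- function(n, mu, phi) {
  if (length(phi) == 1) phi <- rep(phi, length.out = length(mu))
  out <- numeric(length(mu))
  pois <- phi < 1e-12
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / phi[!pois],
                                               mu = mu[!pois])
  out
}

# Expected count from an RPKM-scale mean: unbiased inverse of rpkm() at
# large counts.
expected_count <- function(rpkm_mean, length_bp, library_size) {
  rpkm_mean * (length_bp / 1e3) * (library_size / 1e6)
}

draw_gene_lengths <- function(n) {
  round(exp(stats::runif(n, log(300), log(5000))))
}

#' Simulate a staged meristem maturation atlas
#'
#' Generates a count matrix emulating a multi-stage shoot meristem maturation
#' atlas (default stages EVM, MVM, LVM, TM, FM: early/middle/late vegetative,
#' transition and flower meristem) with a known set of stage-peaked marker
#' genes, negative-binomial count noise, and replicate samples per stage.
#' Marker genes have their true mean expression strictly maximal at their
#' assigned stage (peak RPKM uniform in \[20, 100\], off-stage means at a
#' 3--6 fold lower level); background genes are flat across stages with
#' log-normal levels. Gene lengths are drawn log-uniform in \[300, 5000\] bp
#' so that length normalization is exercised non-trivially.
#'
#' @param n_genes total number of genes; must be at least
#'   `markers_per_stage * length(stage_labels)`.
#' @param stage_labels ordered character vector of stage identifiers (>= 2).
#' @param markers_per_stage number of true marker genes per stage.
#' @param replicates samples per stage; at least 2, because the DDI workflow
#'   needs one calibration replicate and one boundary-setting replicate.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param library_size expected total mapped reads per sample.
#' @param seed integer RNG seed (`set.seed`); `NULL` leaves the RNG alone.
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (class `atlas_truth`: `stage_labels`, `marker_assignment` named by gene,
#'   `base_expression` gene x stage RPKM means, `dispersion`, `gene_lengths`).
#' @export
simulate_atlas <- function(n_genes, stage_labels = c("EVM", "MVM", "LVM", "TM", "FM"),
                           markers_per_stage = 50, replicates = 2,
                           dispersion = 0.05, library_size = 2e6, seed = NULL) {
  n_stages <- length(stage_labels)
  if (n_stages < 2) stop("need at least 2 stages")
  if (n_genes <= 0 || markers_per_stage <= 0 || library_size <= 0)
    stop("sizes must be positive")
  if (replicates < 2)
    stop("replicates must be >= 2 (one calibration and one boundary replicate)")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (markers_per_stage * n_stages > n_genes)
    stop("markers_per_stage * number of stages exceeds n_genes")
  if (!is.null(seed)) set.seed(seed)

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  lengths <- stats::setNames(draw_gene_lengths(n_genes), gene_ids)

  n_markers <- markers_per_stage * n_stages
  marker_stage <- rep(stage_labels, each = markers_per_stage)
  names(marker_stage) <- gene_ids[seq_len(n_markers)]

  # background genes drift mildly across stages (log-normal per stage around
  # a gene-level baseline), so profiles vary without being stage-specific;
  # marker genes follow unimodal developmental waves: expression peaks at the
  # assigned stage and decays geometrically with distance from it, with
  # independent rise and fall rates (3-6 fold per stage) so that no two
  # stages of a marker's profile coincide
  level <- exp(stats::rnorm(n_genes, log(5), 1.2))
  base <- matrix(level * exp(stats::rnorm(n_genes * n_stages, 0, 0.25)),
                 n_genes, n_stages, dimnames = list(gene_ids, stage_labels))
  peak <- stats::runif(n_markers, 20, 100)
  decay_l <- stats::runif(n_markers, 3, 6)
  decay_r <- stats::runif(n_markers, 3, 6)
  for (i in seq_len(n_markers)) {
    s <- match(marker_stage[i], stage_labels)
    k <- seq_len(n_stages)
    base[i, ] <- peak[i] / (decay_l[i]^pmax(s - k, 0) * decay_r[i]^pmax(k - s, 0))
  }

  sample_ids <- paste0(rep(stage_labels, each = replicates), "_r",
                       rep(seq_len(replicates), n_stages))
  counts <- matrix(0, n_genes, length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    s <- rep(stage_labels, each = replicates)[j]
    mu <- expected_count(base[, s], lengths, library_size)
    counts[, j] <- rnb(n_genes, mu, dispersion)
  }
  metadata <- data.frame(sample = sample_ids, genotype = "WT", tissue = "meristem",
                         stage = rep(stage_labels, each = replicates),
                         replicate = rep(seq_len(replicates), n_stages))
  truth <- structure(list(stage_labels = stage_labels,
                          marker_assignment = marker_stage,
                          base_expression = base,
                          dispersion = dispersion,
                          gene_lengths = lengths),
                     class = "atlas_truth")
  list(counts = count_matrix(counts, lengths, metadata), truth = truth)
}

#' Simulate an unknown sample at an intermediate maturation position
#'
#' Draws one count vector for a sample lying at a continuous `position` along
#' the atlas stage axis. In `interpolated` mode every gene's true mean is the
#' linear blend `(1 - lambda) * stage_floor + lambda * stage_ceiling` of the
#' two flanking stage profiles (lambda = fractional part of `position`). In
#' `mixed` mode each marker gene's mean is instead copied wholesale from one
#' of the two flanking stages, chosen independently per gene with probability
#' lambda for the upper stage — emulating a tissue in a mixed maturation
#' state whose score distribution shows multiple peaks; non-marker genes are
#' interpolated.
#'
#' @param truth an `atlas_truth` object from [simulate_atlas()].
#' @param position real in `[1, S]` where `S` is the number of stages.
#' @param mode `"interpolated"` or `"mixed"`.
#' @param library_size expected total mapped reads.
#' @param seed integer RNG seed, or `NULL`.
#' @return list with `counts` (named integer vector), `position`, `mode`.
#' @export
simulate_unknown <- function(truth, position, mode = c("interpolated", "mixed"),
                             library_size = 2e6, seed = NULL) {
  mode <- match.arg(mode)
  n_stages <- length(truth$stage_labels)
  if (position < 1 || position > n_stages)
    stop(sprintf("position must lie in [1, %d]", n_stages))
  if (!is.null(seed)) set.seed(seed)

  lo <- floor(position)
  hi <- min(lo + 1, n_stages)
  lam <- position - lo
  base <- truth$base_expression
  mean_rpkm <- (1 - lam) * base[, lo] + lam * base[, hi]
  if (mode == "mixed" && lam > 0) {
    mk <- names(truth$marker_assignment)
    take_hi <- stats::runif(length(mk)) < lam
    mean_rpkm[mk] <- ifelse(take_hi, base[mk, hi], base[mk, lo])
  }
  mu <- expected_count(mean_rpkm, truth$gene_lengths, library_size)
  counts <- stats::setNames(rnb(length(mu), mu, truth$dispersion), rownames(base))
  list(counts = counts, position = position, mode = mode)
}

#' The 12 gene-action categories
#'
#' The deterministic map from the three contrast calls (heterozygote vs
#' parent 1, heterozygote vs parent 2, parent 1 vs parent 2; a call `"up"`
#' for contrast X-vs-Y means X is expressed above Y) to the 12 gene-action
#' categories and their five major classes. Patterns not in the table —
#' internally inconsistent ones, or parents-differ-only patterns in which the
#' heterozygote is indistinguishable from both parents — are unclassified.
#'
#' @return data.frame with columns `category`, `class`, `call_hp1`,
#'   `call_hp2`, `call_p1p2`.
#' @export
gene_action_categories <- function() {
  data.frame(
    category = 1:12,
    class = c("additive", "additive", "dominant", "dominant",
              "recessive", "recessive",
              "overdominant", "overdominant", "overdominant",
              "underdominant", "underdominant", "underdominant"),
    call_hp1 = c("up", "down", "ns", "ns", "up", "down",
                 "up", "up", "up", "down", "down", "down"),
    call_hp2 = c("down", "up", "up", "down", "ns", "ns",
                 "up", "up", "up", "down", "down", "down"),
    call_p1p2 = c("down", "up", "up", "down", "down", "up",
                  "ns", "down", "up", "ns", "down", "up"),
    stringsAsFactors = FALSE)
}

# True mean triple (P1, P2, H) realizing a category's ordering with adjacent
# fold separation f around baseline b.
category_means <- function(category, b, f) {
  switch(category,
         c(b, b * f^2, b * f),        # 1 additive, P1 < H < P2
         c(b * f^2, b, b * f),        # 2 additive, P2 < H < P1
         c(b * f, b, b * f),          # 3 dominant, H ~ P1 > P2
         c(b, b * f, b),              # 4 dominant, H ~ P1 < P2
         c(b, b * f, b * f),          # 5 recessive, H ~ P2 > P1
         c(b * f, b, b),              # 6 recessive, H ~ P2 < P1
         c(b, b, b * f),              # 7 overdominant, parents equal
         c(b, b * f, b * f^2),        # 8 overdominant, P1 < P2
         c(b * f, b, b * f^2),        # 9 overdominant, P1 > P2
         c(b * f, b * f, b),          # 10 underdominant, parents equal
         c(b * f, b * f^2, b),        # 11 underdominant, P1 < P2
         c(b * f^2, b * f, b))        # 12 underdominant, P1 > P2
}

#' Simulate a parent/parent/heterozygote expression trio
#'
#' Generates counts for two homozygous parental genotypes and their
#' single-gene heterozygote with a known per-gene gene-action category.
#' Genes outside any category have equal true means across genotypes;
#' category genes realize the category's ordering pattern with adjacent
#' groups separated by `effect_size` fold (see [gene_action_categories()]).
#'
#' @param n_genes number of genes.
#' @param category_fractions 12 non-negative fractions (one per category)
#'   summing to at most 1; the remainder of genes are null.
#' @param effect_size fold change between adjacent expression levels; must
#'   exceed 2 so truth is recoverable past the 2-fold classification
#'   threshold.
#' @param replicates libraries per genotype (>= 2).
#' @param dispersion negative-binomial dispersion phi.
#' @param library_size expected total mapped reads per library.
#' @param genotypes names for (parent 1, parent 2, heterozygote); defaults
#'   mirror a determinate tomato cross (sp, sft sp, sft/+ sp).
#' @param seed integer RNG seed, or `NULL`.
#' @return list with `counts` (a [count_matrix()]) and `truth` (class
#'   `trio_truth`: `category_per_gene` (NA for null genes), `class_per_gene`,
#'   `mean_expression` gene x 3 RPKM means).
#' @export
simulate_trio <- function(n_genes, category_fractions = rep(0.01, 12),
                          effect_size = 4, replicates = 3, dispersion = 0.05,
                          library_size = 2e6,
                          genotypes = c("sp", "sft_sp", "sft_het_sp"),
                          seed = NULL) {
  if (n_genes <= 0 || replicates < 2) stop("need n_genes > 0 and replicates >= 2")
  if (length(category_fractions) != 12 || any(category_fractions < 0))
    stop("category_fractions must be 12 non-negative values")
  if (sum(category_fractions) > 1) stop("category_fractions sum to more than 1")
  if (effect_size <= 2)
    stop("effect_size must exceed the 2-fold classification threshold")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  lengths <- stats::setNames(draw_gene_lengths(n_genes), gene_ids)
  n_cat <- round(category_fractions * n_genes)
  category <- rep(NA_integer_, n_genes)
  idx <- 1
  for (k in 1:12) {
    if (n_cat[k] > 0) {
      category[idx:(idx + n_cat[k] - 1)] <- k
      idx <- idx + n_cat[k]
    }
  }
  base <- exp(stats::rnorm(n_genes, log(20), 0.8))
  means <- matrix(0, n_genes, 3, dimnames = list(gene_ids, genotypes))
  for (i in seq_len(n_genes)) {
    means[i, ] <- if (is.na(category[i])) rep(base[i], 3)
                  else category_means(category[i], base[i], effect_size)
  }

  cats <- gene_action_categories()
  class_per_gene <- ifelse(is.na(category), NA_character_,
                           cats$class[category])
  sample_ids <- paste0(rep(genotypes, each = replicates), "_r",
                       rep(seq_len(replicates), 3))
  counts <- matrix(0, n_genes, length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    g <- rep(genotypes, each = replicates)[j]
    mu <- expected_count(means[, g], lengths, library_size)
    counts[, j] <- rnb(n_genes, mu, dispersion)
  }
  metadata <- data.frame(sample = sample_ids,
                         genotype = rep(genotypes, each = replicates),
                         tissue = "leaf", stage = "L6",
                         replicate = rep(seq_len(replicates), 3))
  truth <- structure(list(category_per_gene = stats::setNames(category, gene_ids),
                          class_per_gene = stats::setNames(class_per_gene, gene_ids),
                          mean_expression = means),
                     class = "trio_truth")
  list(counts = count_matrix(counts, lengths, metadata), truth = truth)
}

#' Parameters for a genotype's shoot architecture model
#'
#' Describes the sympodial growth habit of one genotype. The primary shoot
#' produces a uniform number of leaves within `primary_leaf_range` before the
#' first inflorescence (7--9 in wild-type tomato). Successive sympodial units
#' then carry Poisson-distributed leaf counts with expectations
#' `unit_leaf_means + delay_shift`; beyond the supplied vector the expected
#' counts continue the last linear decrement (floored at 0). Growth ends when
#' a unit draws 0 leaves (determinate termination: two juxtaposed
#' inflorescences) or at `max_units` sympodial units (indeterminate).
#' `delay_shift` models a dosage delay of sympodial flowering, as caused by
#' florigen-mutant heterozygosity in a determinate background.
#'
#' @param primary_leaf_range inclusive integer interval, lower bound >= 1.
#' @param unit_leaf_means expected leaves per successive sympodial unit;
#'   non-increasing for determinate genotypes.
#' @param delay_shift non-negative real added to every unit's expectation.
#' @param max_units indeterminate cap on sympodial units.
#' @return object of class `architecture_params`.
#' @export
architecture_params <- function(primary_leaf_range = c(7, 9),
                                unit_leaf_means = c(3, 2, 1),
                                delay_shift = 0, max_units = 10) {
  if (primary_leaf_range[1] < 1) stop("primary_leaf_range lower bound must be >= 1")
  if (delay_shift < 0) stop("delay_shift must be non-negative")
  structure(list(primary_leaf_range = primary_leaf_range,
                 unit_leaf_means = unit_leaf_means,
                 delay_shift = delay_shift, max_units = max_units),
            class = "architecture_params")
}

unit_mean_at <- function(p, i) {
  m <- length(p$unit_leaf_means)
  mu <- if (i <= m) p$unit_leaf_means[i]
        else if (m == 1) p$unit_leaf_means[1]
        else p$unit_leaf_means[m] +
             (i - m) * (p$unit_leaf_means[m] - p$unit_leaf_means[m - 1])
  max(mu, 0) + p$delay_shift
}

#' Simulate per-plant shoot architecture tables
#'
#' Draws a phenotype table (one row per plant) for a set of genotypes, each
#' described by [architecture_params()]. Traits recorded per plant:
#' `leaves_primary` (leaves on the primary shoot before the first
#' inflorescence), `leaves_unit_1..3` (leaves in the first three sympodial
#' units; NA where growth terminated earlier), `sympodial_units`,
#' `inflorescences` (= sympodial units + 1, counting the primary
#' inflorescence).
#'
#' @param params named list of [architecture_params()], one per genotype.
#' @param n_plants plants per genotype.
#' @param seed integer RNG seed, or `NULL`.
#' @return data.frame of class `phenotype_table`.
#' @export
simulate_architecture <- function(params, n_plants = 30, seed = NULL) {
  if (length(params) == 0) stop("empty genotype set")
  if (is.null(names(params)) || any(names(params) == ""))
    stop("params must be a named list (names = genotypes)")
  if (n_plants < 1) stop("n_plants must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  for (g in names(params)) {
    p <- params[[g]]
    for (k in seq_len(n_plants)) {
      primary <- sample(p$primary_leaf_range[1]:p$primary_leaf_range[2], 1)
      unit_leaves <- integer(0)
      i <- 1
      repeat {
        leaves <- stats::rpois(1, unit_mean_at(p, i))
        if (leaves == 0) break        # determinate termination
        unit_leaves <- c(unit_leaves, leaves)
        if (i >= p$max_units) break   # indeterminate cap
        i <- i + 1
      }
      u <- length(unit_leaves)
      rows[[length(rows) + 1]] <- data.frame(
        plant = sprintf("%s_p%03d", g, k), genotype = g,
        leaves_primary = primary,
        leaves_unit_1 = if (u >= 1) unit_leaves[1] else NA_integer_,
        leaves_unit_2 = if (u >= 2) unit_leaves[2] else NA_integer_,
        leaves_unit_3 = if (u >= 3) unit_leaves[3] else NA_integer_,
        sympodial_units = u,
        inflorescences = u + 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}
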