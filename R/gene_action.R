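#' Classify genes into the 12 gene-action categories
#'
#' Maps each gene's three trinary contrast calls — heterozygote vs parent 1,
#' heterozygote vs parent 2, and parent 1 vs parent 2, where a call `"up"`
#' for contrast X-vs-Y means X is expressed above Y — onto the 12 gene-action
#' categories grouped in five major classes: additive (heterozygote strictly
#' between two differing parents), dominant (heterozygote matches parent 1),
#' recessive (matches parent 2), overdominant (above both parents) and
#' underdominant (below both). Patterns with no consistent ordering, with no
#' significant contrast, or where the heterozygote is indistinguishable from
#' both parents are left unclassified. The mapping table is
#' [gene_action_categories()].
#'
#' @param calls data.frame with columns `call_hp1`, `call_hp2`, `call_p1p2`
#'   (values in `up`/`down`/`ns`), and optionally `gene_id`.
#' @return data.frame of class `gene_action_table` with columns `gene_id`,
#'   the three calls, `category` (integer 1--12 or NA) and `class`.
#' @export
classify_gene_action <- function(calls) {
  req <- c("call_hp1", "call_hp2", "call_p1p2")
  if (!all(req %in% names(calls)))
    stop("calls must have columns call_hp1, call_hp2, call_p1p2")
  for (cl in req) {
    bad <- setdiff(unique(calls[[cl]]), c("up", "down", "ns"))
    if (length(bad) > 0)
      stop("unknown call symbol(s) in ", cl, ": ", paste(bad, collapse = ", "))
  }
  map <- gene_action_categories()
  key <- function(a, b, c) paste(a, b, c, sep = "|")
  lookup <- stats::setNames(map$category,
                            key(map$call_hp1, map$call_hp2, map$call_p1p2))
  category <- unname(lookup[key(calls$call_hp1, calls$call_hp2, calls$call_p1p2)])
  cls <- ifelse(is.na(category), NA_character_, map$class[category])
  out <- data.frame(
    gene_id = if (!is.null(calls$gene_id)) calls$gene_id
              else sprintf("gene%d", seq_len(nrow(calls))),
    call_hp1 = calls$call_hp1, call_hp2 = calls$call_hp2,
    call_p1p2 = calls$call_p1p2,
    category = category, class = cls,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_action_table", "data.frame")
  out
}

#' Run the full gene-action analysis on a parent/parent/heterozygote trio
#'
#' Orchestrates the differential-expression stack over the three pairwise
#' contrasts (heterozygote vs each parent, parent vs parent): TMM
#' normalization, tagwise dispersion estimation, exact negative-binomial
#' tests, thresholding at `fold_threshold` and `p_threshold`, then
#' [classify_gene_action()]. Parent 1 anchors the "dominant" class (the
#' functional-allele parent) and parent 2 the "recessive" class.
#'
#' @param cm a [count_matrix()] holding the three genotypes, each with at
#'   least 2 replicates.
#' @param p1,p2,het genotype labels for parent 1, parent 2 and the
#'   heterozygote.
#' @param fold_threshold,p_threshold passed to [de_filter()].
#' @param prior_weight tagwise shrinkage weight for
#'   [estimate_dispersion()].
#' @return list of class `gene_action_result`: `table` (the
#'   [classify_gene_action()] output), `summary` (per-category and
#'   per-class counts with percentages over classified genes, plus `n_de`,
#'   the number of genes with at least one significant contrast),
#'   `de_results` (the three [exact_test()] frames), `dispersion`.
#' @export
run_trio <- function(cm, p1 = "sp", p2 = "sft_sp", het = "sft_het_sp",
                     fold_threshold = 2, p_threshold = 0.01,
                     prior_weight = 10) {
  groups <- cm$metadata$genotype
  for (g in c(p1, p2, het)) {
    if (sum(groups == g) < 2)
      stop(sprintf("genotype '%s' needs at least 2 replicates", g))
  }
  keep <- groups %in% c(p1, p2, het)
  sub <- count_matrix(cm$counts[, keep, drop = FALSE], cm$gene_lengths,
                      cm$metadata[keep, , drop = FALSE])
  factors <- tmm_factors(sub)
  disp <- estimate_dispersion(sub, factors = factors, prior_weight = prior_weight)

  de_hp1 <- exact_test(sub, p1, het, factors = factors, dispersion = disp$tagwise)
  de_hp2 <- exact_test(sub, p2, het, factors = factors, dispersion = disp$tagwise)
  de_p12 <- exact_test(sub, p2, p1, factors = factors, dispersion = disp$tagwise)

  calls <- data.frame(gene_id = de_hp1$gene_id,
                      call_hp1 = de_filter(de_hp1, fold_threshold, p_threshold),
                      call_hp2 = de_filter(de_hp2, fold_threshold, p_threshold),
                      call_p1p2 = de_filter(de_p12, fold_threshold, p_threshold),
                      stringsAsFactors = FALSE)
  tab <- classify_gene_action(calls)
  structure(list(table = tab,
                 summary = summarize_gene_action(tab),
                 de_results = list(h_vs_p1 = de_hp1, h_vs_p2 = de_hp2,
                                   p1_vs_p2 = de_p12),
                 dispersion = disp,
                 genotypes = c(p1 = p1, p2 = p2, het = het)),
            class = "gene_action_result")
}

#' Summarize a gene-action table into category and class proportions
#'
#' @param tab a [classify_gene_action()] result.
#' @return list with `categories` (data.frame: category, class, count,
#'   percent of classified genes), `classes` (per-class totals), `n_de`
#'   (genes with >= 1 significant contrast), `n_classified`.
#' @export
summarize_gene_action <- function(tab) {
  map <- gene_action_categories()
  n_de <- sum(tab$call_hp1 != "ns" | tab$call_hp2 != "ns" | tab$call_p1p2 != "ns")
  counts <- vapply(map$category, function(k) sum(tab$category == k, na.rm = TRUE),
                   numeric(1))
  n_cls <- sum(counts)
  cat_df <- data.frame(category = map$category, class = map$class, count = counts,
                       percent = if (n_cls > 0) 100 * counts / n_cls else NA_real_)
  cls_df <- stats::aggregate(cbind(count, percent) ~ class, cat_df, sum)
  list(categories = cat_df, classes = cls_df, n_de = n_de, n_classified = n_cls)
}

#' @export
print.gene_action_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("gene_action_result: %d genes, %d with >= 1 significant contrast, %d classified\n",
              nrow(x$table), s$n_de, s$n_classified))
  print(s$classes, row.names = FALSE)
  invisible(x)
}

#' Compare gene-action category proportions between two tissues
#'
#' For each of the 12 categories, builds the 2x2 table (in-category vs not,
#' tissue A vs tissue B) over classified genes and reports the two-sided
#' Fisher exact test P-value.
#'
#' @param summary_a,summary_b [summarize_gene_action()] results (integer
#'   counts are required, not only percentages).
#' @return data.frame with columns `category`, `class`, `count_a`,
#'   `count_b`, `p_value`.
#' @export
compare_tissues <- function(summary_a, summary_b) {
  if (summary_a$n_classified == 0 || summary_b$n_classified == 0)
    stop("both tissues must have at least one classified gene")
  ca <- summary_a$categories; cb <- summary_b$categories
  p <- vapply(seq_len(nrow(ca)), function(i) {
    m <- matrix(c(ca$count[i], summary_a$n_classified - ca$count[i],
                  cb$count[i], summary_b$n_classified - cb$count[i]), nrow = 2)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(category = ca$category, class = ca$class,
             count_a = ca$count, count_b = cb$count, p_value = p)
}
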