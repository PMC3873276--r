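#' Select stage-peaked marker genes from a staged calibration set
#'
#' The calibration step of the Digital Differentiation Index (DDI): given one
#' replicate's RPKM profile per ordered maturation stage, a gene becomes a
#' marker for the stage at which its expression is the unique maximum,
#' provided the peak clears an absolute RPKM floor and exceeds the
#' second-highest stage by a specificity fold margin.
#'
#' @param calibration_expr RPKM matrix, genes x stages, one column per stage
#'   in maturation order (a single calibration replicate).
#' @param min_expression RPKM floor the peak must reach (default 5).
#' @param specificity_fold required ratio of peak to second-best stage
#'   (default 1.5, must be >= 1).
#' @return object of class `marker_set`: a data.frame with columns `gene_id`,
#'   `peak_stage`, `peak_index`, `peak_rpkm`, `second_rpkm`; attributes
#'   `stage_labels`, `selection_params`, `calibration_expr` (marker rows
#'   only) and `warnings` (stages left without markers).
#' @export
select_markers <- function(calibration_expr, min_expression = 5,
                           specificity_fold = 1.5) {
  if (ncol(calibration_expr) < 2) stop("need at least 2 calibration stages")
  if (specificity_fold < 1) stop("specificity_fold must be >= 1")
  stages <- colnames(calibration_expr)
  if (is.null(stages)) stages <- paste0("stage", seq_len(ncol(calibration_expr)))

  peak_idx <- max.col(calibration_expr, ties.method = "first")
  peak <- calibration_expr[cbind(seq_len(nrow(calibration_expr)), peak_idx)]
  second <- apply(calibration_expr, 1, function(x) max(x[-which.max(x)]))
  unique_max <- peak > second
  keep <- unique_max & peak >= min_expression & peak >= specificity_fold * second

  ms <- data.frame(gene_id = rownames(calibration_expr)[keep],
                   peak_stage = stages[peak_idx[keep]],
                   peak_index = peak_idx[keep],
                   peak_rpkm = peak[keep],
                   second_rpkm = second[keep],
                   stringsAsFactors = FALSE)
  rownames(ms) <- NULL
  empty <- setdiff(stages, ms$peak_stage)
  warn <- if (length(empty) > 0)
    sprintf("no markers selected for stage(s): %s", paste(empty, collapse = ", "))
  else character(0)
  structure(ms, class = c("marker_set", "data.frame"),
            stage_labels = stages,
            selection_params = list(min_expression = min_expression,
                                    specificity_fold = specificity_fold),
            calibration_expr = calibration_expr[keep, , drop = FALSE],
            warnings = warn)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers over %d stages\n",
              nrow(x), length(attr(x, "stage_labels"))))
  print(table(factor(x$peak_stage, levels = attr(x, "stage_labels"))))
  for (w in attr(x, "warnings")) cat("warning:", w, "\n")
  invisible(x)
}

#' Write a marker set as a tab-separated table
#'
#' @param markers a [select_markers()] result.
#' @param path output TSV path (columns gene_id, peak_stage, peak_rpkm,
#'   second_rpkm).
#' @return invisibly, `markers`.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers[, c("gene_id", "peak_stage", "peak_rpkm", "second_rpkm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(markers)
}

#' Score the maturation state of an unknown sample
#'
#' For every marker gene, the maturation score is the index of the
#' calibration stage whose log-scale expression is nearest the unknown's:
#' the stage s minimizing `|log2(u + 1) - log2(C[g, s] + 1)|` (ties resolved
#' toward the earlier, less mature stage). The per-marker scores form a
#' distribution whose mean summarizes the sample's maturation state and
#' whose Gaussian kernel density (Silverman bandwidth, 512-point grid on
#' `[0.5, S + 0.5]`) is the maturation curve; multiple density peaks indicate
#' a mixed maturation state.
#'
#' @param markers a [select_markers()] result.
#' @param calibration_expr RPKM matrix, genes x stages, covering all marker
#'   genes (defaults to the expression stored in `markers`).
#' @param unknown_expr named RPKM vector covering all marker genes.
#' @param sample_id label for the prediction.
#' @return object of class `maturation_prediction`: list with `sample_id`,
#'   `per_marker_score` (named vector of stage indices), `mean_score`,
#'   `density` (list `grid`, `values`), `stage_labels`.
#' @export
score_sample <- function(markers, calibration_expr = attr(markers, "calibration_expr"),
                         unknown_expr, sample_id = "unknown") {
  stages <- attr(markers, "stage_labels")
  if (is.matrix(unknown_expr)) {
    if (ncol(unknown_expr) != 1)
      stop("unknown_expr must be a single expression vector")
    unknown_expr <- stats::setNames(unknown_expr[, 1], rownames(unknown_expr))
  }
  absent <- setdiff(markers$gene_id, names(unknown_expr))
  if (length(absent) > 0)
    stop("marker gene(s) absent from unknown sample: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) sprintf(" (and %d more)", length(absent) - 5))
  absent_cal <- setdiff(markers$gene_id, rownames(calibration_expr))
  if (length(absent_cal) > 0)
    stop("marker gene(s) absent from calibration: ",
         paste(utils::head(absent_cal, 5), collapse = ", "))

  cal <- log2(calibration_expr[markers$gene_id, , drop = FALSE] + 1)
  u <- log2(unknown_expr[markers$gene_id] + 1)
  d <- abs(cal - u)
  score <- stats::setNames(apply(d, 1, which.min), markers$gene_id)  # first min: earlier stage
  mean_score <- mean(score)
  S <- length(stages)
  dens <- stats::density(score, bw = "nrd0", n = 512, from = 0.5, to = S + 0.5)
  structure(list(sample_id = sample_id,
                 per_marker_score = score,
                 mean_score = mean_score,
                 density = list(grid = dens$x, values = dens$y),
                 stage_labels = stages),
            class = "maturation_prediction")
}

#' @export
print.maturation_prediction <- function(x, ...) {
  cat(sprintf("maturation_prediction '%s': mean score %.3f over %d markers (stages: %s)\n",
              x$sample_id, x$mean_score, length(x$per_marker_score),
              paste(x$stage_labels, collapse = " < ")))
  invisible(x)
}

#' @export
plot.maturation_prediction <- function(x, ...) {
  plot(x$density$grid, x$density$values, type = "l",
       xlab = "maturation score", ylab = "density",
       main = sprintf("%s (mean %.2f)", x$sample_id, x$mean_score), ...)
  graphics::abline(v = seq_along(x$stage_labels), lty = 3, col = "grey60")
  graphics::axis(3, at = seq_along(x$stage_labels), labels = x$stage_labels)
  invisible(x)
}

# Two-sample equal-variance (Student's) t-test on score vectors, with
# degenerate cases defined: zero pooled variance gives p = 1 for equal means
# and the p floor otherwise.
student_t_p <- function(x, y, p_floor = 1e-300, p_cap = 1 - 1e-12) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  if (sp2 <= 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  } else {
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(-abs(t), df = nx + ny - 2)
  }
  min(max(p, p_floor), p_cap)
}

#' Per-stage similarity profile of an unknown prediction
#'
#' Quantifies how similar an unknown sample's maturation state is to each
#' calibration stage. For each stage a two-sample equal-variance Student's
#' t-test compares the unknown's per-marker maturation scores with the
#' stage's own prediction (from the held-out boundary replicate), giving a
#' P-value per stage; these are transformed to `1 / (-log10 P)` (P floored at
#' 1e-300 and capped below 1 so the transform is finite) and min-max scaled
#' across stages into \[0, 1\], so the most similar stage scores 1 and the
#' least similar 0. When all transformed values coincide every stage is
#' reported as 1.
#'
#' @param unknown_pred a [score_sample()] prediction for the unknown.
#' @param stage_preds list of [score_sample()] predictions, one per stage in
#'   stage order (typically of the held-out calibration replicate).
#' @return data.frame with columns `stage`, `p_value`, `scaled_similarity`.
#' @export
similarity_profile <- function(unknown_pred, stage_preds) {
  if (length(unknown_pred$per_marker_score) < 2)
    stop("need at least 2 markers for a similarity profile")
  genes <- names(unknown_pred$per_marker_score)
  for (sp in stage_preds) {
    if (!identical(names(sp$per_marker_score), genes))
      stop("all predictions must share one marker set")
  }
  p <- vapply(stage_preds, function(sp)
    student_t_p(unknown_pred$per_marker_score, sp$per_marker_score), numeric(1))
  v <- 1 / (-log10(p))
  scaled <- if (max(v) - min(v) <= 0) rep(1, length(v))
            else (v - min(v)) / (max(v) - min(v))
  data.frame(stage = unknown_pred$stage_labels[seq_along(stage_preds)],
             p_value = p, scaled_similarity = scaled,
             stringsAsFactors = FALSE)
}

#' Run the full DDI workflow on an atlas and a set of unknowns
#'
#' Orchestrates the complete maturation-staging analysis: RPKM-normalize the
#' atlas, select markers from one designated calibration replicate, predict
#' the held-out boundary replicate of every stage to set stage boundaries,
#' then average each unknown's replicates on the RPKM scale and compute its
#' maturation score distribution and per-stage similarity profile.
#'
#' @param atlas [count_matrix()] of the staged calibration samples; needs at
#'   least two replicates per stage.
#' @param unknowns [count_matrix()] of the query samples.
#' @param calibration_replicate replicate number used for marker selection.
#' @param boundary_replicate replicate treated as unknown to set stage
#'   boundaries.
#' @param min_expression,specificity_fold passed to [select_markers()].
#' @param group_by metadata keys over which unknown replicates are averaged.
#' @return object of class `ddi_report`: list with `markers`,
#'   `stage_predictions`, `unknowns` (per query: `prediction`, `similarity`),
#'   and `method` metadata recording the scoring variant in use.
#' @export
predict_batch <- function(atlas, unknowns, calibration_replicate = 1,
                          boundary_replicate = 2, min_expression = 5,
                          specificity_fold = 1.5,
                          group_by = c("genotype", "tissue", "stage")) {
  md <- atlas$metadata
  stage_order <- unique(md$stage)
  if (!all(table(md$stage) >= 2))
    stop("atlas needs at least 2 replicates per stage")
  em <- rpkm(atlas)
  cal_cols <- md$sample[md$replicate == calibration_replicate]
  bnd_cols <- md$sample[md$replicate == boundary_replicate]
  if (length(cal_cols) != length(stage_order) || length(bnd_cols) != length(stage_order))
    stop("calibration and boundary replicates must each cover every stage once")
  cal <- em[, cal_cols[match(stage_order, md$stage[match(cal_cols, md$sample)])],
            drop = FALSE]
  colnames(cal) <- stage_order
  bnd <- em[, bnd_cols[match(stage_order, md$stage[match(bnd_cols, md$sample)])],
            drop = FALSE]
  colnames(bnd) <- stage_order

  markers <- select_markers(cal, min_expression, specificity_fold)
  stage_preds <- lapply(stage_order, function(s)
    score_sample(markers, cal, bnd[, s], sample_id = paste0("boundary_", s)))
  names(stage_preds) <- stage_order

  uem <- summarize_replicates(rpkm(unknowns), unknowns$metadata, group_by)
  unknown_results <- lapply(colnames(uem), function(id) {
    pred <- score_sample(markers, cal, uem[, id], sample_id = id)
    list(prediction = pred, similarity = similarity_profile(pred, stage_preds))
  })
  names(unknown_results) <- colnames(uem)

  structure(list(markers = markers,
                 stage_predictions = stage_preds,
                 unknowns = unknown_results,
                 method = list(
                   score = "nearest calibration stage in log2(RPKM + 1), ties to earlier stage",
                   similarity = "equal-variance Student's t-test, scaled 1/(-log10 P)",
                   note = paste("maturation-score and marker-specificity rules are",
                                "this package's declared variants of the DDI scheme"))),
            class = "ddi_report")
}

#' @export
print.ddi_report <- function(x, ...) {
  cat(sprintf("ddi_report: %d markers, %d stages, %d unknown sample(s)\n",
              nrow(x$markers), length(x$stage_predictions), length(x$unknowns)))
  for (id in names(x$unknowns)) {
    u <- x$unknowns[[id]]
    best <- u$similarity$stage[which.max(u$similarity$scaled_similarity)]
    cat(sprintf("  %-28s mean score %.3f, most similar stage %s\n",
                id, u$prediction$mean_score, best))
  }
  invisible(x)
}

#' Write a DDI report as JSON
#'
#' Serializes per-unknown mean scores, per-stage P-values and scaled
#' similarities, and density curves, together with the method metadata.
#'
#' @param report a [predict_batch()] result.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_ddi_report <- function(report, path) {
  out <- list(
    method = report$method,
    n_markers = nrow(report$markers),
    stages = attr(report$markers, "stage_labels"),
    stage_boundaries = lapply(report$stage_predictions, function(p)
      list(mean_score = p$mean_score)),
    unknowns = lapply(report$unknowns, function(u)
      list(mean_score = u$prediction$mean_score,
           similarity = u$similarity,
           density = u$prediction$density)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Count local maxima of a maturation-score density curve
#'
#' A grid point is a local maximum when its density value exceeds both
#' neighbours; maxima below `min_height` times the global maximum are
#' ignored. Used to flag mixed maturation states (multi-peak curves).
#'
#' @param density list with `grid` and `values`, as in a
#'   [score_sample()] prediction.
#' @param min_height minimum peak height relative to the highest peak.
#' @return integer number of local maxima.
#' @export
density_peaks <- function(density, min_height = 0.1) {
  y <- density$values
  n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  sum(y[loc] >= min_height * max(y))
}
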