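# ROC/AUC, Hanley-McNeil comparison, top-fraction enrichment, and the
# gene-level cross-validation harness.

#' ROC curve and AUC by the rank (Mann-Whitney) statistic
#'
#' The AUC equals the probability that a random positive outranks a random
#' negative, with ties counted half — computed from midranks, which is
#' identical to the trapezoidal area under the tie-aware ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), same length.
#' @param class_name optional class name carried in the result.
#' @return object of class `roc_result`: `class`, `points` (data.frame
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, class_name = NA_character_) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("single-class labels for '", class_name, "': need >= 1 positive ",
         "and >= 1 negative")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # tie-aware ROC points: one vertex per distinct score, descending
  o <- order(scores, decreasing = TRUE)
  ys <- labels[o]; ss <- scores[o]
  last <- !duplicated(ss, fromLast = TRUE) # last index of each tie block
  tpr <- c(0, cumsum(ys)[last] / n_pos)
  fpr <- c(0, cumsum(1 - ys)[last] / n_neg)
  structure(list(class = class_name,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC%s: AUC %.4f (%d pos / %d neg)\n",
              if (is.na(x$class)) "" else paste0(" [", x$class, "]"),
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE(A) = sqrt((A(1-A) + (n+-1)(Q1-A^2) + (n--1)(Q2-A^2)) / (n+ n-))`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc area under the curve.
#' @param n_pos,n_neg class sizes.
#' @return standard error.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Compare two AUCs (Hanley-McNeil z-test)
#'
#' Uncorrelated two-sided z-test on the AUC difference; the
#' correlation-adjusted variant is available through `r` (the estimated
#' correlation between the two AUCs on the same cases).
#'
#' @param roc_a,roc_b `roc_result` objects on the same label sets.
#' @param r correlation between the AUC estimates (default 0, the
#'   uncorrelated form).
#' @return list with `z`, `p_value`, `se_a`, `se_b`.
#' @export
compare_auc <- function(roc_a, roc_b, r = 0) {
  stopifnot(roc_a$n_pos == roc_b$n_pos, roc_a$n_neg == roc_b$n_neg)
  se_a <- hanley_mcneil_se(roc_a$auc, roc_a$n_pos, roc_a$n_neg)
  se_b <- hanley_mcneil_se(roc_b$auc, roc_b$n_pos, roc_b$n_neg)
  denom <- sqrt(se_a^2 + se_b^2 - 2 * r * se_a * se_b)
  z <- if (denom == 0) 0 else (roc_a$auc - roc_b$auc) / denom
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), se_a = se_a, se_b = se_b)
}

#' Enrichment of positives among the top-ranked fraction
#'
#' Precision within the `ceiling(fraction * n)` highest-scoring items
#' divided by the overall prevalence (the random-classifier baseline).
#' Ties at the cutoff are broken by score, then by item id, for a
#' deterministic result.
#'
#' @param scores named numeric scores (names = item ids; unnamed items get
#'   positional ids).
#' @param labels binary labels, same order.
#' @param fraction top fraction in (0, 1\]; default 0.02.
#' @return enrichment ratio (1 = random).
#' @export
top_fraction_enrichment <- function(scores, labels, fraction = 0.02) {
  stopifnot(fraction > 0, fraction <= 1)
  labels <- as.integer(labels)
  n <- length(scores)
  prev <- mean(labels)
  if (prev == 0) stop("zero prevalence: enrichment undefined")
  ids <- names(scores)
  if (is.null(ids)) ids <- sprintf("item%08d", seq_len(n))
  k <- ceiling(fraction * n)
  o <- order(-scores, ids)
  (sum(labels[o[seq_len(k)]]) / k) / prev
}

#' Reproducible stratified fold assignment at the gene level
#'
#' Genes are ordered by decreasing rarity of their active classes and dealt
#' greedily to the currently smallest eligible fold, so positives of small
#' classes spread across all folds; fold sizes differ by at most 1.
#'
#' @param labels a `label_table` of gene labels.
#' @param k number of folds.
#' @param seed integer seed (assignment is a pure function of it).
#' @return named integer vector: gene id -> fold in `0:(k-1)`.
#' @export
make_folds <- function(labels, k, seed) {
  genes <- sort(unique(labels$entity_id))
  stopifnot(k >= 2L, k <= length(genes))
  set.seed(seed)
  genes <- sample(genes)                   # seed-reproducible shuffle
  act <- labels[labels$label == 1L, , drop = FALSE]
  class_size <- table(act$class)
  rarity <- vapply(genes, function(g) {
    cls <- act$class[act$entity_id == g]
    if (!length(cls)) Inf else min(class_size[cls])
  }, numeric(1L))
  genes <- genes[order(rarity)]            # rarest-class genes first
  fold <- integer(length(genes))
  names(fold) <- genes
  # per-fold counts of positives per class, greedy balancing
  counts <- matrix(0L, k, length(class_size),
                   dimnames = list(NULL, names(class_size)))
  sizes <- integer(k)
  max_size <- ceiling(length(genes) / k)
  for (g in genes) {
    cls <- act$class[act$entity_id == g]
    eligible <- which(sizes < max_size)
    load <- if (length(cls))
      rowSums(counts[eligible, cls, drop = FALSE]) else sizes[eligible]
    pick <- eligible[order(load, sizes[eligible])][1L]
    fold[g] <- pick - 1L
    sizes[pick] <- sizes[pick] + 1L
    if (length(cls)) counts[pick, cls] <- counts[pick, cls] + 1L
  }
  fold
}

#' Gene-level k-fold cross-validation of the full EM model
#'
#' For each fold the model is trained (full EM) on the training genes'
#' labels only and held-out genes are scored with the fold model's forward
#' activities; per-class AUCs are aggregated across folds.  A class with
#' no positive (or no negative) held-out gene in a fold is skipped for
#' that fold with a warning.  The model trained on all labeled genes is
#' returned for external validation.
#'
#' @param data a `model_data`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param ... passed to [run_em()] (init, tol, dmax_step, ...).
#' @return list with `auc` (data.frame class x fold AUCs and mean),
#'   `folds` (assignment), `full_model` (an `em_state` trained on all
#'   labels), `full_auc` (per-class AUC of the full model on its training
#'   labels).
#' @export
cross_validate <- function(data, k = 10L, seed = 1L, ...) {
  gl <- data$gene_labels
  folds <- make_folds(gl, k, seed)
  per_fold <- vector("list", k)
  pooled_p <- matrix(NA_real_, nrow(data$R), length(data$classes),
                     dimnames = list(rownames(data$R), data$classes))
  for (fi in seq_len(k) - 1L) {
    test_genes <- names(folds)[folds == fi]
    train <- gl[!gl$entity_id %in% test_genes, , drop = FALSE]
    d_train <- data
    d_train$gene_labels <- train
    d_train$gene_label_matrix <-
      label_matrix(train, rownames(data$R), data$classes)
    state <- run_em(d_train, ...)
    pred <- predict_from_state(state, data)
    pooled_p[test_genes, ] <- pred$p[test_genes, , drop = FALSE]
    lm_test <- label_matrix(gl[gl$entity_id %in% test_genes, , drop = FALSE],
                            rownames(data$R), data$classes)
    aucs <- rep(NA_real_, length(data$classes))
    names(aucs) <- data$classes
    for (cl in data$classes) {
      y <- lm_test[, cl]
      keep <- !is.na(y)
      if (sum(y[keep] == 1) < 1L || sum(y[keep] == 0) < 1L) {
        warning("fold ", fi, ", class ", cl,
                ": single-class held-out labels; skipped")
        next
      }
      aucs[cl] <- roc_auc(pred$p[keep, cl], y[keep], cl)$auc
    }
    per_fold[[fi + 1L]] <- aucs
  }
  auc_mat <- do.call(cbind, per_fold)
  colnames(auc_mat) <- paste0("fold", seq_len(k) - 1L)
  full <- run_em(data, ...)
  pred_full <- predict_from_state(full, data)
  lm_all <- data$gene_label_matrix
  full_auc <- vapply(data$classes, function(cl) {
    y <- lm_all[, cl]; keep <- !is.na(y)
    if (sum(y[keep] == 1) < 1L || sum(y[keep] == 0) < 1L) return(NA_real_)
    roc_auc(pred_full$p[keep, cl], y[keep], cl)$auc
  }, numeric(1L))
  # pooled held-out AUC: every labeled gene scored by the fold model that
  # did not see it (finite even for leave-one-out)
  pooled_auc <- vapply(data$classes, function(cl) {
    y <- lm_all[, cl]; keep <- !is.na(y) & !is.na(pooled_p[, cl])
    if (sum(y[keep] == 1) < 1L || sum(y[keep] == 0) < 1L) return(NA_real_)
    roc_auc(pooled_p[keep, cl], y[keep], cl)$auc
  }, numeric(1L))
  list(auc = data.frame(class = data$classes, auc_mat,
                        mean_auc = rowMeans(auc_mat, na.rm = TRUE),
                        pooled_auc = pooled_auc,
                        stringsAsFactors = FALSE),
       folds = folds, held_out_p = pooled_p,
       full_model = full, full_auc = full_auc)
}

#' Write an evaluation report as TSV
#'
#' One row per class: AUC, Hanley-McNeil SE, class sizes and top-2\%
#' enrichment of the supplied predictions against the labels.
#'
#' @param p gene x class prediction matrix.
#' @param label_mat gene x class label matrix (NA = unlabeled).
#' @param path output TSV.
#' @param fraction top fraction for the enrichment column.
#' @return the report data.frame, invisibly written to `path`.
#' @export
write_evaluation <- function(p, label_mat, path, fraction = 0.02) {
  rows <- lapply(colnames(label_mat), function(cl) {
    y <- label_mat[, cl]; keep <- !is.na(y)
    if (sum(y[keep] == 1) < 1L || sum(y[keep] == 0) < 1L)
      return(data.frame(class = cl, auc = NA, se = NA,
                        n_pos = sum(y[keep] == 1), n_neg = sum(y[keep] == 0),
                        enrichment_top2pct = NA))
    r <- roc_auc(p[keep, cl], y[keep], cl)
    data.frame(class = cl, auc = r$auc,
               se = hanley_mcneil_se(r$auc, r$n_pos, r$n_neg),
               n_pos = r$n_pos, n_neg = r$n_neg,
               enrichment_top2pct =
                 top_fraction_enrichment(p[keep, cl], y[keep], fraction))
  })
  rep <- do.call(rbind, rows)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Write ROC curve points as TSV
#' @param roc a `roc_result`.
#' @param path output TSV with columns fpr, tpr.
#' @export
write_roc_points <- function(roc, path) {
  write.table(roc$points, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
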