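# Layer 3: distance/insulator weights, promoter response, and the
# noisy-OR gene activation model with its log-likelihood.

#' CRM-promoter interaction weight
#'
#' The probability that an active CRM reaches the promoter: linearly
#' decreasing with distance, reaching 0 at `dmax`, and 0 outright when the
#' number of intervening insulator peaks exceeds `insulator_limit`.
#'
#' @param distance bp from TSS to nearest CRM edge (vectorized).
#' @param insulator_count intervening insulator peaks (vectorized).
#' @param dmax maximal effective distance in bp.
#' @param insulator_limit max insulator peaks tolerated before the
#'   interaction is considered blocked (default 0: a single intervening
#'   peak blocks).
#' @return weights in \[0,1\].
#' @export
crm_gene_weight <- function(distance, insulator_count, dmax,
                            insulator_limit = 0L) {
  stopifnot(dmax > 0, all(distance >= 0))
  w <- pmax(0, 1 - distance / dmax)
  w[insulator_count > insulator_limit] <- 0
  w
}

#' Promoter response from the H3K4me3 state
#'
#' @param high logical (vectorized): promoter called high.
#' @param p_high,p_low response probabilities for high / low promoters
#'   (defaults 0.95 / 0.05).
#' @return response `R` in \[0,1\].
#' @export
promoter_response <- function(high, p_high = 0.95, p_low = 0.05) {
  stopifnot(p_high >= 0, p_high <= 1, p_low >= 0, p_low <= 1)
  ifelse(high, p_high, p_low)
}

#' Noisy-OR gene activation probability
#'
#' A gene is expressed when its promoter responds and at least one linked
#' CRM both is active and reaches it:
#' `p = R * (1 - prod_i (1 - A_i * W_i))`.
#'
#' @param A activity probabilities of the linked CRMs.
#' @param W interaction weights (same length).
#' @param R promoter response.
#' @return activation probability.
#' @export
gene_activation <- function(A, W, R) {
  stopifnot(length(A) == length(W),
            all(A >= 0 & A <= 1), all(W >= 0 & W <= 1), R >= 0, R <= 1)
  R * (1 - prod(1 - A * W))
}

# batch noisy-OR over a link table: gene x class matrix of activation
# probabilities.  A: CRM x class activity matrix; R: gene x class response
# matrix (rownames = gene ids).  Genes in `genes` with no positive-weight
# link get p = 0.
activation_matrix <- function(links, A, R, dmax, insulator_limit = 0L,
                              genes = rownames(R)) {
  W <- crm_gene_weight(links$distance, links$insulator_count, dmax,
                       insulator_limit)
  keep <- which(W > 0 & links$crm_id %in% rownames(A) &
                  links$gene_id %in% genes)
  P <- matrix(0, length(genes), ncol(A),
              dimnames = list(genes, colnames(A)))
  if (length(keep)) {
    ci <- match(links$crm_id[keep], rownames(A))
    gi <- match(links$gene_id[keep], genes)
    w <- W[keep]
    for (cl in seq_len(ncol(A))) {
      lf <- log1p(-pmin(A[ci, cl] * w, 1))        # log(1 - A*W), <= 0
      s <- rowsum(lf, group = gi)
      idx <- as.integer(rownames(s))
      P[idx, cl] <- -expm1(s[, 1L])               # 1 - prod(1 - A*W)
    }
  }
  P * R[genes, colnames(A), drop = FALSE]
}

#' Gene expression predictions for all genes and classes
#'
#' @param links a `link_table`.
#' @param A CRM x class activity matrix (e.g. forward probabilities).
#' @param R gene x class promoter-response matrix.
#' @param dmax maximal effective distance (bp).
#' @param insulator_limit see [crm_gene_weight()].
#' @return object of class `gene_prediction`: list with `p` (gene x class
#'   activation probabilities), `n_crms` (genes' positive-weight CRM
#'   counts), `dmax`, `insulator_limit`.
#' @export
predict_genes <- function(links, A, R, dmax, insulator_limit = 0L) {
  P <- activation_matrix(links, A, R, dmax, insulator_limit)
  W <- crm_gene_weight(links$distance, links$insulator_count, dmax,
                       insulator_limit)
  tab <- table(links$gene_id[W > 0])
  n_crms <- stats::setNames(rep(0L, nrow(R)), rownames(R))
  n_crms[names(tab)] <- as.integer(tab)
  structure(list(p = P, n_crms = n_crms, dmax = dmax,
                 insulator_limit = insulator_limit),
            class = "gene_prediction")
}

#' @export
print.gene_prediction <- function(x, ...) {
  cat("Gene predictions:", nrow(x$p), "genes x", ncol(x$p),
      "classes (dmax =", x$dmax, "bp)\n")
  invisible(x)
}

#' Write predictions as TSV
#'
#' Long format: gene_id, class, p_expressed, R, n_contributing_crms.
#' @param pred a `gene_prediction`.
#' @param R gene x class response matrix used for the prediction.
#' @param path output TSV.
#' @export
write_predictions <- function(pred, R, path) {
  p <- pred$p
  df <- data.frame(
    gene_id = rep(rownames(p), ncol(p)),
    class = rep(colnames(p), each = nrow(p)),
    p_expressed = as.vector(p),
    R = as.vector(R[rownames(p), colnames(p)]),
    n_contributing_crms = rep(pred$n_crms[rownames(p)], ncol(p)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-likelihood of binary expression labels under predictions
#'
#' Sum over labeled (gene, class) pairs of `log p` for active labels and
#' `log(1 - p)` for inactive ones.  Probabilities are clamped to
#' `[eps, 1 - eps]` so degenerate predictions cannot yield infinities.
#'
#' @param p gene x class matrix of activation probabilities.
#' @param labels gene x class matrix with entries 0/1 and `NA` for
#'   unlabeled, or a `label_table`.
#' @param eps clamp (default 1e-9).
#' @return list with `total` and per-class vector `by_class`.
#' @export
log_likelihood <- function(p, labels, eps = 1e-9) {
  if (inherits(labels, "label_table"))
    labels <- label_matrix(labels, rownames(p), colnames(p))
  stopifnot(identical(dim(p), dim(labels)))
  pc <- pmin(pmax(p, eps), 1 - eps)
  ll <- ifelse(is.na(labels), 0,
               ifelse(labels == 1, log(pc), log1p(-pc)))
  list(total = sum(ll), by_class = colSums(ll))
}

#' Link saturation statistics over a distance sweep
#'
#' Mean number of positively-weighted CRMs per gene and genes per CRM as a
#' function of the maximum distance, with and without insulator blocking.
#' Means are taken over the genes/CRMs present in the link table.
#'
#' @param links a `link_table`.
#' @param dmax_values distances to sweep (bp).
#' @param insulator_limit blocking threshold for the "with insulators"
#'   column.
#' @return data.frame with columns `dmax`, `crms_per_gene`,
#'   `genes_per_crm`, `crms_per_gene_ins`, `genes_per_crm_ins`.
#' @export
link_statistics <- function(links, dmax_values, insulator_limit = 0L) {
  n_genes <- length(unique(links$gene_id))
  n_crms <- length(unique(links$crm_id))
  do.call(rbind, lapply(dmax_values, function(d) {
    open <- links$distance < d
    surv <- open & links$insulator_count <= insulator_limit
    data.frame(dmax = d,
               crms_per_gene = sum(open) / n_genes,
               genes_per_crm = sum(open) / n_crms,
               crms_per_gene_ins = sum(surv) / n_genes,
               genes_per_crm_ins = sum(surv) / n_crms)
  }))
}
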