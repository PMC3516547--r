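# Coupling the layers: latent CRM activity estimated by forward/backward
# smoothing (E-step), network and dmax refit (M-step), iterated to
# convergence.

#' Bundle all model inputs
#'
#' @param occupancy an `occupancy_matrix`.
#' @param links a `link_table`; links to genes absent from `R` or CRMs
#'   absent from the occupancy matrix are dropped with a message.
#' @param R gene x class promoter-response matrix (a `promoter_activity`
#'   object's `R`, or any numeric matrix in \[0,1\]).
#' @param gene_labels `label_table` of expression labels (training genes).
#' @param crm_labels optional `label_table` of known CRM activities (the
#'   initialization subset).
#' @param window link window in bp (default 100 kb); also the upper end of
#'   the dmax grid.
#' @param insulator_limit see [crm_gene_weight()].
#' @param discretizer optional pre-fitted `gmm_discretizer`.
#' @return object of class `model_data`.
#' @export
model_data <- function(occupancy, links, R, gene_labels,
                       crm_labels = NULL, window = 1e5,
                       insulator_limit = 0L, discretizer = NULL) {
  if (inherits(R, "promoter_activity")) R <- R$R
  stopifnot(is.matrix(R), all(R >= 0 & R <= 1))
  classes <- colnames(R)
  drop <- !(links$gene_id %in% rownames(R)) |
          !(links$crm_id %in% rownames(occupancy))
  if (any(drop)) {
    message("dropping ", sum(drop),
            " link(s) to genes/CRMs absent from the inputs")
    links <- links[!drop, , drop = FALSE]
  }
  if (is.null(discretizer)) discretizer <- fit_discretizer(occupancy)
  evidence <- soft_evidence(discretizer, occupancy)
  gl <- label_matrix(gene_labels, rownames(R), classes)
  cl <- if (is.null(crm_labels)) NULL
        else label_matrix(crm_labels, rownames(occupancy), classes)
  structure(list(occupancy = occupancy, evidence = evidence,
                 links = links, R = R, gene_label_matrix = gl,
                 crm_label_matrix = cl, gene_labels = gene_labels,
                 crm_labels = crm_labels, classes = classes,
                 window = window, insulator_limit = insulator_limit,
                 discretizer = discretizer),
            class = "model_data")
}

#' Backward probabilities of CRM activity from gene expression
#'
#' For CRM i and class c, the likelihood of the labeled expression of all
#' genes within reach (`W_ij > 0`) under `A_i = 1` versus `A_i = 0`, with
#' the other CRM activities fixed at their current smoothed estimates
#' (mean-field): a CRM can only be inactive if every expressed gene in its
#' range is turned on by another CRM.  Genes with no label for a class
#' contribute nothing.  The pair is normalized so `max(b0, b1) = 1`; only
#' the ratio matters for smoothing.
#'
#' @param A CRM x class matrix of current activity estimates.
#' @param data a `model_data`.
#' @param dmax current maximal distance (bp).
#' @param eps probability clamp (default 1e-9).
#' @return list with matrices `b0`, `b1` (CRM x class); both 1 for CRMs
#'   linked to no labeled gene.
#' @export
backward_probability <- function(A, data, dmax, eps = 1e-9) {
  links <- data$links
  labels <- data$gene_label_matrix
  crms <- rownames(data$occupancy)
  genes <- rownames(data$R)
  W <- crm_gene_weight(links$distance, links$insulator_count, dmax,
                       data$insulator_limit)
  b0 <- b1 <- matrix(1, length(crms), length(data$classes),
                     dimnames = list(crms, data$classes))
  pos <- which(W > 0)
  if (!length(pos)) return(list(b0 = b0, b1 = b1))
  ci <- match(links$crm_id[pos], crms)
  gi <- match(links$gene_id[pos], genes)
  w <- W[pos]
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  for (cl in seq_along(data$classes)) {
    y <- labels[gi, cl]
    keep <- which(!is.na(y))
    if (!length(keep)) next
    aw <- pmin(A[ci[keep], cl] * w[keep], 1)
    lf <- log1p(-aw)
    # log prod over a gene's links, then leave-one-out per link
    s <- rowsum(lf, group = gi[keep])
    logq <- s[match(as.character(gi[keep]), rownames(s)), 1L]
    logq_wo <- logq - lf
    exact <- which(!is.finite(logq_wo))    # an A*W == 1 link elsewhere
    if (length(exact)) {
      for (m in exact) {
        same <- keep[gi[keep] == gi[keep][m]]
        others <- setdiff(same, keep[m])
        logq_wo[m] <- sum(log1p(-pmin(A[ci[others], cl] * w[others], 1)))
      }
    }
    qwo <- exp(logq_wo)
    r <- data$R[gi[keep], cl]
    p1 <- r * (1 - (1 - w[keep]) * qwo)
    p0 <- r * (1 - qwo)
    yk <- y[keep]
    l1 <- ifelse(yk == 1, log(clamp(p1)), log1p(-clamp(p1)))
    l0 <- ifelse(yk == 1, log(clamp(p0)), log1p(-clamp(p0)))
    s1 <- rowsum(l1, group = ci[keep])
    s0 <- rowsum(l0, group = ci[keep])
    idx <- as.integer(rownames(s1))
    mx <- pmax(s1[, 1L], s0[, 1L])
    b1[idx, cl] <- exp(s1[, 1L] - mx)
    b0[idx, cl] <- exp(s0[, 1L] - mx)
  }
  list(b0 = b0, b1 = b1)
}

#' E-step: smoothed posterior CRM activities
#'
#' Combines forward (binding) and backward (expression) evidence:
#' `smoothed = f*b1 / (f*b1 + (1-f)*b0)`; when the denominator vanishes
#' the forward value is kept.
#'
#' @param bn current fitted `bipartite_bn`.
#' @param data a `model_data`.
#' @param dmax current maximal distance.
#' @param A_prev CRM x class activities used for the mean-field backward
#'   pass (defaults to the forward probabilities).
#' @param clamp_known_crms if `TRUE`, CRMs with experimental labels are
#'   clamped to them (default `FALSE`: known activity is used only at
#'   initialization).
#' @return list with `forward`, `b0`, `b1`, `smoothed` matrices.
#' @export
e_step <- function(bn, data, dmax, A_prev = NULL,
                   clamp_known_crms = FALSE) {
  f <- forward_probability(bn, data$evidence)
  if (is.null(A_prev)) A_prev <- f
  b <- backward_probability(A_prev, data, dmax)
  num <- f * b$b1
  den <- num + (1 - f) * b$b0
  smoothed <- ifelse(den == 0, f, num / den)
  if (clamp_known_crms && !is.null(data$crm_label_matrix)) {
    known <- !is.na(data$crm_label_matrix)
    smoothed[known] <- data$crm_label_matrix[known]
  }
  list(forward = f, b0 = b$b0, b1 = b$b1, smoothed = smoothed)
}

#' M-step: refit the network and dmax from smoothed activities
#'
#' The bipartite network is relearned (structure and CPTs) using the
#' smoothed activities of all CRMs as fractional labels; dmax is then the
#' exhaustive-grid argmax (step `dmax_step`, ties to the smallest value)
#' of the expression log-likelihood under the assumed (smoothed) CRM
#' activities.
#'
#' @param smoothed CRM x class matrix from [e_step()].
#' @param data a `model_data`.
#' @param dmax_step grid step in bp (default 200, the minimal CRM size).
#' @param max_parents,ess structure-search settings.
#' @param current_dmax value to keep when no gene is labeled.
#' @return list with `bn`, `dmax`, `forward`, `ll` (the log-likelihood
#'   under the smoothed activities at the chosen dmax).
#' @export
m_step <- function(smoothed, data, dmax_step = 200, max_parents = 3L,
                   ess = 1, current_dmax = NULL) {
  bn <- learn_structure(data$evidence, smoothed, max_parents, ess)
  bn <- fit_cpts(bn, data$evidence, smoothed)
  f <- forward_probability(bn, data$evidence)
  if (all(is.na(data$gene_label_matrix))) {
    message("no labeled genes; dmax left unchanged")
    dm <- if (is.null(current_dmax)) data$window else current_dmax
    return(list(bn = bn, dmax = dm, forward = f, ll = 0))
  }
  grid <- seq(dmax_step, data$window, by = dmax_step)
  ll <- dmax_profile(grid, smoothed, data)
  best <- which(ll >= max(ll) - 1e-9)[1L]
  list(bn = bn, dmax = grid[best], forward = f, ll = ll[best])
}

# expression log-likelihood profile over a dmax grid (C++ kernel)
dmax_profile <- function(grid, A, data, eps = 1e-9) {
  links <- data$links
  cpp_dmax_scan(as.numeric(grid),
                match(links$gene_id, rownames(data$R)),
                match(links$crm_id, rownames(A)),
                as.numeric(links$distance),
                links$insulator_count > data$insulator_limit,
                A, data$R[, data$classes, drop = FALSE],
                data$gene_label_matrix, eps)
}

# log-likelihood of the labeled expression under given CRM activities
tracked_ll <- function(A, dmax, data) {
  p <- activation_matrix(data$links, A, data$R, dmax, data$insulator_limit)
  log_likelihood(p, data$gene_label_matrix)
}

#' Initialize from known CRM activity data
#'
#' The network is learned on the experimentally labeled CRM subset only
#' and dmax starts at the window limit so no CRM is excluded early.
#'
#' @param data a `model_data` with `crm_labels`.
#' @param max_parents,ess structure-search settings.
#' @return list with `bn`, `dmax`.
#' @export
initialize_from_cad <- function(data, max_parents = 3L, ess = 1) {
  cm <- data$crm_label_matrix
  if (is.null(cm) || all(is.na(cm)))
    stop("no CRM activity labels available; use init = 'nearest_gene'")
  empty <- colnames(cm)[colSums(!is.na(cm)) == 0L]
  if (length(empty))
    warning("class(es) with no labeled CRM initialized with empty ",
            "parent set: ", paste(empty, collapse = ", "))
  bn <- learn_structure(data$evidence, cm, max_parents, ess)
  bn <- fit_cpts(bn, data$evidence, cm)
  list(bn = bn, dmax = data$window)
}

#' Proxy CRM activity labels from promoter-proximal genes
#'
#' Each CRM within `max_dist` of a labeled gene's TSS inherits that gene's
#' class labels; a CRM near several labeled genes takes the union of their
#' active labels (enhancers can serve multiple genes).
#'
#' @param links a `link_table`.
#' @param gene_labels a `label_table` of gene expression.
#' @param max_dist proximity threshold in bp (default 500).
#' @return a `label_table` of proxy CRM labels.
#' @export
initialize_nearest_gene <- function(links, gene_labels, max_dist = 500) {
  near <- links[links$distance < max_dist &
                  links$gene_id %in% gene_labels$entity_id, , drop = FALSE]
  if (!nrow(near)) return(label_table(character(), character(), integer()))
  m <- merge(near[c("crm_id", "gene_id")], gene_labels,
             by.x = "gene_id", by.y = "entity_id")
  agg <- stats::aggregate(label ~ crm_id + class, data = m, FUN = max)
  label_table(agg$crm_id, agg$class, agg$label)
}

#' Two-layer baseline: binding features mapped directly to gene expression
#'
#' Skips the latent CRM layer: each gene's feature vector is the
#' weight-summed occupancy of its linked CRMs per binding variable (weights
#' from the window-limit dmax); a bipartite network from these features to
#' the class labels yields gene predictions directly.  Less accurate than
#' the full model but usable as an EM initializer when no CRM activity
#' data exist.
#'
#' @param data a `model_data`.
#' @param max_parents,ess structure-search settings.
#' @return list with `bn`, `features` (gene x binding variable), `p` (gene
#'   x class predictions).
#' @export
two_layer_model <- function(data, max_parents = 3L, ess = 1) {
  links <- data$links
  genes <- rownames(data$R)
  occ <- unclass(data$occupancy)
  W <- crm_gene_weight(links$distance, links$insulator_count, data$window,
                       data$insulator_limit)
  feat <- matrix(0, length(genes), ncol(occ),
                 dimnames = list(genes, colnames(occ)))
  pos <- which(W > 0)
  if (length(pos)) {
    contrib <- occ[match(links$crm_id[pos], rownames(occ)), , drop = FALSE] *
      W[pos]
    s <- rowsum(contrib, group = links$gene_id[pos])
    feat[rownames(s), ] <- s
  }
  disc <- suppressWarnings(fit_discretizer(feat))
  ev <- soft_evidence(disc, feat)
  bn <- learn_structure(ev, data$gene_label_matrix, max_parents, ess)
  bn <- fit_cpts(bn, ev, data$gene_label_matrix)
  p <- forward_probability(bn, ev)
  list(bn = bn, features = feat, p = p)
}

# two-layer gene predictions translated into fractional CRM labels:
# each CRM takes the weight-averaged predicted activity of its linked genes
two_layer_crm_init <- function(data, max_parents = 3L, ess = 1) {
  tl <- two_layer_model(data, max_parents, ess)
  links <- data$links
  W <- crm_gene_weight(links$distance, links$insulator_count, data$window,
                       data$insulator_limit)
  pos <- which(W > 0)
  frac <- matrix(NA_real_, nrow(data$occupancy), length(data$classes),
                 dimnames = list(rownames(data$occupancy), data$classes))
  if (length(pos)) {
    gi <- match(links$gene_id[pos], rownames(tl$p))
    num <- rowsum(tl$p[gi, , drop = FALSE] * W[pos],
                  group = links$crm_id[pos])
    den <- rowsum(W[pos], group = links$crm_id[pos])
    frac[rownames(num), ] <- num / den[, 1L]
  }
  bn <- learn_structure(data$evidence, frac, max_parents, ess)
  bn <- fit_cpts(bn, data$evidence, frac)
  list(bn = bn, dmax = data$window)
}

#' Run the full Expectation-Maximization procedure
#'
#' Alternates [e_step()] and [m_step()] from the chosen initialization
#' until the relative improvement of the expression log-likelihood falls
#' below `tol` (default 2\%) or `max_iter` is reached.  An M-step proposal
#' that would decrease the tracked likelihood is rejected (the previous
#' parameters are kept and EM stops) — a generalized-EM safeguard, since
#' the mean-field backward pass does not guarantee monotone updates; the
#' trace is therefore non-decreasing by construction and any residual
#' decrease raises an error.
#'
#' @param data a `model_data`.
#' @param init `"cad"` (known CRM activities), `"nearest_gene"` (proxy
#'   labels from promoter-proximal genes), or `"two_layer"`.
#' @param tol relative likelihood-improvement convergence threshold
#'   (default 0.02).
#' @param max_iter iteration cap (default 50).
#' @param dmax_step grid step in bp (default 200).
#' @param max_parents,ess structure-search settings.
#' @param clamp_known_crms clamp labeled CRMs during the E-step (default
#'   `FALSE`).
#' @param checkpoint_dir optional directory for per-iteration checkpoints
#'   (network text file + smoothed-posterior TSV).
#' @param verbose print per-iteration likelihood and dmax.
#' @return object of class `em_state`: `bn`, `dmax`, `posterior` (forward,
#'   b0, b1, smoothed), `ll_trace`, `by_class_ll`, `iterations`,
#'   `converged`, `rejected_update`.
#' @export
run_em <- function(data, init = c("cad", "nearest_gene", "two_layer"),
                   tol = 0.02, max_iter = 50L, dmax_step = 200,
                   max_parents = 3L, ess = 1, clamp_known_crms = FALSE,
                   checkpoint_dir = NULL, verbose = FALSE) {
  init <- match.arg(init)
  state0 <- switch(init,
    cad = initialize_from_cad(data, max_parents, ess),
    nearest_gene = {
      proxy <- initialize_nearest_gene(data$links, data$gene_labels)
      if (!nrow(proxy))
        stop("nearest_gene initialization found no CRM within 500 bp of ",
             "a labeled gene")
      pm <- label_matrix(proxy, rownames(data$occupancy), data$classes)
      bn <- learn_structure(data$evidence, pm, max_parents, ess)
      list(bn = fit_cpts(bn, data$evidence, pm), dmax = data$window)
    },
    two_layer = two_layer_crm_init(data, max_parents, ess))
  bn <- state0$bn
  dmax <- state0$dmax
  post <- e_step(bn, data, dmax, clamp_known_crms = clamp_known_crms)
  ll <- tracked_ll(post$smoothed, dmax, data)$total
  trace <- ll
  converged <- FALSE
  rejected <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cand <- m_step(post$smoothed, data, dmax_step, max_parents, ess,
                   current_dmax = dmax)
    if (verbose)
      message(sprintf("iter %d: ll %.4f -> %.4f, dmax %g", iter, ll,
                      cand$ll, cand$dmax))
    if (cand$ll < ll) {                 # generalized-EM rejection
      rejected <- TRUE
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    improved <- (cand$ll - ll) / abs(ll)
    if (!is.finite(improved)) improved <- 0
    bn <- cand$bn
    dmax <- cand$dmax
    trace <- c(trace, cand$ll)
    ll <- cand$ll
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      write_bn(bn, file.path(checkpoint_dir, sprintf("bn_iter%02d.txt", iter)))
      write.table(
        data.frame(crm_id = rownames(post$smoothed), post$smoothed,
                   check.names = FALSE),
        file.path(checkpoint_dir, sprintf("smoothed_iter%02d.tsv", iter)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (improved < tol) { converged <- TRUE; break }
    post <- e_step(bn, data, dmax, A_prev = post$smoothed,
                   clamp_known_crms = clamp_known_crms)
  }
  if (any(diff(trace) < -1e-6 * abs(trace[-length(trace)])))
    stop("log-likelihood decreased during EM: implementation bug in the ",
         "E/M coupling")
  post_final <- e_step(bn, data, dmax, A_prev = post$smoothed,
                       clamp_known_crms = clamp_known_crms)
  llf <- tracked_ll(post_final$smoothed, dmax, data)
  structure(list(bn = bn, dmax = dmax, posterior = post_final,
                 ll_trace = trace, by_class_ll = llf$by_class,
                 iterations = iter, converged = converged,
                 rejected_update = rejected, init = init,
                 tol = tol, dmax_step = dmax_step),
            class = "em_state")
}

#' @export
print.em_state <- function(x, ...) {
  cat("EM state:", x$iterations, "iteration(s),",
      if (x$converged) "converged," else "iteration cap reached,",
      "dmax =", x$dmax, "bp\n")
  cat("log-likelihood trace:",
      paste(sprintf("%.2f", x$ll_trace), collapse = " -> "), "\n")
  invisible(x)
}

#' Predictions from a converged EM state
#'
#' Forward (binding-based) activities under the final network and dmax —
#' usable for genes whose expression was never observed.
#' @param state an `em_state`.
#' @param data the `model_data` it was trained on (or a compatible one).
#' @return a `gene_prediction`.
#' @export
predict_from_state <- function(state, data) {
  f <- forward_probability(state$bn, data$evidence)
  predict_genes(data$links, f, data$R, state$dmax, data$insulator_limit)
}
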