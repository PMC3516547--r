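# Layer 1 -> 2: soft discretization of occupancy and the bipartite
# Bayesian network from binding variables to activity classes.

#' Fit per-variable two-component Gaussian mixtures to occupancy signal
#'
#' Each binding variable's continuous ChIP signal is modeled as a mixture
#' of an "unbound" and a "bound" (higher-mean) Gaussian; the posterior of
#' the bound component turns the signal into soft binary evidence.
#' Initialization is a deterministic quantile split (lower/upper tertiles),
#' so the fit is reproducible without a seed.
#'
#' @param occupancy an `occupancy_matrix` (or plain numeric matrix, CRMs in
#'   rows).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return object of class `gmm_discretizer`: per-variable list with
#'   `weights`, `means`, `sds` (bound component second) or `degenerate =
#'   TRUE` for constant columns.
#' @export
fit_discretizer <- function(occupancy, max_iter = 500L, tol = 1e-10) {
  x <- unclass(occupancy)
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (nrow(x) < 20L)
    warning("fewer than 20 CRMs; mixture fits may be unstable")
  fits <- lapply(seq_len(ncol(x)), function(j) fit_gmm2(x[, j], max_iter, tol))
  names(fits) <- colnames(x)
  structure(list(fits = fits, binding_vars = colnames(x)),
            class = "gmm_discretizer")
}

# deterministic 1-D two-component GMM via EM, tertile initialization
fit_gmm2 <- function(v, max_iter = 500L, tol = 1e-10) {
  if (stats::var(v) < .Machine$double.eps * max(1, mean(v)^2) ||
      length(unique(v)) == 1L)
    return(list(degenerate = TRUE))
  q <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  lo <- v[v <= q[1L]]; hi <- v[v >= q[2L]]
  mu <- c(mean(lo), mean(hi))
  if (diff(mu) == 0) mu <- mu + c(-1, 1) * stats::sd(v) / 4
  sd0 <- function(x) if (length(x) < 2L || is.na(stats::sd(x))) 0
                     else stats::sd(x)
  sg <- pmax(c(sd0(lo), sd0(hi)), stats::sd(v) / 20, 1e-8)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(v, mu[1L], sg[1L])
    d2 <- w[2L] * stats::dnorm(v, mu[2L], sg[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
    n2 <- sum(r); n1 <- length(v) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / length(v)
    mu <- c(sum((1 - r) * v) / n1, sum(r * v) / n2)
    sg <- sqrt(c(sum((1 - r) * (v - mu[1L])^2) / n1,
                 sum(r * (v - mu[2L])^2) / n2))
    sg <- pmax(sg, 1e-8)
  }
  if (mu[2L] < mu[1L]) {          # keep the bound component second
    mu <- rev(mu); sg <- rev(sg); w <- rev(w)
  }
  list(degenerate = FALSE, weights = w, means = mu, sds = sg)
}

#' Soft binding evidence from a fitted discretizer
#'
#' @param disc a `gmm_discretizer`.
#' @param occupancy occupancy matrix with the same columns.
#' @return matrix of `p_bound` posteriors in \[0,1\] (CRM x binding
#'   variable); degenerate variables give 0.5 everywhere.
#' @export
soft_evidence <- function(disc, occupancy) {
  x <- unclass(occupancy)
  stopifnot(identical(colnames(x), disc$binding_vars))
  E <- matrix(0.5, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    f <- disc$fits[[j]]
    if (isTRUE(f$degenerate)) next
    d1 <- f$weights[1L] * stats::dnorm(x[, j], f$means[1L], f$sds[1L])
    d2 <- f$weights[2L] * stats::dnorm(x[, j], f$means[2L], f$sds[2L])
    tot <- d1 + d2
    E[, j] <- ifelse(tot == 0, 0.5, d2 / tot)
  }
  E
}

# n x 2^p matrix of parent-configuration probabilities for soft evidence
# E (n x p); configuration index c = 1 + sum over k of bit_k * 2^(k-1),
# bit_k = 1 meaning parent k bound.
config_weights <- function(E) {
  E <- as.matrix(E)
  p <- ncol(E)
  n <- nrow(E)
  if (p == 0L) return(matrix(1, n, 1L))
  W <- matrix(1, n, 2^p)
  for (k in seq_len(p)) {
    bit <- bitwAnd(seq_len(2^p) - 1L, bitwShiftL(1L, k - 1L)) > 0L
    W <- W * ifelse(matrix(bit, n, 2^p, byrow = TRUE), E[, k], 1 - E[, k])
  }
  W
}

#' BDe score of one class node given a candidate parent set
#'
#' Log marginal likelihood of the class variable under a BDeu prior with
#' equivalent sample size `ess`, computed from expected (fractional)
#' counts: each CRM distributes its probability mass over the `2^p` parent
#' configurations (from the soft evidence) and over active/inactive (from
#' its fractional label).
#'
#' @param labels fractional activity labels in \[0,1\], one per CRM.
#' @param parent_evidence matrix of `p_bound` values restricted to the
#'   candidate parents (n x p); `NULL` or 0 columns for the empty set.
#' @param ess Dirichlet equivalent sample size (default 1).
#' @return log marginal likelihood (scalar).
#' @export
bde_score <- function(labels, parent_evidence = NULL, ess = 1) {
  if (!length(labels)) stop("empty CRM set")
  stopifnot(all(labels >= 0 & labels <= 1), ess > 0)
  if (is.null(parent_evidence))
    parent_evidence <- matrix(numeric(0), length(labels), 0L)
  W <- config_weights(parent_evidence)
  q <- ncol(W)
  N <- crossprod(W, cbind(labels, 1 - labels))   # q x 2 expected counts
  a <- ess / (2 * q)
  sum(lgamma(a + N) - lgamma(a)) +
    sum(lgamma(2 * a) - lgamma(2 * a + rowSums(N)))
}

#' Learn the bipartite network structure by exhaustive subset search
#'
#' For each activity class independently, the parent set (a subset of the
#' binding variables of size at most `max_parents`) maximizing
#' [bde_score()] is found by exhaustive enumeration — global optimality is
#' guaranteed because class nodes share no edges.  Ties are broken in
#' favor of the smaller set, then lexicographic order of parent indices.
#'
#' @param evidence soft-evidence matrix (CRM x binding variable).
#' @param labels CRM x class matrix of fractional labels; rows with `NA`
#'   for a class are dropped for that class.
#' @param max_parents maximum parent-set size (default 3).
#' @param ess BDeu equivalent sample size (default 1).
#' @return object of class `bipartite_bn` with per-class parent sets; CPTs
#'   are filled in by [fit_cpts()].
#' @export
learn_structure <- function(evidence, labels, max_parents = 3L, ess = 1) {
  evidence <- as.matrix(evidence)
  labels <- as.matrix(labels)
  nv <- ncol(evidence)
  vars <- colnames(evidence)
  if (is.null(vars)) vars <- paste0("v", seq_len(nv))
  subsets <- list(integer(0))
  for (sz in seq_len(min(max_parents, nv)))
    subsets <- c(subsets, combn(nv, sz, simplify = FALSE))
  classes <- colnames(labels)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(labels)))
  nodes <- vector("list", length(classes))
  names(nodes) <- classes
  # classes sharing a labeled-row pattern share every subset's
  # configuration weights, so they are scored together in one pass
  pattern <- apply(!is.na(labels), 2L, paste, collapse = "")
  for (pat in unique(pattern)) {
    cls <- which(pattern == pat)
    keep <- which(!is.na(labels[, cls[1L]]))
    if (!length(keep)) {
      for (c in cls)
        nodes[[c]] <- list(parents = character(0), cpt = 0.5,
                           unlabeled = TRUE)
      next
    }
    Y <- labels[keep, cls, drop = FALSE]
    best_score <- rep(-Inf, length(cls))
    best_set <- vector("list", length(cls))
    # subsets are enumerated by size then lexicographically, and a
    # candidate replaces the incumbent only on a strict improvement, so
    # ties resolve to the smaller, lexicographically first parent set
    for (s in subsets) {
      W <- config_weights(evidence[keep, s, drop = FALSE])
      q <- ncol(W)
      a <- ess / (2 * q)
      Ntot <- colSums(W)
      Nact <- crossprod(W, Y)                       # q x |cls|
      sc <- colSums(lgamma(a + Nact) + lgamma(a + (Ntot - Nact)) -
                      2 * lgamma(a)) +
        sum(lgamma(2 * a) - lgamma(2 * a + Ntot))
      upd <- which(sc > best_score + 1e-9)
      for (u in upd) {
        best_score[u] <- sc[u]
        best_set[[u]] <- s
      }
    }
    for (k in seq_along(cls))
      nodes[[cls[k]]] <- list(parents = vars[best_set[[k]]], cpt = NULL,
                              score = best_score[k])
  }
  structure(list(nodes = nodes, binding_vars = vars, ess = ess,
                 max_parents = max_parents),
            class = "bipartite_bn")
}

#' Fit (smoothed maximum-likelihood) conditional probability tables
#'
#' Each CPT entry is the posterior-mean estimate
#' `(fractional active count + ess/(2 q)) / (fractional total + ess/q)`
#' with `q = 2^|parents|`; unseen configurations fall back to the prior
#' mean 0.5.
#'
#' @param bn a `bipartite_bn` from [learn_structure()].
#' @param evidence,labels as in [learn_structure()].
#' @return the network with `cpt` filled: per class, a vector of
#'   `P(active | configuration)` over the `2^p` configurations.
#' @export
fit_cpts <- function(bn, evidence, labels) {
  evidence <- as.matrix(evidence)
  labels <- as.matrix(labels)
  ess <- bn$ess
  for (cl in names(bn$nodes)) {
    node <- bn$nodes[[cl]]
    if (isTRUE(node$unlabeled)) {
      bn$nodes[[cl]]$cpt <- rep(0.5, 2^length(node$parents))
      next
    }
    y <- labels[, cl]
    keep <- which(!is.na(y))
    E <- evidence[keep, node$parents, drop = FALSE]
    W <- config_weights(E)
    q <- ncol(W)
    Nact <- crossprod(W, y[keep])[, 1L]
    Ntot <- colSums(W)
    bn$nodes[[cl]]$cpt <-
      (Nact + ess / (2 * q)) / (Ntot + ess / q)
  }
  bn
}

#' Forward activity probabilities for every CRM
#'
#' `P(class active | binding evidence)` marginalized over the parent
#' configurations: `sum_c CPT(active | c) * P(c | soft evidence)`.
#' Defined for all CRMs, labeled or not.
#'
#' @param bn a fitted `bipartite_bn` (CPTs present).
#' @param evidence soft-evidence matrix (CRM x binding variable).
#' @return CRM x class matrix of forward probabilities.
#' @export
forward_probability <- function(bn, evidence) {
  evidence <- as.matrix(evidence)
  out <- matrix(NA_real_, nrow(evidence), length(bn$nodes),
                dimnames = list(rownames(evidence), names(bn$nodes)))
  for (cl in names(bn$nodes)) {
    node <- bn$nodes[[cl]]
    if (is.null(node$cpt)) stop("CPTs not fitted; call fit_cpts() first")
    W <- config_weights(evidence[, node$parents, drop = FALSE])
    out[, cl] <- as.vector(W %*% node$cpt)
  }
  out
}

#' @export
print.bipartite_bn <- function(x, ...) {
  cat("Bipartite Bayesian network:", length(x$binding_vars),
      "binding variables ->", length(x$nodes), "activity classes\n")
  for (cl in names(x$nodes)) {
    p <- x$nodes[[cl]]$parents
    cat(sprintf("  %-10s <- {%s}\n", cl,
                if (length(p)) paste(p, collapse = ", ") else ""))
  }
  invisible(x)
}

#' Serialize / restore a bipartite network as structured text
#'
#' Human-readable format: one `class:` block per activity class with its
#' parent list and CPT (configuration bits in parent order, low bit first).
#' @param bn network to write.
#' @param path file path.
#' @export
write_bn <- function(bn, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("binding_vars:", paste(bn$binding_vars, collapse = ",")),
               paste("ess:", format(bn$ess, digits = 17)),
               paste("max_parents:", bn$max_parents)), con)
  for (cl in names(bn$nodes)) {
    node <- bn$nodes[[cl]]
    writeLines(c(paste0("class: ", cl),
                 paste0("  parents: ", paste(node$parents, collapse = ",")),
                 paste0("  cpt: ",
                        paste(format(node$cpt, digits = 17),
                              collapse = ","))), con)
  }
  invisible(path)
}

#' @rdname write_bn
#' @export
read_bn <- function(path) {
  ln <- readLines(path)
  val <- function(l) sub("^[^:]*:\\s*", "", l)
  bv <- strsplit(val(ln[1L]), ",")[[1L]]
  ess <- as.numeric(val(ln[2L]))
  mp <- as.integer(val(ln[3L]))
  starts <- grep("^class: ", ln)
  nodes <- list()
  for (s in starts) {
    cl <- val(ln[s])
    p <- strsplit(val(ln[s + 1L]), ",")[[1L]]
    p <- p[nzchar(p)]
    cpt <- as.numeric(strsplit(val(ln[s + 2L]), ",")[[1L]])
    nodes[[cl]] <- list(parents = p, cpt = cpt)
  }
  structure(list(nodes = nodes, binding_vars = bv, ess = ess,
                 max_parents = mp), class = "bipartite_bn")
}
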