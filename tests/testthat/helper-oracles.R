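# Independent brute-force oracles.  These deliberately re-derive each
# quantity by enumeration or naive loops, sharing no code with the
# package's own implementations.

# noisy-OR by enumeration over all 2^n joint binary CRM states
oracle_noisy_or <- function(A, W, R) {
  n <- length(A)
  total <- 0
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(n)]
    p_state <- prod(ifelse(bits == 1L, A, 1 - A))
    p_on <- R * (1 - prod(ifelse(bits == 1L, 1 - W, 1)))
    total <- total + p_state * p_on
  }
  total
}

# discrete BDe via the closed Beta-integral form on hard data
oracle_bde_discrete <- function(y, X, ess) {
  q <- if (is.null(X) || ncol(X) == 0L) 1L else 2L^ncol(X)
  cfg <- if (q == 1L) rep(1L, length(y))
         else as.vector(X %*% 2L^(seq_len(ncol(X)) - 1L)) + 1L
  a <- ess / (2 * q)
  total <- 0
  for (c in seq_len(q)) {
    n1 <- sum(y[cfg == c] == 1L)
    n0 <- sum(y[cfg == c] == 0L)
    total <- total + lbeta(a + n1, a + n0) - lbeta(a, a)
  }
  total
}

# per-class exhaustive parent-set search built directly on bde_score
oracle_best_subset <- function(E, y, max_parents, ess) {
  nv <- ncol(E)
  best <- list(score = -Inf, set = integer(0))
  sets <- list(integer(0))
  for (sz in seq_len(min(max_parents, nv)))
    sets <- c(sets, combn(nv, sz, simplify = FALSE))
  for (s in sets) {
    sc <- bde_score(y, E[, s, drop = FALSE], ess)
    if (sc > best$score + 1e-9) best <- list(score = sc, set = s)
  }
  sort(colnames(E)[best$set])
}

# all-pairs O(n^2) link scan with naive per-pair insulator counting
oracle_link_table <- function(layout, window) {
  rows <- list()
  for (gi in seq_len(nrow(layout$tss))) {
    g <- layout$tss[gi, ]
    t0 <- g$pos - 1L
    for (ci in seq_len(nrow(layout$crms))) {
      cr <- layout$crms[ci, ]
      if (cr$chrom != g$chrom) next
      d <- max(0L, cr$start - t0 - 1L, t0 - cr$end)
      if (d >= window) next
      nearest <- if (cr$start > t0) cr$start
                 else if (t0 >= cr$end) cr$end - 1L else t0
      lo <- min(t0, nearest); hi <- max(t0, nearest)
      nins <- 0L
      if (nrow(layout$insulators)) {
        for (ii in seq_len(nrow(layout$insulators))) {
          ins <- layout$insulators[ii, ]
          if (ins$chrom != g$chrom) next
          m <- (ins$start + ins$end) / 2
          if (m > lo && m < hi) nins <- nins + 1L
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(crm_id = cr$crm_id, gene_id = g$gene_id,
                   distance = d, insulator_count = nins,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# AUC by exhaustive positive-negative pair counting, ties counted half
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# expression log-likelihood at one dmax, computed by naive loops
oracle_expression_ll <- function(dmax, links, A, R, labels,
                                 insulator_limit = 0L, eps = 1e-9) {
  total <- 0
  for (j in rownames(labels)) for (cl in colnames(labels)) {
    y <- labels[j, cl]
    if (is.na(y)) next
    rows <- links[links$gene_id == j, , drop = FALSE]
    q <- 1
    if (nrow(rows)) for (k in seq_len(nrow(rows))) {
      w <- if (rows$insulator_count[k] > insulator_limit) 0
           else max(0, 1 - rows$distance[k] / dmax)
      q <- q * (1 - A[rows$crm_id[k], cl] * w)
    }
    p <- min(max(R[j, cl] * (1 - q), eps), 1 - eps)
    total <- total + if (y == 1) log(p) else log(1 - p)
  }
  total
}

# exact conditional posterior of one CRM's activity: other CRM activities
# fixed at the supplied values, genes' likelihoods enumerated per gene
# over the joint binary states of its other linked CRMs
oracle_crm_posterior <- function(i, cl, f, A_others, links, R, labels,
                                 dmax, insulator_limit = 0L, eps = 1e-9) {
  crms <- rownames(A_others)
  lik <- c(`0` = 1, `1` = 1)
  for (a in 0:1) {
    for (j in rownames(labels)) {
      y <- labels[j, cl]
      if (is.na(y)) next
      rows <- links[links$gene_id == j, , drop = FALSE]
      rows$w <- ifelse(rows$insulator_count > insulator_limit, 0,
                       pmax(0, 1 - rows$distance / dmax))
      rows <- rows[rows$w > 0, , drop = FALSE]
      if (!crms[i] %in% rows$crm_id) next     # gene out of CRM i's range
      others <- rows[rows$crm_id != crms[i], , drop = FALSE]
      w_i <- rows$w[rows$crm_id == crms[i]]
      no <- nrow(others)
      p_on <- 0
      for (s in 0:(2^no - 1)) {
        bits <- if (no) as.integer(intToBits(s))[seq_len(no)] else integer(0)
        pr <- if (no)
          prod(ifelse(bits == 1L, A_others[others$crm_id, cl],
                      1 - A_others[others$crm_id, cl])) else 1
        fail <- prod(ifelse(bits == 1L, 1 - others$w, 1)) * (1 - a * w_i)
        p_on <- p_on + pr * R[j, cl] * (1 - fail)
      }
      p_on <- min(max(p_on, eps), 1 - eps)
      lik[a + 1L] <- lik[a + 1L] * if (y == 1) p_on else 1 - p_on
    }
  }
  f[i, cl] * lik[2L] / (f[i, cl] * lik[2L] + (1 - f[i, cl]) * lik[1L])
}

# small random world shared by several suites
tiny_world <- function(seed, n_genes = 60L, n_crms = 30L) {
  suppressWarnings(simulate_dataset(sim_config(
    n_genes = n_genes, n_crms = n_crms, seed = seed,
    chrom_length = n_genes * 8000)))
}
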