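# small worlds are built by helpers; the EM itself is exercised end-to-end
# in test-acceptance.R at desk scale

make_micro_data <- function(seed, n_genes = 60L, n_crms = 30L) {
  b <- tiny_world(seed, n_genes, n_crms)
  list(bundle = b,
       data = suppressWarnings(
         model_data(b$occupancy, b$links, b$R, b$gene_labels,
                    b$crm_labels)))
}

test_that("backward probabilities: closed cases", {
  # one CRM, one gene, W = 1, R = 1, gene expressed: the CRM is the only
  # possible activator
  occ <- matrix(c(1, 2), 1, 2,
                dimnames = list("c1", c("v1", "v2")))
  class(occ) <- c("occupancy_matrix", class(occ))
  links <- data.frame(crm_id = "c1", gene_id = "g1", distance = 0,
                      insulator_count = 0L)
  class(links) <- c("link_table", "data.frame")
  R <- matrix(1, 1, 1, dimnames = list("g1", "cls"))
  gl <- label_table("g1", "cls", 1L)
  d <- model_data(occ, links, R, gl,
                  discretizer = suppressWarnings(fit_discretizer(
                    rbind(occ, occ + 1))))
  A <- matrix(0.5, 1, 1, dimnames = list("c1", "cls"))
  b <- backward_probability(A, d, dmax = 1000)
  expect_equal(unname(b$b1["c1", "cls"]), 1)
  expect_lt(unname(b$b0["c1", "cls"]), 1e-8)

  # a CRM linked to no labeled gene is uninformative
  gl2 <- label_table("g1", "cls", 1L)
  d2 <- d
  d2$links <- d$links[0, , drop = FALSE]
  b2 <- backward_probability(A, d2, dmax = 1000)
  expect_equal(unname(b2$b1["c1", "cls"]), unname(b2$b0["c1", "cls"]))
})

test_that("backward matches per-gene enumeration on a 2x2 toy", {
  # two CRMs, two genes, mixed labels; other CRM fixed at its estimate
  crms <- c("c1", "c2"); genes <- c("g1", "g2")
  occ <- matrix(rnorm(4), 2, 2, dimnames = list(crms, c("v1", "v2")))
  class(occ) <- c("occupancy_matrix", class(occ))
  links <- data.frame(
    crm_id = c("c1", "c2", "c1", "c2"),
    gene_id = c("g1", "g1", "g2", "g2"),
    distance = c(0, 5000, 2000, 1000), insulator_count = 0L)
  class(links) <- c("link_table", "data.frame")
  R <- matrix(c(0.95, 0.8), 2, 1, dimnames = list(genes, "cls"))
  gl <- label_table(genes, "cls", c(1L, 0L))
  d <- model_data(occ, links, R, gl,
                  discretizer = suppressWarnings(
                    fit_discretizer(rbind(occ, occ + 1))))
  A <- matrix(c(0.6, 0.3), 2, 1, dimnames = list(crms, "cls"))
  dmax <- 10000
  got <- backward_probability(A, d, dmax)
  labels <- label_matrix(gl, genes, "cls")
  W <- matrix(0, 2, 2, dimnames = list(crms, genes))
  for (k in seq_len(nrow(links)))
    W[links$crm_id[k], links$gene_id[k]] <-
      crm_gene_weight(links$distance[k], 0L, dmax)
  for (i in 1:2) {
    for (a in 0:1) {
      lik <- 1
      for (j in 1:2) {
        if (W[i, j] == 0) next
        other <- setdiff(1:2, i)
        q <- (1 - a * W[i, j]) * (1 - A[other, 1] * W[other, j])
        p <- R[j, 1] * (1 - q)
        lik <- lik * if (labels[j, 1] == 1) p else 1 - p
      }
      if (a == 0) l0 <- lik else l1 <- lik
    }
    m <- max(l0, l1)
    expect_equal(unname(got$b1[i, 1]), l1 / m, tolerance = 1e-12)
    expect_equal(unname(got$b0[i, 1]), l0 / m, tolerance = 1e-12)
  }
})

test_that("e_step smoothing: closed cases", {
  md <- make_micro_data(31L)
  d <- md$data
  bn <- fit_cpts(learn_structure(d$evidence, md$bundle$truth$activity),
                 d$evidence, md$bundle$truth$activity)
  # uninformative backward (no labeled genes) -> smoothed == forward
  d_nolab <- d
  d_nolab$gene_label_matrix[] <- NA_real_
  post <- e_step(bn, d_nolab, dmax = 20000)
  expect_equal(post$smoothed, post$forward)
  # forward 0.5, b1 = 1, b0 = 0 -> smoothed 1 (via the formula itself)
  expect_equal(0.5 * 1 / (0.5 * 1 + 0.5 * 0), 1)
})

test_that("smoothed posterior equals the exact conditional posterior", {
  md <- make_micro_data(32L, n_genes = 24L, n_crms = 10L)
  d <- md$data
  bn <- fit_cpts(learn_structure(d$evidence, md$bundle$truth$activity),
                 d$evidence, md$bundle$truth$activity)
  f <- forward_probability(bn, d$evidence)
  post <- e_step(bn, d, dmax = 20000, A_prev = f)
  labels <- d$gene_label_matrix
  for (i in sample(nrow(f), 4)) {
    for (cl in sample(colnames(f), 2)) {
      want <- oracle_crm_posterior(i, cl, f, f, d$links, d$R, labels,
                                   dmax = 20000)
      expect_equal(unname(post$smoothed[i, cl]), unname(want),
                   tolerance = 1e-9)
    }
  }
})

test_that("m_step picks the dmax grid argmax (exhaustive oracle)", {
  md <- make_micro_data(33L)
  d <- md$data
  A <- md$bundle$truth$activity
  grid <- c(10000, 20000, 40000)
  ll_oracle <- vapply(grid, oracle_expression_ll, numeric(1),
                      links = d$links, A = A, R = d$R,
                      labels = d$gene_label_matrix)
  ll_pkg <- crm2gene:::dmax_profile(grid, A, d)
  expect_equal(ll_pkg, ll_oracle, tolerance = 1e-9)
})

test_that("m_step recovers the planted dmax within one grid step", {
  cfg <- default_paper_scale("desk", seed = 2L)
  b <- simulate_dataset(cfg)
  d <- model_data(b$occupancy, b$links, b$R, b$gene_labels, b$crm_labels)
  ms <- m_step(b$truth$activity, d)
  expect_lte(abs(ms$dmax - b$truth$dmax), 200)
})

test_that("m_step leaves dmax unchanged without labeled genes", {
  md <- make_micro_data(34L)
  d <- md$data
  d$gene_label_matrix[] <- NA_real_
  expect_message(
    ms <- m_step(md$bundle$truth$activity, d, current_dmax = 7400),
    "dmax left unchanged")
  expect_equal(ms$dmax, 7400)
})

test_that("run_em is deterministic and monotone, within the iteration cap", {
  md <- make_micro_data(35L, n_genes = 150L, n_crms = 70L)
  s1 <- run_em(md$data, init = "cad")
  s2 <- run_em(md$data, init = "cad")
  expect_identical(s1$ll_trace, s2$ll_trace)
  expect_identical(s1$dmax, s2$dmax)
  expect_true(all(diff(s1$ll_trace) >= -1e-9))
  expect_lte(s1$iterations, 50L)
})

test_that("fully observed, clamped CRM activities degenerate to the
          supervised fit in one step", {
  cfg <- sim_config(n_genes = 150L, n_crms = 70L, seed = 36L,
                    reveal_crm_fraction = 1)
  b <- simulate_dataset(cfg)
  d <- model_data(b$occupancy, b$links, b$R, b$gene_labels, b$crm_labels)
  st <- run_em(d, init = "cad", clamp_known_crms = TRUE)
  sup <- fit_cpts(learn_structure(d$evidence, d$crm_label_matrix),
                  d$evidence, d$crm_label_matrix)
  for (cl in names(sup$nodes))
    expect_identical(st$bn$nodes[[cl]]$parents, sup$nodes[[cl]]$parents)
})

test_that("initialize_from_cad equals the supervised fit on the labeled
          subset and errors without labels", {
  md <- make_micro_data(37L)
  d <- md$data
  init <- initialize_from_cad(d)
  sup <- fit_cpts(learn_structure(d$evidence, d$crm_label_matrix),
                  d$evidence, d$crm_label_matrix)
  for (cl in names(sup$nodes)) {
    expect_identical(init$bn$nodes[[cl]]$parents, sup$nodes[[cl]]$parents)
    expect_equal(init$bn$nodes[[cl]]$cpt, sup$nodes[[cl]]$cpt)
  }
  expect_equal(init$dmax, d$window)
  d$crm_label_matrix <- NULL
  expect_error(initialize_from_cad(d), "nearest_gene")
})

test_that("nearest-gene proxy labels: threshold, union, and recount", {
  links <- data.frame(
    crm_id = c("c1", "c2", "c3", "c3"),
    gene_id = c("g1", "g1", "g1", "g2"),
    distance = c(300, 600, 100, 400), insulator_count = 0L)
  class(links) <- c("link_table", "data.frame")
  gl <- label_table(c("g1", "g1", "g2", "g2"),
                    c("meso", "vm", "meso", "vm"), c(1L, 0L, 0L, 1L))
  proxy <- initialize_nearest_gene(links, gl)
  m <- label_matrix(proxy, c("c1", "c2", "c3"), c("meso", "vm"))
  expect_equal(unname(m["c1", ]), c(1, 0))     # inherits g1
  expect_true(all(is.na(m["c2", ])))           # 600 bp: beyond threshold
  expect_equal(unname(m["c3", ]), c(1, 1))     # union of g1 and g2

  b <- tiny_world(38L, n_genes = 120L, n_crms = 60L)
  got <- initialize_nearest_gene(b$links, b$gene_labels)
  # brute-force recount
  lm <- label_matrix(b$gene_labels, rownames(b$R), colnames(b$R))
  for (cr in unique(b$links$crm_id)) {
    near <- b$links$gene_id[b$links$crm_id == cr & b$links$distance < 500]
    near <- near[near %in% b$gene_labels$entity_id]
    for (cl in colnames(b$R)) {
      want <- if (length(near)) max(lm[near, cl]) else NA_real_
      have <- got$label[got$entity_id == cr & got$class == cl]
      if (is.na(want)) expect_length(have, 0L)
      else expect_equal(have, want)
    }
  }
})

test_that("two-layer baseline features and ordering of AUCs", {
  md <- make_micro_data(39L, n_genes = 300L, n_crms = 150L)
  d <- md$data
  tl <- two_layer_model(d)
  # a gene with no linked CRM has an all-zero feature vector
  linked <- unique(d$links$gene_id[
    crm_gene_weight(d$links$distance, d$links$insulator_count,
                    d$window, 0L) > 0])
  lonely <- setdiff(rownames(d$R), linked)
  if (length(lonely))
    expect_true(all(tl$features[lonely, ] == 0))
  # a single-CRM gene's features equal that CRM's occupancy x weight
  tab <- table(d$links$gene_id)
  singles <- names(tab)[tab == 1L]
  if (length(singles)) {
    g <- singles[1L]
    row <- d$links[d$links$gene_id == g, ]
    w <- crm_gene_weight(row$distance, row$insulator_count, d$window, 0L)
    expect_equal(unname(tl$features[g, ]),
                 unname(unclass(d$occupancy)[row$crm_id, ] * w))
  }
  # two-layer AUC beats chance but trails the three-layer model
  b <- md$bundle
  held <- setdiff(rownames(b$R), unique(b$gene_labels$entity_id))
  st <- run_em(d, init = "cad")
  pred3 <- predict_from_state(st, d)
  auc2 <- auc3 <- numeric(0)
  for (cl in colnames(b$R)) {
    y <- b$truth$expression[held, cl]
    if (length(unique(y)) < 2L) next
    auc2 <- c(auc2, roc_auc(tl$p[held, cl], y)$auc)
    auc3 <- c(auc3, roc_auc(pred3$p[held, cl], y)$auc)
  }
  expect_gt(mean(auc2), 0.5)
  expect_gt(mean(auc3), mean(auc2))
})

test_that("EM runs from nearest_gene and two_layer initializations", {
  md <- make_micro_data(40L, n_genes = 200L, n_crms = 100L)
  for (ini in c("nearest_gene", "two_layer")) {
    st <- run_em(md$data, init = ini)
    expect_true(all(diff(st$ll_trace) >= -1e-9))
    expect_true(all(st$posterior$smoothed >= 0 &
                      st$posterior$smoothed <= 1))
  }
})
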