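test_that("discretizer recovers a well-separated mixture", {
  set.seed(101)
  v <- c(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  occ <- matrix(v, ncol = 1, dimnames = list(NULL, "x"))
  disc <- fit_discretizer(occ)
  f <- disc$fits[["x"]]
  expect_false(f$degenerate)
  expect_lt(abs(f$means[1L] - 0), 0.2)
  expect_lt(abs(f$means[2L] - 10), 0.2)
  expect_equal(sum(f$weights), 1)
})

test_that("degenerate constant column falls back to p_bound 0.5", {
  occ <- cbind(x = rnorm(50), const = rep(2, 50))
  disc <- fit_discretizer(occ)
  expect_true(disc$fits[["const"]]$degenerate)
  E <- soft_evidence(disc, occ)
  expect_true(all(E[, "const"] == 0.5))
})

test_that("equal-posterior point of a fitted mixture gives p_bound 0.5", {
  set.seed(102)
  occ <- matrix(c(rnorm(1000, 0, 1), rnorm(1000, 6, 1)), ncol = 1,
                dimnames = list(NULL, "x"))
  disc <- fit_discretizer(occ)
  f <- disc$fits[["x"]]
  xstar <- uniroot(function(x)
    f$weights[1] * dnorm(x, f$means[1], f$sds[1]) -
      f$weights[2] * dnorm(x, f$means[2], f$sds[2]),
    c(f$means[1], f$means[2]))$root
  E <- soft_evidence(disc, matrix(xstar, 1, 1, dimnames = list(NULL, "x")))
  expect_equal(unname(E[1, 1]), 0.5, tolerance = 1e-4)
})

test_that("bde_score matches the Beta-Bernoulli closed form", {
  # empty parent set, hard labels {1,1,0}, ess = 1 -> alpha = beta = 0.5
  got <- bde_score(c(1, 1, 0), NULL, ess = 1)
  expect_equal(got, lbeta(0.5 + 2, 0.5 + 1) - lbeta(0.5, 0.5))
})

test_that("bde_score with hard evidence equals the discrete Dirichlet
          integral on random toys", {
  set.seed(103)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    p <- sample(0:2, 1)
    y <- rbinom(n, 1, 0.5)
    X <- if (p) matrix(rbinom(n * p, 1, 0.5), n, p) else NULL
    ess <- sample(c(0.5, 1, 2), 1)
    got <- bde_score(y, X, ess)
    want <- oracle_bde_discrete(y, X, ess)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("a constant parent never increases a hard-label BDe score", {
  set.seed(104)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    y <- rbinom(n, 1, 0.5)
    X <- matrix(rbinom(n, 1, 0.5), n, 1)
    const <- matrix(1, n, 1)
    expect_lte(bde_score(y, cbind(X, const), 1), bde_score(y, X, 1) + 1e-12)
    expect_lte(bde_score(y, const, 1), bde_score(y, NULL, 1) + 1e-12)
  }
})

test_that("learn_structure recovers a planted single-parent network", {
  set.seed(105)
  n <- 500L
  nv <- 6L
  B <- matrix(rbinom(n * nv, 1, 0.4), n, nv,
              dimnames = list(NULL, paste0("tf", 1:nv, "_t2")))
  y <- rbinom(n, 1, ifelse(B[, 2L] == 1, 0.9, 0.1))   # class <- tf2_t2
  E <- 0.9 * B + 0.05                                 # noisy soft evidence
  bn <- learn_structure(E, cbind(cls = y), max_parents = 3L, ess = 1)
  expect_identical(bn$nodes[["cls"]]$parents, "tf2_t2")
})

test_that("coin-flip labels select the empty parent set", {
  set.seed(106)
  n <- 500L
  E <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rbinom(n, 1, 0.5)
  bn <- learn_structure(E, cbind(cls = y))
  expect_length(bn$nodes[["cls"]]$parents, 0L)
})

test_that("a single perfectly predictive variable is selected", {
  y <- rep(c(1, 0), each = 10)
  E <- matrix(y, ncol = 1, dimnames = list(NULL, "v1"))
  bn <- learn_structure(E, cbind(cls = y), max_parents = 1L)
  expect_identical(bn$nodes[["cls"]]$parents, "v1")
})

test_that("learn_structure equals exhaustive enumeration (random toys)", {
  set.seed(107)
  for (rep in 1:5) {
    n <- 40L
    nv <- sample(4:10, 1)
    E <- matrix(runif(n * nv), n, nv,
                dimnames = list(NULL, paste0("v", seq_len(nv))))
    y <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    mp <- sample(1:3, 1)
    bn <- learn_structure(E, y, max_parents = mp, ess = 1)
    for (cl in c("a", "b"))
      expect_identical(sort(bn$nodes[[cl]]$parents),
                       oracle_best_subset(E, y[, cl], mp, 1))
  }
})

test_that("fit_cpts: ML frequencies, fractional counts, and smoothing", {
  # no parents, 3 active / 1 inactive, ess -> 0: P(active) = 0.75
  E <- matrix(numeric(0), 4, 0)
  bn <- learn_structure(matrix(0.5, 4, 1, dimnames = list(NULL, "v1")),
                        cbind(cls = c(1, 1, 1, 0)), max_parents = 0L,
                        ess = 1e-12)
  bn <- fit_cpts(bn, matrix(0.5, 4, 1, dimnames = list(NULL, "v1")),
                 cbind(cls = c(1, 1, 1, 0)))
  expect_equal(bn$nodes[["cls"]]$cpt, 0.75, tolerance = 1e-9)

  # all-soft toy: 2 CRMs, p_bound 0.5 each, labels {1, 0}; expected
  # fractional counts per configuration: N_act = 0.5, N_tot = 1
  ev <- matrix(0.5, 2, 1, dimnames = list(NULL, "v1"))
  bn2 <- structure(list(nodes = list(cls = list(parents = "v1")),
                        binding_vars = "v1", ess = 1, max_parents = 1L),
                   class = "bipartite_bn")
  bn2 <- fit_cpts(bn2, ev, cbind(cls = c(1, 0)))
  # per config: (0.5 + 1/4) / (1 + 1/2) = 0.5
  expect_equal(unname(bn2$nodes[["cls"]]$cpt), c(0.5, 0.5))

  # unseen parent configuration with ess > 0 falls back to prior mean 0.5
  ev3 <- matrix(1, 3, 1, dimnames = list(NULL, "v1"))   # always bound
  bn3 <- structure(list(nodes = list(cls = list(parents = "v1")),
                        binding_vars = "v1", ess = 1, max_parents = 1L),
                   class = "bipartite_bn")
  bn3 <- fit_cpts(bn3, ev3, cbind(cls = c(1, 1, 0)))
  expect_equal(unname(bn3$nodes[["cls"]]$cpt[1L]), 0.5)  # unbound unseen
})

test_that("forward_probability: closed cases and enumeration", {
  ev <- matrix(c(0.3, 0.8, 0.1, 0.6), 2, 2,
               dimnames = list(c("c1", "c2"), c("v1", "v2")))
  # no parents
  bn0 <- structure(list(nodes = list(cls = list(parents = character(0),
                                                cpt = 0.7)),
                        binding_vars = c("v1", "v2"), ess = 1,
                        max_parents = 3L), class = "bipartite_bn")
  expect_equal(unname(forward_probability(bn0, ev)[, "cls"]), c(0.7, 0.7))
  # one parent, p_bound 1, P(active | bound) = 0.9
  ev1 <- matrix(1, 1, 1, dimnames = list("c1", "v1"))
  bn1 <- structure(list(nodes = list(cls = list(parents = "v1",
                                                cpt = c(0.2, 0.9))),
                        binding_vars = "v1", ess = 1, max_parents = 3L),
                   class = "bipartite_bn")
  expect_equal(unname(forward_probability(bn1, ev1)[1, "cls"]), 0.9)
  # two soft parents: enumeration over the 4 configurations
  cpt <- c(0.05, 0.6, 0.3, 0.95)   # order: 00, 10, 01, 11 (low bit = v1)
  bn2 <- structure(list(nodes = list(cls = list(parents = c("v1", "v2"),
                                                cpt = cpt)),
                        binding_vars = c("v1", "v2"), ess = 1,
                        max_parents = 3L), class = "bipartite_bn")
  got <- forward_probability(bn2, ev)[, "cls"]
  for (i in 1:2) {
    p1 <- ev[i, "v1"]; p2 <- ev[i, "v2"]
    want <- cpt[1] * (1 - p1) * (1 - p2) + cpt[2] * p1 * (1 - p2) +
      cpt[3] * (1 - p1) * p2 + cpt[4] * p1 * p2
    expect_equal(unname(got[i]), want)
  }
})

test_that("forward probabilities stay in [0,1] and respect monotone CPTs", {
  set.seed(108)
  b <- tiny_world(3L)
  d <- model_data(b$occupancy, b$links, b$R, b$gene_labels, b$crm_labels)
  bn <- learn_structure(d$evidence, b$truth$activity)
  bn <- fit_cpts(bn, d$evidence, b$truth$activity)
  f <- forward_probability(bn, d$evidence)
  expect_true(all(f >= 0 & f <= 1))
  # monotone CPT in one parent: raising that parent's evidence cannot
  # lower the forward probability
  cl <- names(which(vapply(bn$nodes, function(n)
    length(n$parents) == 1L, logical(1))))[1L]
  if (!is.na(cl)) {
    par <- bn$nodes[[cl]]$parents
    if (diff(bn$nodes[[cl]]$cpt) >= 0) {
      ev_hi <- d$evidence
      ev_hi[, par] <- pmin(ev_hi[, par] + 0.2, 1)
      expect_true(all(forward_probability(bn, ev_hi)[, cl] >=
                        f[, cl] - 1e-12))
    }
  }
})

test_that("bipartite network text serialization round-trips", {
  b <- tiny_world(5L)
  d <- model_data(b$occupancy, b$links, b$R, b$gene_labels, b$crm_labels)
  bn <- fit_cpts(learn_structure(d$evidence, b$truth$activity),
                 d$evidence, b$truth$activity)
  f <- withr::local_tempfile(fileext = ".txt")
  write_bn(bn, f)
  bn2 <- read_bn(f)
  expect_identical(names(bn2$nodes), names(bn$nodes))
  for (cl in names(bn$nodes)) {
    expect_identical(bn2$nodes[[cl]]$parents, bn$nodes[[cl]]$parents)
    expect_equal(unname(bn2$nodes[[cl]]$cpt), unname(bn$nodes[[cl]]$cpt))
  }
})
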