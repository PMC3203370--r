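test_that("smoothing matrix matches its closed forms", {
  expect_identical(unclass(smoothing_matrix(2, 0))[, ], diag(2))
  S1 <- smoothing_matrix(2, 1)
  expect_true(all(S1 == 0.5))
  expect_equal(as.numeric(S1 %*% c(1, 3)), c(2, 2))  # the mean vector
  S <- smoothing_matrix(3, 0.5)
  expect_true(all(abs(diag(S) - 2 / 3) < 1e-15))
  expect_true(all(abs(S[row(S) != col(S)] - 1 / 6) < 1e-15))
  expect_error(smoothing_matrix(2, 1.1), "theta")
})

test_that("smoothing-matrix rows sum to 1 for random k and theta", {
  set.seed(50)
  for (i in 1:25) {
    k <- sample(1:8, 1)
    th <- runif(1)
    S <- smoothing_matrix(k, th)
    expect_lt(max(abs(rowSums(S) - 1)), 1e-12)
    expect_true(all(S >= 0))
    expect_identical(unclass(S)[, ], t(unclass(S))[, ])
  }
})

test_that("Hoyer sparseness matches hand-computed values", {
  expect_equal(hoyer_sparseness(c(0, 0, 1, 0)), 1)
  expect_equal(hoyer_sparseness(rep(3, 4)), 0)
  expect_equal(hoyer_sparseness(c(1, 1, 0, 0)), 2 - sqrt(2))
  expect_error(hoyer_sparseness(c(0, 0)), "zero vector")
  expect_error(hoyer_sparseness(5), "length")
})

test_that("an exact rank-1 factorization is found", {
  V <- outer(c(1, 2, 3), c(4, 5))
  fit <- nsnmf_once(V, k = 1, theta = 0, n_iter = 2000, seed = 1L)
  rec <- fit$metagenes %*% fit$encodings
  expect_lt(norm(V - rec, "F") / norm(V, "F"), 1e-6)
  expect_equal(sum(fit$metagenes), 1, tolerance = 1e-9)  # unit l1 column
})

test_that("the theta = 0 path reproduces classical KL-NMF updates", {
  # independent plain-R oracle for the Lee-Seung divergence updates
  set.seed(60)
  V <- matrix(runif(15 * 6), 15, 6)
  eps <- 1e-9
  ini <- mfgex:::with_seed(3L, list(
    W = matrix(runif(15 * 2, eps, 1), 15),
    H = matrix(runif(2 * 6, eps, 1), 2)))
  W <- ini$W; H <- ini$H
  for (it in 1:25) {
    H <- H * (t(W) %*% (V / (W %*% H))) / colSums(W)
    H[H < eps] <- eps
    W <- W * ((V / (W %*% H)) %*% t(H)) / rep(rowSums(H), each = nrow(W))
    W[W < eps] <- eps
  }
  fit <- nsnmf_once(V, k = 2, theta = 0, n_iter = 25, seed = 3L)
  # undo the final unit-l1 rescaling before comparing
  sc <- colSums(W)
  expect_equal(fit$metagenes, sweep(W, 2, sc, "/"), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$encodings, H * sc, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the KL objective trace is nonincreasing", {
  set.seed(61)
  V <- matrix(runif(500), 50, 10)
  fit <- nsnmf_once(V, k = 3, theta = 0.5, n_iter = 2000, seed = 4L)
  expect_lte(max(diff(fit$objective_trace)), 1e-9)
  expect_identical(fit$iterations, 2000L)
})

test_that("factors stay nonnegative and V preconditions are enforced", {
  set.seed(62)
  V <- matrix(runif(200), 20, 10)
  fit <- nsnmf_once(V, k = 2, theta = 0.7, n_iter = 100, seed = 5L)
  expect_true(all(fit$metagenes >= 0) && all(fit$encodings >= 0))
  expect_error(nsnmf_once(V - 10, k = 2), "nonnegative")
  expect_error(nsnmf_once(V, k = 15), "exceeds min")
  Vz <- V; Vz[3, ] <- 0
  expect_warning(nsnmf_once(Vz, k = 2, n_iter = 10, seed = 1L), "all-zero")
})

test_that("multistart equals a single run for one restart and min-selects", {
  set.seed(63)
  V <- matrix(runif(300), 30, 10)
  cfg1 <- run_config(seed = 9L, k = 2, nsnmf_n_restarts = 1L,
                     nsnmf_n_iter = 200L)
  ms <- nsnmf_multistart(V, cfg1)
  once <- nsnmf_once(V, k = 2, theta = cfg1$theta, n_iter = 200L,
                     seed = derive_seed(9L, "nsnmf", 1L))
  expect_identical(ms$metagenes, once$metagenes)
  expect_identical(ms$final_objective, once$final_objective)

  cfg5 <- run_config(seed = 9L, k = 2, nsnmf_n_restarts = 5L,
                     nsnmf_n_iter = 200L)
  cfg10 <- run_config(seed = 9L, k = 2, nsnmf_n_restarts = 10L,
                      nsnmf_n_iter = 200L)
  best5 <- nsnmf_multistart(V, cfg5)
  best10 <- nsnmf_multistart(V, cfg10)
  expect_identical(best10$restart_objectives[1:5], best5$restart_objectives)
  expect_lte(best10$final_objective, best5$final_objective)
})

test_that("multistart recovers planted metagene modules", {
  labels <- default_phenotypes()
  sim <- simulate_nmf_dataset(n_genes = 500, labels = labels, k = 2,
                              module_size = 50, seed = 70L)
  cfg <- run_config(seed = 70L, k = 2, theta = 0.5, nsnmf_n_restarts = 5L,
                    nsnmf_n_iter = 1000L)
  fit <- nsnmf_multistart(make_nonnegative(sim$data), cfg)
  gidx <- lapply(sim$truth$metagene_modules,
                 function(mod) match(mod, rownames(fit$metagenes)))
  # each planted module dominates exactly one W column
  ratios <- sapply(1:2, function(j) {
    w <- fit$metagenes[, j]
    max(sapply(gidx, function(ix) mean(w[ix]) / mean(w[-ix])))
  })
  expect_true(all(ratios > 5))
})

test_that("higher theta yields sparser metagenes on planted-module data", {
  labels <- default_phenotypes()
  sp <- sapply(71:73, function(seed) {
    sim <- simulate_nmf_dataset(n_genes = 300, labels = labels, k = 2,
                                module_size = 30, seed = seed)
    nn <- make_nonnegative(sim$data)
    f0 <- nsnmf_once(nn, k = 2, theta = 0, n_iter = 500, seed = seed)
    f7 <- nsnmf_once(nn, k = 2, theta = 0.7, n_iter = 500, seed = seed)
    c(median(f0$sparseness), median(f7$sparseness))
  })
  expect_true(all(sp[2, ] > sp[1, ]))
})

test_that("rescaling V leaves the normalized metagene support unchanged", {
  set.seed(64)
  labels <- tiny_labels()
  sim <- simulate_nmf_dataset(n_genes = 200, labels = labels, k = 2,
                              module_size = 25, seed = 80L)
  nn <- make_nonnegative(sim$data)
  f1 <- nsnmf_once(nn, k = 2, theta = 0.5, n_iter = 500, seed = 2L)
  f2 <- nsnmf_once(unclass(nn) * 7, k = 2, theta = 0.5, n_iter = 500,
                   seed = 2L)
  top1 <- apply(f1$metagenes, 2, function(w) order(-w)[1:25])
  top2 <- apply(f2$metagenes, 2, function(w) order(-w)[1:25])
  expect_identical(sort(as.vector(top1)), sort(as.vector(top2)))
})
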