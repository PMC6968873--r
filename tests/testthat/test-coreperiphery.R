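test_that("consistency matrix counts edge persistence across layers", {
  A1 <- A2 <- A3 <- A4 <- A5 <- matrix(0, 4, 4)
  always <- cbind(c(1, 2), c(2, 1))
  A1[always] <- A2[always] <- A3[always] <- A4[always] <- A5[always] <- 1
  ## edge (3,4) present in 3 of the 5 layers
  A1[3, 4] <- A1[4, 3] <- A2[3, 4] <- A2[4, 3] <- A3[3, 4] <- A3[4, 3] <- 1
  ml <- toy_multilayer(list(A1, A2, A3, A4, A5))
  G <- consistency_matrix(ml)
  expect_equal(G$G[1, 2], 1)
  expect_equal(G$G[3, 4], 0.6)
  expect_equal(G$G[1, 3], 0)
  expect_equal(diag(G$G), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(abs(G$G * 5 - round(G$G * 5)) < 1e-12))
})

test_that("coreness template follows the sigmoid and its limits", {
  expect_equal(core_template(7, 0, 0.5), rep(0.5, 7))
  ## m = beta * N lands exactly on the midpoint
  tmpl <- core_template(10, 0.6, 0.5)
  expect_equal(tmpl[5], 0.5)
  ## nondecreasing in m for a sweep of parameter pairs
  for (a in c(0, 0.3, 0.7, 0.95, 1)) {
    for (b in c(0, 0.2, 0.5, 0.8, 1)) {
      expect_true(all(diff(core_template(25, a, b)) >= 0))
    }
  }
  ## binary step limit
  step <- core_template(10, 1, 0.5)
  expect_equal(step, c(rep(0, 4), 0.5, rep(1, 5)))
  ## closed-form check at one interior point
  expect_equal(core_template(10, 0.4, 0.3)[7],
               1 / (1 + exp(-(7 - 3) * tan(pi * 0.2))), tolerance = 1e-12)
})

test_that("core quality matches direct evaluation and its invariances", {
  G <- matrix(c(0, 2, 1, 0,
                2, 0, 3, 1,
                1, 3, 0, 2,
                0, 1, 2, 0) / 4, 4, 4)
  cvec <- c(0.9, 0.8, 0.3, 0.1)
  direct <- 0
  for (i in 1:4) for (j in 1:4) direct <- direct + G[i, j] * cvec[i] * cvec[j]
  expect_equal(core_quality(G, cvec), direct, tolerance = 1e-12)
  expect_equal(core_quality(matrix(0, 4, 4), cvec), 0)

  ## invariant under simultaneous permutation of G and coreness
  set.seed(41)
  G2 <- random_symmetric_weights(8)
  cv <- core_template(8, 0.5, 0.5)[sample.int(8)]
  perm <- sample.int(8)
  expect_equal(core_quality(G2, cv),
               core_quality(G2[perm, perm], cv[perm]), tolerance = 1e-12)

  ## swapping coreness of nodes with identical G rows leaves R unchanged
  G3 <- matrix(0.5, 5, 5); diag(G3) <- 0
  cv3 <- c(0.9, 0.1, 0.5, 0.5, 0.2)
  cv3b <- cv3[c(2, 1, 3, 4, 5)]
  expect_equal(core_quality(G3, cv3), core_quality(G3, cv3b))
})

test_that("annealing attains the factorial optimum on small matrices", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:7, 1)
    G <- random_symmetric_weights(n)
    alpha <- runif(1, 0.2, 0.9)
    beta <- runif(1, 0.2, 0.8)
    fit <- anneal_coreness(G, alpha, beta, n_restarts = 5,
                           max_sweeps = 100)
    expect_equal(fit$R, brute_best_R(G, core_template(n, alpha, beta)),
                 tolerance = 1e-10)
    ## coreness is a permutation of the template
    expect_equal(sort(fit$coreness),
                 sort(core_template(n, alpha, beta)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("persistent edges raise the optimal core quality", {
  set.seed(43)
  G <- random_symmetric_weights(12) * 0.5
  fit <- anneal_coreness(G, 0.8, 0.7, n_restarts = 5)
  idx <- order(fit$coreness, decreasing = TRUE)[1:2]
  G2 <- G
  G2[idx[1], idx[2]] <- G2[idx[2], idx[1]] <- 1
  fit2 <- anneal_coreness(G2, 0.8, 0.7, n_restarts = 5)
  expect_gte(fit2$R, fit$R)
})

test_that("grid search covers the parameter plane and is centered under a null G", {
  pts <- caimnet:::grid_points(31)
  expect_equal(nrow(pts), 961L)
  expect_length(unique(pts$alpha), 31L)
  expect_length(unique(pts$beta), 31L)
  expect_equal(range(pts$alpha), c(0, 1))

  ## uniformly random G: delta_R has no systematic sign
  set.seed(44)
  deltas <- replicate(6, {
    G <- random_symmetric_weights(12)
    gr <- grid_search(G, n_grid = 3, n_null = 10, n_restarts = 2,
                      max_sweeps = 60)
    mean(gr$delta_R)
  })
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)))

  ## structured G: the observed core beats the weight-shuffled null
  core_block <- matrix(0, 20, 20)
  core_block[1:5, 1:5] <- 1
  diag(core_block) <- 0
  gr2 <- grid_search(core_block + 0.05, n_grid = 3, n_null = 10,
                     n_restarts = 2, max_sweeps = 60)
  expect_gt(max(gr2$delta_R), 0)
  expect_equal(sum(gr2$top10), 1L)  # ceiling of 10% of 9 points
})

test_that("planted persistent core is recovered from the consistency matrix", {
  set.seed(45)
  cfg <- core_config(45)
  st <- generate_study(cfg)
  nets <- lapply(st$sessions, build_network, n_jitter = 100)
  ml <- build_multilayer(nets)
  G <- consistency_matrix(ml)
  fit <- anneal_coreness(G, alpha = 0.9, beta = 0.8)
  truth <- names(which(st$ground_truth$core_mask))
  overlap <- mean(top_core_ids(fit, 0.2) %in% truth)
  expect_gte(overlap, 0.8)
})

test_that("core cells keep more stable connections than the periphery", {
  set.seed(46)
  cfg <- core_config(46)
  st <- generate_study(cfg)
  nets <- lapply(st$sessions, build_network, n_jitter = 100)
  ml <- build_multilayer(nets)
  fit <- anneal_coreness(consistency_matrix(ml), alpha = 0.9, beta = 0.8)
  cs <- core_noncore_stability(nets, fit, top_frac = 0.2, n_perm = 200)
  expect_gt(cs$core$r, cs$noncore$r)
  ## core and non-core partition the fitted node set
  expect_setequal(c(cs$core_ids,
                    setdiff(names(fit$coreness), cs$core_ids)),
                  names(fit$coreness))
})

test_that("degenerate flat template flags the arbitrary core selection", {
  set.seed(47)
  G <- random_symmetric_weights(10)
  fit <- anneal_coreness(G, alpha = 0, beta = 0.5, n_restarts = 2)
  expect_warning(top_core_ids(fit, 0.1), "tie-break")
})

test_that("flexibility-coreness correlation recovers exact and null relations", {
  prof <- function(f) {
    structure(list(profile = data.frame(
      cell_id = sprintf("c%02d", seq_along(f)),
      mean_rank_flexibility = f,
      mean_flexibility = f / max(f))), class = "flexibility_profile")
  }
  f <- c(5, 3, 8, 1, 6, 2, 7, 4)
  core_exact <- 1 - f / max(f)
  names(core_exact) <- sprintf("c%02d", 1:8)
  expect_equal(flexibility_vs_coreness(prof(f), core_exact), -1)

  set.seed(48)
  rhos <- replicate(100, {
    fr <- sample(1:20)
    cr <- runif(20)
    names(cr) <- sprintf("c%02d", 1:20)
    flexibility_vs_coreness(prof(fr), cr)
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))

  const <- rep(0.5, 8)
  names(const) <- sprintf("c%02d", 1:8)
  expect_warning(out <- flexibility_vs_coreness(prof(f), const),
                 "constant")
  expect_true(is.na(out))
})
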