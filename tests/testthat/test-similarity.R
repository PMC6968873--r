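make_named <- function(M, ids) { dimnames(M) <- list(ids, ids); M }

test_that("shared submatrices restrict to the cell intersection", {
  ids_u <- c("a", "b", "c")
  ids_v <- c("b", "c", "d")
  M_u <- make_named(matrix(1:9 + 0, 3), ids_u)
  M_v <- make_named(matrix(9:1 + 0, 3), ids_v)
  sub <- shared_submatrices(M_u, M_v, min_shared = 2)
  expect_equal(sub$shared_ids, c("b", "c"))
  expect_equal(dim(sub$M_u), c(2L, 2L))
  expect_equal(sub$M_u, M_u[2:3, 2:3])
  expect_equal(sub$M_v, M_v[1:2, 1:2])

  ## identical sets pass through unchanged
  sub2 <- shared_submatrices(M_u, make_named(matrix(0, 3, 3), ids_u),
                             min_shared = 3)
  expect_equal(sub2$M_u, M_u)

  ## disjoint sets are skipped with a warning
  M_w <- make_named(matrix(0, 3, 3), c("x", "y", "z"))
  expect_warning(out <- shared_submatrices(M_u, M_w, min_shared = 10),
                 "skipped")
  expect_null(out)
})

test_that("matrix similarity uses only the strictly upper triangle", {
  set.seed(21)
  M <- random_symmetric_weights(4)
  N <- random_symmetric_weights(4)
  r <- matrix_similarity(M, N)
  ## independent oracle: direct Pearson formula on the 6 upper elements
  mu <- M[upper.tri(M)]; nu <- N[upper.tri(N)]
  expect_equal(r, sum((mu - mean(mu)) * (nu - mean(nu))) /
                 sqrt(sum((mu - mean(mu))^2) * sum((nu - mean(nu))^2)),
               tolerance = 1e-12)

  expect_equal(matrix_similarity(M, M), 1)
  M2 <- M; diag(M2) <- 99
  expect_equal(matrix_similarity(M2, N), r)
  expect_warning(matrix_similarity(matrix(1, 4, 4), N), "degenerate")
})

test_that("Mantel z separates shared structure from noise and matches vegan's statistic", {
  set.seed(22)
  block <- matrix(0.1, 20, 20)
  block[1:10, 1:10] <- block[11:20, 11:20] <- 0.9
  noise <- function() {
    E <- matrix(rnorm(400, sd = 0.05), 20)
    E <- (E + t(E)) / 2
    E
  }
  M_u <- block + noise(); M_v <- block + noise()
  diag(M_u) <- diag(M_v) <- 1
  hits <- sum(replicate(10, mantel_z(M_u, M_v, n_perm = 100)$z > 2))
  expect_gte(hits, 10)

  ## observed statistic equals vegan's Mantel r
  vg <- vegan::mantel(as.dist(1 - M_u), as.dist(1 - M_v),
                      permutations = 99)
  expect_equal(mantel_z(1 - M_u, 1 - M_v, n_perm = 100)$r_obs,
               unname(vg$statistic), tolerance = 1e-10)

  ## independent random matrices: z centered at zero
  set.seed(23)
  zs <- replicate(200, {
    A <- random_symmetric_weights(12)
    B <- random_symmetric_weights(12)
    mantel_z(A, B, n_perm = 100)$z
  })
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("decay analysis needs three usable pairs and flags degenerate input", {
  pairs <- data.frame(z = c(3, 2), d = c(3, 7))
  expect_error(decay_analysis(pairs), "at least 3")
  pairs3 <- data.frame(z = c(3, 3, 3), d = c(3, 7, 10))
  expect_warning(out <- decay_analysis(pairs3), "constant")
  expect_true(is.na(out$r))
  pairs_ok <- data.frame(z = c(5, 3, 1), d = c(2, 5, 9))
  expect_equal(decay_analysis(pairs_ok)$r, cor(c(5, 3, 1), c(2, 5, 9)))
})

test_that("similarity of drifting studies decays with day distance", {
  set.seed(24)
  cfg <- drift_config(24)
  st <- generate_study(cfg)
  nets <- lapply(st$sessions, build_network, n_jitter = 100)
  tab <- session_similarity(nets, kind = "correlation", n_perm = 200)
  expect_s3_class(tab, "session_pair_similarity")
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$n_shared >= 10))
  expect_true(all(tab$d >= 1))
  dec <- decay_analysis(tab)
  expect_lt(dec$r, -0.5)

  ## co-assignment route decays as well
  tabc <- session_similarity(nets, kind = "coassignment", n_perm = 200,
                             n_partitions = 100)
  expect_lt(decay_analysis(tabc)$r, 0)
})

test_that("hierarchy terciles split levels as expected", {
  expect_equal(caimnet:::level_terciles(9), rep(1:3, each = 3))
  expect_equal(caimnet:::level_terciles(2), c(1L, 1L))
  expect_equal(caimnet:::level_terciles(1), 1L)
})

test_that("tercile decay is negative at all depths of a drifting study", {
  set.seed(25)
  cfg <- synth_config(n_cells = 96L, n_sessions = 5L,
                      day_offsets = c(0L, 3L, 7L, 10L, 14L),
                      n_frames = 900L, noise_sd = 0.35,
                      hierarchy_branching = c(2L, 2L, 2L),
                      signal_strength_per_level = c(0.35, 0.5, 0.75),
                      core_fraction = 0.1, drift_prob_per_day = 0.1,
                      dropout_prob = 0.05, seed = 25L)
  st <- generate_study(cfg)
  nets <- lapply(st$sessions, build_network, n_jitter = 100)
  ## three-level reference hierarchies from the generator's ground truth
  hierarchies <- lapply(seq_along(nets), function(i) {
    labs <- st$ground_truth$labels[[i]][, nets[[i]]$cell_ids, drop = FALSE]
    structure(list(labels = labs, n_levels = nrow(labs),
                   gamma_per_level = seq_len(nrow(labs)),
                   p_per_level = rep(0.01, nrow(labs)), sig_alpha = 0.05),
              class = "hierarchical_partition")
  })
  ts <- tercile_similarity(hierarchies, nets, n_perm = 200)
  expect_named(ts, c("coarse", "middle", "fine"))
  for (grp in ts) {
    expect_false(is.null(grp))
    expect_lt(grp$r, 0)
  }
})

test_that("single-level hierarchies collapse the terciles with a warning", {
  set.seed(26)
  cfg <- drift_config(26, drift = 0.1)
  st <- generate_study(cfg)
  nets <- lapply(st$sessions, build_network, n_jitter = 100)
  hierarchies <- lapply(seq_along(nets), function(i) {
    labs <- st$ground_truth$labels[[i]][1L, nets[[i]]$cell_ids,
                                        drop = FALSE]
    structure(list(labels = labs, n_levels = 1L, gamma_per_level = 1,
                   p_per_level = 0.01, sig_alpha = 0.05),
              class = "hierarchical_partition")
  })
  expect_warning(ts <- tercile_similarity(hierarchies, nets,
                                          n_perm = 200), "collapse")
  expect_named(ts, "all")
})
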