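test_that("config validation names the offending field", {
  expect_error(synth_config(n_cells = 0), "n_cells")
  expect_error(synth_config(dropout_prob = 1.2), "dropout_prob")
  expect_error(synth_config(day_offsets = c(0, 3)), "day_offsets")
  expect_error(synth_config(day_offsets = c(0, 5, 3, 7, 9)), "day_offsets")
  expect_error(synth_config(hierarchy_branching = c(20, 20),
                            signal_strength_per_level = c(0.5, 0.5),
                            n_cells = 100), "hierarchy_branching")
  expect_error(synth_config(signal_strength_per_level = c(0.5)),
               "signal_strength_per_level")
  expect_error(synth_config(signal_strength_per_level = c(0.5, 1.4)),
               "signal_strength_per_level")
})

test_that("generation is bit-reproducible and degenerate cases behave", {
  cfg <- label_config(5, n_sessions = 1L, day_offsets = 0L)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1, st2)

  ## single session covers all cells in the ground truth
  expect_equal(ncol(st1$ground_truth$labels[[1]]), cfg$n_cells)
  expect_length(st1$sessions, 1L)

  ## zero dropout: every cell in every session
  cfg0 <- label_config(6)
  st <- generate_study(cfg0)
  for (s in st$sessions) expect_length(s$cell_ids, cfg0$n_cells)
})

test_that("ground-truth hierarchy levels are nested refinements", {
  cfg <- label_config(7, hierarchy_branching = c(2L, 2L, 2L),
                      signal_strength_per_level = c(0.4, 0.5, 0.6),
                      n_cells = 64L)
  st <- generate_study(cfg)
  for (lab in st$ground_truth$labels) {
    for (l in 2:nrow(lab)) {
      ## each finer module maps into exactly one coarser module
      split_map <- tapply(lab[l - 1L, ], lab[l, ],
                          function(x) length(unique(x)))
      expect_true(all(split_map == 1L))
    }
  }
})

test_that("core cells never change finest module; periphery drifts with day gap", {
  n_seeds <- 20
  gaps <- c(3, 4, 3, 4)
  dis_by_gap <- matrix(NA_real_, n_seeds, 2)  # short (3d) vs long (7d+) gaps
  for (s in seq_len(n_seeds)) {
    cfg <- label_config(300 + s, drift_prob_per_day = 0.08)
    st <- generate_study(cfg)
    labs <- st$ground_truth$labels
    core <- st$ground_truth$core_mask
    fin <- vapply(labs, function(m) m[nrow(m), ], integer(cfg$n_cells))
    ## core invariance across all sessions
    expect_true(all(apply(fin[core, , drop = FALSE], 1L,
                          function(x) length(unique(x)) == 1L)))
    ## non-core disagreement grows with day separation
    per <- fin[!core, , drop = FALSE]
    days <- cfg$day_offsets
    dshort <- dlong <- c()
    for (u in 1:4) for (v in (u + 1):5) {
      dis <- mean(per[, u] != per[, v])
      gap <- days[v] - days[u]
      if (gap <= 4) dshort <- c(dshort, dis) else dlong <- c(dlong, dis)
    }
    dis_by_gap[s, ] <- c(mean(dshort), mean(dlong))
  }
  expect_gt(mean(dis_by_gap[, 2] - dis_by_gap[, 1]), 0)
})

test_that("planted modules are spatially compact relative to the field", {
  cfg <- label_config(9, spatial_module_sd = 20, fov_size_um = 500)
  st <- generate_study(cfg)
  pos <- st$ground_truth$positions
  lab <- st$ground_truth$labels[[1]]
  fin <- lab[nrow(lab), ]
  D <- as.matrix(dist(pos))
  diag(D) <- Inf
  within_nn_for <- function(labels) {
    mean(vapply(unique(labels), function(m) {
      idx <- which(labels == m)
      mean(apply(D[idx, idx, drop = FALSE], 1, min))
    }, numeric(1)))
  }
  ## same-module neighbours are far closer than under shuffled labels
  shuffled <- replicate(50, within_nn_for(sample(fin)))
  expect_lt(within_nn_for(fin), min(shuffled))
})

test_that("strong-signal traces correlate more within than between modules", {
  cfg <- synth_config(n_cells = 40L, n_sessions = 1L, day_offsets = 0L,
                      n_frames = 600L, noise_sd = 0.2,
                      signal_strength_per_level = c(0.8, 0.6),
                      dropout_prob = 0, seed = 21L)
  st <- generate_study(cfg)
  R <- cor(t(st$sessions[[1]]$traces))
  fin <- st$ground_truth$labels[[1]][2L, ]
  same <- outer(fin, fin, "==")
  ut <- upper.tri(R)
  expect_gt(mean(R[ut & same]), mean(R[ut & !same]))
})

test_that("dropout respects the shared-cell floor and matches binomial expectation", {
  ## expected shared count n * (1 - q)^2 within 3 binomial SDs
  cfg <- synth_config(n_cells = 150L, n_sessions = 2L,
                      day_offsets = c(0L, 3L), n_frames = 30L,
                      dropout_prob = 0.3, seed = 31L)
  st <- generate_study(cfg)
  sm <- summarize_study(st)
  shared <- sm$shared[1, 2]
  expected <- 150 * 0.49
  tol <- 3 * sqrt(150 * 0.49 * 0.51)
  expect_lt(abs(shared - expected), tol)
  expect_gte(min(sm$shared), 10)

  ## impossible dropout fails with a generation error
  expect_error(
    generate_study(synth_config(n_cells = 12L, n_sessions = 2L,
                                day_offsets = c(0L, 1L), n_frames = 30L,
                                dropout_prob = 0.95, seed = 1L)),
    "generation error")
})

test_that("study summary handles one session and zero dropout", {
  st1 <- generate_study(label_config(11, n_sessions = 1L, day_offsets = 0L,
                                     n_cells = 100L))
  sm1 <- summarize_study(st1)
  expect_equal(unname(sm1$shared[1, 1]), 100L)

  st2 <- generate_study(label_config(12, n_sessions = 2L,
                                     day_offsets = c(0L, 2L)))
  sm2 <- summarize_study(st2)
  expect_equal(unname(sm2$shared[1, 2]), 80L)
  expect_equal(unname(sm2$day_gap[1, 2]), 2)
})

test_that("studies round-trip through delimited text files", {
  cfg <- label_config(13, n_cells = 12L, n_sessions = 2L,
                      day_offsets = c(0L, 4L), n_frames = 20L,
                      dropout_prob = 0.1)
  st <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$cell_ids, st$sessions[[i]]$cell_ids)
    expect_equal(back[[i]]$day_offset, st$sessions[[i]]$day_offset)
    expect_equal(back[[i]]$traces, st$sessions[[i]]$traces,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})
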