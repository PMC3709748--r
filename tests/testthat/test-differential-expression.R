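test_that("SAM d matches the pooled-scatter hand computation", {
  m <- rbind(f1 = c(1, 2, 4, 5))
  colnames(m) <- paste0("s", 1:4)
  lab <- c(s1 = "normal", s2 = "normal", s3 = "tumor", s4 = "tumor")
  res <- sam_d_statistics(m, lab, s0 = 0)
  expect_equal(res$s, 0.70711, tolerance = 1e-4)
  expect_equal(res$d, 4.24264, tolerance = 1e-4)

  # zero numerator; location invariance; antisymmetry under group swap
  m2 <- rbind(f1 = c(3, 4, 3, 4))
  colnames(m2) <- colnames(m)
  expect_equal(sam_d_statistics(m2, lab, 0)$d, 0)
  shifted <- sam_d_statistics(m + 100, lab, 0)
  expect_equal(shifted$d, res$d)
  swapped <- c(s1 = "tumor", s2 = "tumor", s3 = "normal", s4 = "normal")
  expect_equal(sam_d_statistics(m, swapped, 0)$d, -res$d)

  # a group with < 2 observations after NA removal is flagged undefined
  m3 <- rbind(f1 = c(1, NA, 4, 5), f2 = c(1, 2, 4, 5))
  colnames(m3) <- colnames(m)
  res3 <- sam_d_statistics(m3, lab, 0)
  expect_true(is.na(res3$d[1]))
  expect_false(is.na(res3$d[2]))
})

test_that("s0 selection returns the median or the CV-minimizing percentile", {
  expect_identical(choose_s0(c(1, 2, 3), "median_s"), 2)
  expect_warning(z <- choose_s0(c(0, 0, 0), "median_s"), "zero")
  expect_identical(z, 0)

  # percentile search: chosen candidate minimizes the directly evaluated CV
  set.seed(11)
  n <- 1000
  s <- rexp(n, rate = 2) + 0.05
  r <- rnorm(n, sd = s + 0.2)
  s0 <- choose_s0(s, "percentile_search", mean_diff = r)
  cv_of <- function(s0c) {
    d <- r / (s + s0c)
    bins <- cut(rank(s, ties.method = "first"), breaks = 10, labels = FALSE)
    disp <- vapply(split(d, bins), mad, numeric(1))
    sd(disp) / mean(disp)
  }
  grid <- unique(quantile(s, seq(0, 1, 0.05), names = FALSE))
  expect_equal(cv_of(s0), min(vapply(grid, cv_of, numeric(1))))
  expect_lte(cv_of(s0), cv_of(0))
})

test_that("exhaustive permutation q-values: planted feature hits q = 0", {
  set.seed(3)
  n_null <- 50
  m <- matrix(rnorm(n_null * 8, mean = 7, sd = 0.5), n_null, 8)
  planted <- c(rnorm(4, 4, 0.1), rnorm(4, 10, 0.1))  # delta log2 = 6
  m <- rbind(planted, m)
  rownames(m) <- c("planted", sprintf("null%02d", seq_len(n_null)))
  colnames(m) <- paste0("s", 1:8)
  lab <- setNames(rep(c("normal", "tumor"), each = 4), colnames(m))
  cfg <- sam_config(n_permutations = 100)  # C(8,4) = 70 <= cap: exhaustive
  q <- permutation_q_values(m, lab, cfg)
  expect_identical(q$q[q$feature_id == "planted"], 0)
  expect_true(all(q$q >= 0 & q$q <= 1))
  # monotone non-increasing in |d|
  ord <- order(abs(q$d), decreasing = TRUE)
  expect_true(all(diff(q$q[ord]) >= 0))
  # exhaustive mode is reproducible and invariant to sample order
  q2 <- permutation_q_values(m, lab, cfg)
  expect_identical(q, q2)
  perm <- sample(ncol(m))
  q3 <- permutation_q_values(m[, perm], lab[perm], cfg)
  expect_equal(q3$q, q$q)
})

test_that("fold changes are linear-scale mean ratios with reciprocal symmetry", {
  es <- toy_expression_set()
  fc <- fold_changes(es)
  expect_equal(fc$fc[fc$feature_id == "fA"], 12 / 3)
  expect_equal(fc$fc[fc$feature_id == "fB"], 6 / 11)

  swapped <- es
  swapped$labels[] <- ifelse(es$labels == "tumor", "normal", "tumor")
  fc_swap <- fold_changes(swapped)
  expect_equal(fc$fc * fc_swap$fc, c(1, 1), ignore_attr = TRUE)

  # normal mean 2, tumor mean 1 -> 0.5
  v <- rbind(f = c(2, 2, 1, 1))
  colnames(v) <- paste0("s", 1:4)
  es2 <- expression_set(v, c(s1 = "normal", s2 = "normal",
                             s3 = "tumor", s4 = "tumor"), "linear")
  expect_equal(fold_changes(es2)$fc, 0.5)
})

test_that("selection combines the q and two-sided fold-change thresholds", {
  de <- data.frame(feature_id = c("a", "b", "c", "d"),
                   q = c(0, 0, 0, 0.5),
                   fc = c(0.38, 1.0, 6.58, 9))
  sel <- select_differential(de, q_threshold = 1e-6, fc_threshold = 2.5)
  expect_identical(sel$direction, c("down", "ns", "up", "ns"))
  # 1/0.38 = 2.63 >= 2.5: a down-regulated ratio passes the shared threshold
  expect_identical(sel$direction[sel$fc == 0.38], "down")
  # up and down sets partition the selected features
  expect_identical(sum(sel$direction == "up" & sel$direction == "down"), 0L)
})

test_that("planted features are recovered with no false positives", {
  hits <- 0; total <- 0; fp <- 0
  for (seed in 1:10) {
    sim <- simulate_expression(200, 10, 10, de_fraction = 0.05,
                               log2_effect = 3, noise_sd = 0.5, seed = seed)
    de <- sam_analysis(sim$es, sam_config(seed = seed))
    sel <- de$feature_id[de$direction != "ns"]
    planted <- c(sim$truth$planted_up, sim$truth$planted_down)
    hits <- hits + length(intersect(sel, planted))
    total <- total + length(planted)
    fp <- fp + length(setdiff(sel, planted))
    # directions match the planted signs
    expect_true(all(de$direction[de$feature_id %in% sim$truth$planted_up]
                    %in% c("up", "ns")))
    expect_true(all(de$direction[de$feature_id %in% sim$truth$planted_down]
                    %in% c("down", "ns")))
  }
  expect_gte(hits / total, 0.95)
  expect_equal(fp, 0)
})
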