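toy_table <- function() {
  set.seed(3)
  df <- data.frame(model = paste0("m", 1:12),
                   target = rep(c("T1", "T2", "T3"), each = 4),
                   qscore = runif(12, 0.4, 0.8),
                   clashscore = runif(12, 2, 40))
  df$ccbox <- 0.5 + 0.4 * df$qscore + rnorm(12, sd = 0.01)
  score_table(df)
}

test_that("score tables load from CSV with missing-cell accounting", {
  df <- data.frame(model = c("a", "b", "c"), target = "T1",
                   qscore = c(0.5, NA, 0.7), clashscore = c("3", "x", "5"))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  tbl <- load_scores(f)
  expect_equal(nrow(tbl$data), 3)
  expect_setequal(tbl$metrics, c("qscore", "clashscore"))
  expect_equal(tbl$n_missing, 2L)   # the NA and the unparsable "x"
  ## duplicated (model, target) rows are an error naming the model
  df2 <- rbind(df, df[1, ])
  f2 <- tempfile(fileext = ".csv")
  write.csv(df2, f2, row.names = FALSE)
  expect_error(load_scores(f2), "a T1")
})

test_that("correlation matrices match a hand-computed Pearson oracle", {
  df <- data.frame(model = paste0("m", 1:4), target = "T1",
                   a = c(1, 2, 3, 5), b = c(2.2, 3.9, 6.1, 9.8),
                   c = c(9, 7, 4, 1))
  tbl <- score_table(df)
  cm <- correlation_matrix(tbl, "pooled")
  expect_equal(cm["a", "b"], pearson_oracle(df$a, df$b), tolerance = 1e-12)
  expect_equal(cm["a", "c"], pearson_oracle(df$a, df$c), tolerance = 1e-12)
  expect_true(isSymmetric(unclass(cm)[seq_len(3), seq_len(3)]))
  expect_equal(diag(cm), rep(1, 3), ignore_attr = TRUE)
  ## linear relations give +/-1 in every scope
  df$b <- 2 * df$a + 1; df$c <- -df$a
  cm2 <- correlation_matrix(score_table(df), "pooled")
  expect_equal(cm2["a", "b"], 1, tolerance = 1e-12)
  expect_equal(cm2["a", "c"], -1, tolerance = 1e-12)
})

test_that("per-target-averaged correlations are the mean of per-target r", {
  tbl <- toy_table()
  per <- correlation_matrix(tbl, "per_target")
  avg <- correlation_matrix(tbl, "per_target_averaged")
  hand <- (per[["T1"]]["qscore", "ccbox"] + per[["T2"]]["qscore", "ccbox"] +
             per[["T3"]]["qscore", "ccbox"]) / 3
  expect_equal(avg["qscore", "ccbox"], hand, tolerance = 1e-12)
})

test_that("clustering on 1-|r| recovers block structure and merges anti-correlated pairs first", {
  ## six metrics in two perfectly correlated triplets
  set.seed(7)
  base1 <- rnorm(30); base2 <- rnorm(30)
  df <- data.frame(model = paste0("m", 1:30), target = "T1",
                   a1 = base1, a2 = 2 * base1 + 3, a3 = -base1,
                   b1 = base2, b2 = 0.5 * base2, b3 = -2 * base2)
  cl <- cluster_metrics(correlation_matrix(score_table(df), "pooled"), 2)
  lab <- cl$labels
  expect_equal(length(unique(lab[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(lab[c("b1", "b2", "b3")])), 1)
  expect_true(lab["a1"] != lab["b1"])
  ## anti-correlated pair (distance 0 under |r|) merges at height ~0
  expect_lt(cl$merge_heights[1], 1e-9)
  ## complete linkage: merge heights non-decreasing
  expect_true(all(diff(cl$merge_heights) >= -1e-12))
  expect_error(cluster_metrics(correlation_matrix(score_table(df), "pooled"), 9),
               "n_clusters")
})

test_that("composite Z matches a hand-computed weighted sum", {
  ## 5-model toy with the coordinates-only weight set
  df <- data.frame(model = paste0("m", 1:5), target = "T1",
                   cablam_outliers = c(0.0, 0.02, 0.05, 0.10, 0.01),
                   calpha_outliers = c(0.01, 0.00, 0.04, 0.08, 0.02),
                   clashscore = c(3, 8, 20, 45, 5))
  tbl <- score_table(df)
  w <- default_weight_sets()$coords_only
  zr <- composite_z(tbl, w)
  hand <- rep(0, 5)
  for (m in names(w)) {
    z <- (df[[m]] - mean(df[[m]])) / sd(df[[m]])
    hand <- hand - w[[m]] * z    # all three are lower-is-better
  }
  expect_equal(zr$composite$composite[match(df$model, zr$composite$model)],
               hand, tolerance = 1e-12)
})

test_that("composite Z properties: mean model, domination, affine invariance", {
  df <- data.frame(model = paste0("m", 1:5), target = "T1",
                   qscore = c(0.5, 0.6, 0.7, 0.8, 0.65),
                   lddt = c(60, 70, 80, 90, 75))
  tbl <- score_table(df)
  w <- c(qscore = 0.6, lddt = 0.4)
  zr <- composite_z(tbl, w)
  ## affine rescaling of a metric column changes nothing
  df2 <- df; df2$qscore <- 100 * df2$qscore - 7
  zr2 <- composite_z(score_table(df2), w)
  expect_equal(zr2$composite$composite, zr$composite$composite,
               tolerance = 1e-12)
  ## a model dominating every metric ranks strictly first
  top <- zr$composite$model[which.max(zr$composite$composite)]
  expect_equal(top, "m4")
  ## zero-variance metric dropped with a log entry
  df3 <- df; df3$qscore <- 0.5
  zr3 <- composite_z(score_table(df3), w)
  expect_equal(nrow(zr3$dropped), 1)
  ## refuse undeclared orientations
  df4 <- df; names(df4)[3] <- "mystery"
  expect_error(composite_z(score_table(df4), c(mystery = 1)), "orientation")
})

test_that("Z-scores standardize to mean 0, sd 1 within target and metric", {
  tbl <- toy_table()
  zr <- composite_z(tbl, c(qscore = 0.5, clashscore = 0.5))
  for (tg in unique(zr$z$target)) for (m in unique(zr$z$metric)) {
    zz <- zr$z$z[zr$z$target == tg & zr$z$metric == m]
    expect_equal(mean(zz), 0, tolerance = 1e-12)
    expect_equal(sd(zz), 1, tolerance = 1e-12)
  }
})

test_that("percentile summaries follow the linear-interpolation convention", {
  df <- data.frame(model = paste0("m", 1:9), target = "T1",
                   qscore = as.numeric(1:9))
  s <- distribution_summary(score_table(df), "qscore")
  expect_equal(s$p50, 5)
  expect_equal(s$p25, 3)
  expect_equal(s$p75, 7)
  expect_equal(s$p10, as.numeric(quantile(1:9, 0.1, type = 7)))
  expect_false(s$degenerate_box)
  ## constant scores: degenerate box flag
  dfc <- data.frame(model = paste0("m", 1:4), target = "T1", qscore = 0.5)
  sc <- distribution_summary(score_table(dfc), "qscore")
  expect_true(sc$degenerate_box)
  expect_true(all(unlist(sc[c("p10", "p25", "p50", "p75", "p90")]) == 0.5))
  ## single score
  df1 <- data.frame(model = "m1", target = "T1", qscore = 0.42)
  s1 <- distribution_summary(score_table(df1), "qscore")
  expect_true(all(unlist(s1[c("p10", "p25", "p50", "p75", "p90")]) == 0.42))
})
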