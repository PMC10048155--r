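make_ab <- function(m, conds) {
  abundance_table(m, setNames(conds, colnames(m)))
}

test_that("per-protein ANOVA matches lm on general data and handles edges", {
  set.seed(21)
  m <- matrix(rlnorm(20 * 9, 5, 0.3), 20, 9,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:9)))
  conds <- rep(c("SM", "AD", "OB"), each = 3)
  res <- anova_per_protein(make_ab(m, conds))
  for (i in c(1, 7, 20)) {
    ref <- anova(lm(m[i, ] ~ factor(conds)))
    expect_equal(res$f[i], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p[i], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # all values identical -> F = 0, p = 1
  flat <- make_ab(matrix(5, 1, 9, dimnames = list("p", paste0("s", 1:9))),
                  conds)
  rf <- anova_per_protein(flat)
  expect_equal(rf$f, 0); expect_equal(rf$p, 1)
  # two conditions: F equals the square of the pooled-variance t statistic
  m2 <- m[, 1:6]
  res2 <- anova_per_protein(make_ab(m2, rep(c("A", "B"), each = 3)))
  tt <- t.test(m2[3, 1:3], m2[3, 4:6], var.equal = TRUE)
  expect_equal(res2$f[3], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p[3], tt$p.value, tolerance = 1e-10)
  # replicate guard
  expect_error(anova_per_protein(make_ab(m[, 1:4], c("A", "A", "A", "B"))),
               "fewer than 2 replicates")
})

test_that("3x3 toy ANOVA matches a hand-computed sum-of-squares split", {
  y <- c(10, 12, 14, 20, 22, 24, 10, 11, 12)
  g <- rep(c("A", "B", "C"), each = 3)
  m <- matrix(y, 1, 9, dimnames = list("p", paste0("s", 1:9)))
  res <- anova_per_protein(make_ab(m, g))
  gm <- tapply(y, g, mean); grand <- mean(y)
  ssb <- sum(3 * (gm - grand)^2)
  sse <- sum((y - rep(gm, each = 3))^2)
  f <- (ssb / 2) / (sse / 6)
  expect_equal(res$f, f, tolerance = 1e-12)
  expect_equal(res$p, pf(f, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("difference-of-means ranking is ascending with id tie-break", {
  set.seed(5)
  m <- matrix(rlnorm(50 * 9, 6, 0.5), 50, 9,
              dimnames = list(sprintf("p%02d", 1:50), paste0("s", 1:9)))
  tab <- make_ab(m, rep(c("SM", "AD", "OB"), each = 3))
  rows <- rank_by_mean_difference(tab, "SM", "AD")
  # independent sort oracle
  d <- abs(rowMeans(m[, 1:3]) - rowMeans(m[, 4:6]))
  expect_identical(rows$protein_id, names(sort(d)))
  expect_equal(rows$diff_primary, unname(sort(d)), tolerance = 1e-12)
  expect_true(all(diff(rows$rank) == 1))
  expect_error(rank_by_mean_difference(tab, "SM", "XX"),
               "unknown condition")
  # identical means everywhere -> all diffs 0, rank by id
  flat <- make_ab(matrix(3, 4, 6, dimnames = list(c("d", "b", "a", "c"),
                                                  paste0("s", 1:6))),
                  rep(c("A", "B"), each = 3))
  fr <- rank_by_mean_difference(flat, "A", "B")
  expect_identical(fr$protein_id, c("a", "b", "c", "d"))
  expect_equal(fr$diff_primary, rep(0, 4))
})

test_that("top-n candidate filter retains exactly the stable proteins", {
  tab <- eadmsc_screen_table()
  rows <- rank_by_mean_difference(tab, "SM", "AD")
  kept <- select_candidates(rows, top_n = 25, p_min = 0.05)
  expect_equal(nrow(kept), 23)
  expect_false(any(grepl("^SYNTH_PAD", kept$protein_id)))
  # the padding rows do sit inside the top 25
  top25 <- rows$protein_id[rows$rank <= 25]
  expect_true(all(c("SYNTH_PAD1", "SYNTH_PAD2") %in% top25))
  # selection preserves rank order and is a subset of the top n
  expect_true(all(diff(kept$rank) > 0))
  expect_true(all(kept$rank <= 25))
  # boundaries (padding-free table: every p-value is strictly positive)
  rows_np <- rank_by_mean_difference(eadmsc_screen_table(padding = FALSE),
                                     "SM", "AD")
  expect_equal(nrow(select_candidates(rows_np, top_n = 10, p_min = 0)), 10)
  rows0 <- rows; rows0$anova_p <- 0
  expect_equal(nrow(select_candidates(rows0, 25, 0.05)), 0)
  expect_warning(select_candidates(rows, top_n = 1000, p_min = 0.05),
                 "clamped")
})

test_that("protein fold changes and t-tests match direct recomputation", {
  m <- rbind(p1 = c(10, 10, 10, 20, 20, 20),
             p2 = c(8, 10, 12, 8, 10, 12))
  colnames(m) <- paste0("s", 1:6)
  tab <- make_ab(m, rep(c("C", "T"), each = 3))
  fc <- protein_fold_change(tab, "C")
  expect_equal(fc$fold[fc$protein_id == "p1" & fc$condition == "T"], 2)
  expect_equal(fc$fold[fc$protein_id == "p2" & fc$condition == "T"], 1)
  expect_equal(fc$p[fc$protein_id == "p2" & fc$condition == "T"], 1)
  # control condition: fold exactly 1
  expect_equal(fc$fold[fc$condition == "C"], c(1, 1), tolerance = 1e-12)
  # unequal-variance toy vs direct Welch recomputation
  m3 <- rbind(q = c(5, 6, 7, 9, 14, 19))
  colnames(m3) <- paste0("s", 1:6)
  t3 <- make_ab(m3, rep(c("C", "T"), each = 3))
  fc3 <- protein_fold_change(t3, "C")
  ctrl_mean <- mean(c(5, 6, 7))
  ref <- t.test(c(9, 14, 19) / ctrl_mean, c(5, 6, 7) / ctrl_mean)
  expect_equal(fc3$fold[fc3$condition == "T"], mean(c(9, 14, 19)) / ctrl_mean,
               tolerance = 1e-12)
  expect_equal(fc3$p[fc3$condition == "T"], ref$p.value, tolerance = 1e-12)
  # zero control mean
  mz <- rbind(z = c(0, 0, 0, 1, 1, 1)); colnames(mz) <- paste0("s", 1:6)
  expect_error(protein_fold_change(make_ab(mz, rep(c("C", "T"), each = 3)),
                                   "C"), "mean abundance is 0")
})
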