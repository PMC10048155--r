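test_that("standard-curve geometry and the efficiency formula are exact", {
  # perfect 2-fold dilution series, one cycle per dilution step
  amounts <- 360 / 2^(0:6)
  cq <- 18 + (0:6)
  fit <- fit_standard_curve(amounts, cq)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(fit$E, 2, tolerance = 1e-10)
  expect_equal(fit$percent_e, 100, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$valid)
  # slope -3.8 corresponds to E = 10^(1/3.8)
  cq38 <- 30 - 3.8 * log10(amounts)
  fit38 <- fit_standard_curve(amounts, cq38)
  expect_equal(fit38$E, 10^(1 / 3.8), tolerance = 1e-10)
  expect_equal(fit38$percent_e, (10^(1 / 3.8) - 1) * 100, tolerance = 1e-8)
  # round-trip with the slope conversion
  expect_equal(slope_from_efficiency(fit38$E), -3.8, tolerance = 1e-10)
})

test_that("standard-curve fitting warns, drops and flags as specified", {
  amounts <- 360 / 2^(0:6)
  set.seed(8)
  cq <- 18 + (0:6) + rnorm(7, 0, 0.15)
  fit <- fit_standard_curve(amounts, cq)
  expect_lt(fit$r_squared, 1)
  ci <- confint(lm(cq ~ log10(amounts)))[2, ]
  expect_true(ci[1] <= -1 / log10(2) && -1 / log10(2) <= ci[2])
  # explicit end-point dropping
  fit5 <- fit_standard_curve(amounts, cq, drop_low = 1, drop_high = 1)
  expect_equal(length(fit5$amounts), 5)
  expect_warning(fit_standard_curve(amounts[1:4], cq[1:4]),
                 "fewer than 5")
  expect_error(suppressWarnings(fit_standard_curve(amounts[1:4], cq[1:4],
                                                   drop_low = 2)),
               ">= 3 points")
  # non-negative slope flagged invalid, E withheld
  expect_warning(bad <- fit_standard_curve(amounts, rev(cq)),
                 "invalid")
  expect_false(bad$valid)
  expect_true(is.na(bad$E))
})

test_that("Pfaffl ratios evaluate exactly", {
  expect_equal(pfaffl_ratio(2, 1, 2, 0), 2, tolerance = 1e-12)
  expect_equal(pfaffl_ratio(1.9, 1.3, 1.9, 1.3), 1, tolerance = 1e-12)
  expect_equal(pfaffl_ratio(1.88, 2, 2, 0.5), 1.88^2 / 2^0.5,
               tolerance = 1e-12)
  expect_equal(pfaffl_ratio(2, 1.7, 2, 0.4), 2^(1.7 - 0.4),
               tolerance = 1e-12)
  expect_error(pfaffl_ratio(1, 1, 2, 1), "must be > 1")
})

test_that("single-RG normalization reduces to the Pfaffl ratio", {
  x <- toy_cq()
  # geometric-mean folds reduce exactly on general data
  q <- multi_rg_nrq(x, "TGT", "RGA", "CTRL", fold_mean = "geometric")
  ctrl <- names(x$condition)[x$condition == "CTRL"]
  trt <- names(x$condition)[x$condition == "TRT"]
  dcq_t <- mean(x$cq["TGT", ctrl]) - mean(x$cq["TGT", trt])
  dcq_r <- mean(x$cq["RGA", ctrl]) - mean(x$cq["RGA", trt])
  expect_equal(q$table$fold[q$table$condition == "TRT"],
               pfaffl_ratio(x$efficiency["TGT"], dcq_t,
                            x$efficiency["RGA"], dcq_r),
               tolerance = 1e-12, ignore_attr = TRUE)
  # arithmetic folds reduce when arms are within-arm constant
  m <- rbind(T1 = c(24, 24, 24, 22, 22, 22), R1 = c(20, 20, 20, 19.5,
                                                    19.5, 19.5))
  colnames(m) <- paste0("s", 1:6)
  xf <- suppressWarnings(
    cq_table(m, setNames(rep(c("C", "T"), each = 3), colnames(m)),
             c(T1 = 1.95, R1 = 2.02)))
  qf <- suppressWarnings(multi_rg_nrq(xf, "T1", "R1", "C"))  # p = 0 limit
  expect_equal(qf$table$fold[qf$table$condition == "T"],
               pfaffl_ratio(1.95, 2, 2.02, 0.5), tolerance = 1e-12)
})

test_that("multi-RG normalization matches a spreadsheet-style oracle", {
  x <- toy_cq()
  q <- multi_rg_nrq(x, "TGT", c("RGA", "RGB", "RGC"), "CTRL")
  # independent recomputation, cell by cell
  ctrl <- names(x$condition)[x$condition == "CTRL"]
  nrq <- sapply(colnames(x$cq), function(s) {
    rqs <- sapply(c("TGT", "RGA", "RGB", "RGC"), function(g)
      unname(x$efficiency[g])^(mean(x$cq[g, ctrl]) - x$cq[g, s]))
    rqs[["TGT"]] / prod(rqs[c("RGA", "RGB", "RGC")])^(1 / 3)
  })
  expect_equal(q$nrq, nrq, tolerance = 1e-12)
  expect_equal(q$table$fold[q$table$condition == "TRT"],
               mean(nrq[4:6]) / mean(nrq[1:3]), tolerance = 1e-12)
  ref <- t.test(nrq[4:6], nrq[1:3])
  expect_equal(q$table$p[q$table$condition == "TRT"], ref$p.value,
               tolerance = 1e-12)
  # control fold is exactly 1 with p = 1
  expect_equal(q$table$fold[q$table$condition == "CTRL"], 1,
               tolerance = 1e-12)
  expect_equal(q$table$p[q$table$condition == "CTRL"], 1)
})

test_that("reference-set algebra: duplication, self-normalization, loading", {
  x <- toy_cq()
  # duplicating a reference gene does not change the result
  m <- rbind(x$cq, RGA2 = x$cq["RGA", ])
  x2 <- suppressWarnings(
    cq_table(m, x$condition,
             c(x$efficiency, RGA2 = unname(x$efficiency["RGA"]))))
  qa <- multi_rg_nrq(x2, "TGT", "RGA", "CTRL")
  qb <- multi_rg_nrq(x2, "TGT", c("RGA", "RGA2"), "CTRL")
  expect_equal(qa$nrq, qb$nrq, tolerance = 1e-12)
  # normalizing each RG by the whole set: per-sample NRQ product is 1
  rgs <- c("RGA", "RGB", "RGC")
  prod_nrq <- rep(1, ncol(x$cq))
  for (g in rgs) {
    qg_nrq <- to_relative_quantities(x, "control_mean", "CTRL")$rq[g, ] /
      exp(colMeans(log(to_relative_quantities(x, "control_mean",
                                              "CTRL")$rq[rgs, ])))
    prod_nrq <- prod_nrq * qg_nrq
  }
  expect_equal(unname(prod_nrq), rep(1, 6), tolerance = 1e-10)
  # equal efficiencies: per-sample loading shifts cancel
  me <- x$cq
  xeq <- cq_table(me, x$condition,
                  setNames(rep(2, 4), rownames(me)))
  shift <- c(0.7, -0.3, 0.2, 0, 0.5, -0.4)
  xsh <- cq_table(sweep(me, 2, -shift), x$condition,
                  setNames(rep(2, 4), rownames(me)))
  q1 <- multi_rg_nrq(xeq, "TGT", c("RGA", "RGB"), "CTRL")
  q2 <- multi_rg_nrq(xsh, "TGT", c("RGA", "RGB"), "CTRL")
  expect_equal(q1$nrq, q2$nrq, tolerance = 1e-10)
})

test_that("fold-change test handles degenerate variance cases", {
  expect_equal(unname(fold_change_test(c(1, 1, 1), c(1, 1, 1))),
               c(1, 1))
  expect_warning(ft <- fold_change_test(c(1, 1, 1), c(2, 2, 2)),
                 "p = 0 limit")
  expect_equal(unname(ft), c(2, 0))
  # guards
  expect_error(multi_rg_nrq(toy_cq(), "TGT", c("TGT", "RGA"), "CTRL"),
               "must not be part")
  expect_error(multi_rg_nrq(toy_cq(), "TGT", "RGA", "NOPE"),
               "not present")
  expect_error(multi_rg_nrq(toy_cq(), "TGT", character(0), "CTRL"),
               "non-empty")
})
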