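test_that("relative quantities follow the efficiency power law", {
  m <- rbind(g1 = c(20, 21, 22), g2 = c(24, 24, 24), g3 = c(20, 21, 20))
  colnames(m) <- paste0("s", 1:3)
  x <- cq_table(m, setNames(c("A", "A", "B"), colnames(m)),
                c(g1 = 2, g2 = 2, g3 = 1.883))
  rq <- to_relative_quantities(x)
  expect_equal(unname(rq$rq["g1", ]), c(1, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(unname(rq$rq["g2", ]), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(rq$rq["g3", 2]), 1 / 1.883, tolerance = 1e-12)
  # min-Cq calibrator: per-gene maximum is exactly 1
  expect_equal(unname(apply(rq$rq, 1, max)), rep(1, 3), tolerance = 1e-12)
  x$efficiency["g1"] <- 1
  expect_error(to_relative_quantities(x), "must be > 1")
})

test_that("BestKeeper statistics match a step-by-step recomputation", {
  x <- random_cq(7, 9, seed = 33)
  bk <- bestkeeper(x)
  m <- x$cq
  idx <- exp(colMeans(log(m)))           # geometric-mean index
  expect_equal(bk$index, idx, tolerance = 1e-12)
  for (g in rownames(m)) {
    expect_equal(bk$stats$sd[bk$stats$gene_id == g], sd(m[g, ]),
                 tolerance = 1e-12)
    expect_equal(bk$stats$cv[bk$stats$gene_id == g],
                 100 * sd(m[g, ]) / mean(m[g, ]), tolerance = 1e-12)
    ct <- cor.test(m[g, ], idx)
    expect_equal(bk$stats$r[bk$stats$gene_id == g], unname(ct$estimate),
                 tolerance = 1e-12)
    expect_equal(bk$stats$p[bk$stats$gene_id == g], ct$p.value,
                 tolerance = 1e-12)
  }
  # ranking is descending in r
  ord <- order(bk$stats$rank)
  expect_true(all(diff(bk$stats$r[ord]) <= 0))
})

test_that("BestKeeper handles constant and collinear genes", {
  m <- rbind(flat = rep(20, 5), a = c(20, 21, 20.5, 22, 19),
             b = c(21, 22, 21.5, 23, 20))
  colnames(m) <- paste0("s", 1:5)
  x <- suppressWarnings(cq_table(m, setNames(rep("A", 5), colnames(m))))
  bk <- bestkeeper(x)
  expect_equal(bk$stats$sd[bk$stats$gene_id == "flat"], 0)
  expect_true(bk$stats$suitable[bk$stats$gene_id == "flat"])
  expect_true(is.na(bk$stats$r[bk$stats$gene_id == "flat"]))
  # b = a + 1 on every sample: pairwise r exactly 1
  expect_equal(bk$pairwise_r["a", "b"], 1, tolerance = 1e-12)
})

test_that("geNorm M and V equal brute-force recomputation", {
  x <- random_cq(7, 9, seed = 14)
  rq <- to_relative_quantities(x)
  gn <- genorm(rq)
  expect_equal(setNames(gn$stats$m, gn$stats$gene_id),
               oracle_genorm_m(rq$rq), tolerance = 1e-12)
  # V series against direct normalization-factor recomputation
  ord <- gn$stats$gene_id[order(gn$stats$rank)]
  for (n in 2:6) {
    nf_n <- exp(colMeans(log(rq$rq[ord[1:n], , drop = FALSE])))
    nf_n1 <- exp(colMeans(log(rq$rq[ord[1:(n + 1)], , drop = FALSE])))
    expect_equal(unname(gn$v[n - 1]), sd(log2(nf_n / nf_n1)),
                 tolerance = 1e-12)
  }
  expect_true(all(gn$v >= 0) && all(gn$stats$m >= 0))
})

test_that("constant-ratio genes reach M = 0 and V = 0", {
  base <- c(1, 0.5, 0.25, 0.8, 0.6)
  rq <- rbind(a = base, b = 0.5 * base, c = 0.25 * base)
  colnames(rq) <- paste0("s", 1:5)
  obj <- structure(list(rq = rq, efficiency = c(a = 2, b = 2, c = 2),
                        condition = setNames(rep("A", 5), colnames(rq)),
                        calibrator = "min"), class = "rq_matrix")
  gn <- genorm(obj)
  expect_equal(gn$stats$m, rep(0, 3), tolerance = 1e-12)
  expect_equal(gn$stats$m_step, rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(gn$v), 0, tolerance = 1e-12)
  expect_equal(gn$recommended_n, 2L)
})

test_that("delta-Ct equals brute-force all-pairs enumeration", {
  x <- random_cq(5, 8, seed = 9)
  dc <- delta_ct_method(x)
  expect_equal(setNames(dc$stats$mean_sd, dc$stats$gene_id),
               oracle_delta_ct(x$cq), tolerance = 1e-12)
  # co-shifted pair has pair SD zero; a jittered gene scores strictly worse
  m <- rbind(a = c(20, 21, 22, 20), b = c(22, 23, 24, 22),
             j = c(20, 22, 21, 23))
  colnames(m) <- paste0("s", 1:4)
  x2 <- suppressWarnings(cq_table(m, setNames(rep("A", 4), colnames(m))))
  dc2 <- delta_ct_method(x2)
  expect_equal(dc2$pair_sd["a", "b"], 0, tolerance = 1e-12)
  st <- setNames(dc2$stats$mean_sd, dc2$stats$gene_id)
  expect_gt(st["j"], st["a"])
  expect_gt(st["j"], st["b"])
})

test_that("stability metrics are invariant to a constant Cq shift", {
  x <- random_cq(6, 9, seed = 55)
  xs <- x
  xs$cq["g3", ] <- xs$cq["g3", ] + 3   # shift one gene everywhere
  for (get in list(
    function(t) setNames(genorm(to_relative_quantities(t))$stats$m,
                         genorm(to_relative_quantities(t))$stats$gene_id),
    function(t) setNames(delta_ct_method(t)$stats$mean_sd,
                         delta_ct_method(t)$stats$gene_id),
    function(t) setNames(bestkeeper(t)$stats$sd,
                         bestkeeper(t)$stats$gene_id))) {
    expect_equal(get(xs)["g3"], get(x)["g3"], tolerance = 1e-9)
  }
  # BestKeeper r: shifting Cq moves the index slightly, so compare the
  # gene-vs-others correlation structure instead via pairwise r
  expect_equal(bestkeeper(xs)$pairwise_r["g3", "g1"],
               bestkeeper(x)$pairwise_r["g3", "g1"], tolerance = 1e-12)
})

test_that("NormFinder ties, floors and ordering behave as the model says", {
  # all genes share one pattern: zero residual after centering, all tie
  base <- c(20, 21, 19, 22, 20, 21)
  m <- rbind(a = base, b = base + 2, c = base - 1)
  colnames(m) <- paste0("s", 1:6)
  x <- suppressWarnings(cq_table(m, setNames(rep(c("A", "B"), each = 3),
                                             colnames(m))))
  nf <- normfinder(x)
  expect_equal(nf$stats$rho, rep(nf$stats$rho[1], 3), tolerance = 1e-12)
  # single group: a gene with zero *centered* variance (it equals the
  # across-gene average profile) sits at the floor, below any noisy gene
  base2 <- c(20, 21, 19, 22, 20, 21)
  jit <- c(0.3, -0.2, 0.5, -0.4, 0.1, -0.3)
  m2 <- rbind(up = base2 + jit, down = base2 - jit, flat = base2)
  colnames(m2) <- paste0("s", 1:6)
  x2 <- suppressWarnings(cq_table(m2, setNames(rep("A", 6), colnames(m2))))
  nf2 <- normfinder(x2, grouped = FALSE)
  st <- setNames(nf2$stats$rho, nf2$stats$gene_id)
  expect_lt(st["flat"], st["up"])
  expect_lt(st["flat"], st["down"])
  # grouped mode rejects singleton groups
  x3 <- suppressWarnings(cq_table(m2[, 1:3],
                                  setNames(c("A", "A", "B"),
                                           colnames(m2)[1:3])))
  expect_error(normfinder(x3), "single sample")
})

test_that("NormFinder stability tracks the injected variance ordering", {
  # at 3 groups x 3 replicates the pooled variance estimates carry 6
  # degrees of freedom, so adjacent-gene orderings are noisy by nature;
  # the recoverable properties are strong rank agreement overall and
  # near-certain separation of clearly different genes
  sds <- c(g1 = 0.05, g2 = 0.2, g3 = 0.45, g4 = 0.9)
  genes <- data.frame(gene_id = names(sds), base_cq = c(20, 22, 24, 18),
                      bio_sd = 0, tech_sd = unname(sds), efficiency = 2)
  truth <- sim_truth(genes, conditions = c("A", "B", "C"), load_sd = 0.3)
  sep <- 0; spear <- numeric(200)
  for (i in 1:200) {
    tab <- simulate_cq(truth, bio_reps = 3, tech_reps = 1, seed = 4000 + i)
    nf <- normfinder(tab)
    r <- setNames(nf$stats$rank, nf$stats$gene_id)
    sep <- sep + (r[["g1"]] < r[["g4"]])
    spear[i] <- cor(r[names(sds)], seq_along(sds), method = "spearman")
  }
  expect_gte(sep / 200, 0.95)
  expect_gte(mean(spear), 0.75)
})
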