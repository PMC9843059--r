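toy_ranking <- function(rho, genes = sprintf("G%03d", seq_along(rho))) {
  ord <- order(-rho, genes)
  out <- data.frame(gene = genes[ord], rho = rho[ord],
                    p = rep(NA_real_, length(rho)), stringsAsFactors = FALSE)
  attr(out, "n") <- 50
  class(out) <- c("gene_ranking", "data.frame")
  out
}

test_that("gene filtering removes genes zero in more than 20% of patients", {
  # zero fractions 0.0 .. 0.9 in steps of 0.1 over 10 patients
  m <- t(sapply(0:9, function(z) c(rep(0, z), rep(1, 10 - z))))
  rownames(m) <- sprintf("G%d", 0:9)
  colnames(m) <- sprintf("P%d", 1:10)
  kept <- filter_genes(m)
  expect_identical(rownames(kept), c("G0", "G1", "G2"))
  # boundary sharpness at n = 100: 20 zeros retained, 21 removed
  m2 <- rbind(at20 = c(rep(0, 20), rep(1, 80)),
              at21 = c(rep(0, 21), rep(1, 79)),
              allz = rep(0, 100))
  colnames(m2) <- sprintf("P%d", 1:100)
  expect_identical(rownames(filter_genes(m2)), "at20")
  expect_error(filter_genes(m2[0, , drop = FALSE]), "empty")
  expect_error(filter_genes(m2, 1.2), "\\[0, 1\\]")
})

test_that("Spearman rankings match hand-computed rank correlations", {
  f <- stats::setNames(c(1, 2, 3, 4, 5), sprintf("P%d", 1:5))
  ex <- rbind(printed = c(2, 1, 4, 3, 5),    # sum(d^2) = 4  -> rho = 0.8
              shifted = c(1, 2, 4, 5, 3),    # sum(d^2) = 6  -> rho = 0.7
              mono = exp(c(1, 2, 3, 4, 5)),  # monotone transform -> rho = 1
              anti = c(5, 4, 3, 2, 1),       # reversal -> rho = -1
              flat = rep(2, 5))              # zero variance -> excluded
  colnames(ex) <- names(f)
  rk <- rank_genes(ex, f)
  rho <- stats::setNames(rk$rho, rk$gene)
  expect_equal(unname(rho["printed"]), 0.8)
  expect_equal(unname(rho["shifted"]), 0.7)
  expect_equal(unname(rho["mono"]), 1)
  expect_equal(unname(rho["anti"]), -1)
  expect_identical(attr(rk, "excluded"), "flat")
  expect_false("flat" %in% rk$gene)
  # ordering is by rho descending
  expect_true(all(diff(rk$rho) <= 0))
  # agreement with stats::cor on randomized data (ties included)
  for (rep in 1:8) {
    withr::with_seed(700 + rep, {
      n <- 25
      fv <- stats::setNames(sample(1:10, n, TRUE) + stats::runif(n),
                            sprintf("P%02d", 1:n))
      mm <- matrix(sample(1:6, 5 * n, TRUE), 5, n,
                   dimnames = list(sprintf("G%d", 1:5), names(fv)))
    })
    rk2 <- rank_genes(mm, fv)
    for (g in rk2$gene)
      expect_equal(rk2$rho[rk2$gene == g],
                   unname(stats::cor(mm[g, ], fv, method = "spearman")),
                   info = paste(rep, g))
  }
  expect_error(rank_genes(ex[, 1:2], f[1:2]), ">= 3")
})

test_that("BH adjustment is exact, monotone and idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (rep in 1:10) {
    p <- withr::with_seed(800 + rep, stats::runif(20))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # order preservation
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
  # re-adjusting a fully tied step-up output leaves it unchanged
  expect_equal(bh_adjust(bh_adjust(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
})

test_that("enrichment scores equal the brute-force running sum exactly", {
  # 20-gene ranking, 4-gene set, exponent 1
  rho <- withr::with_seed(901, sort(stats::rnorm(20), decreasing = TRUE))
  rk <- toy_ranking(rho)
  for (rep in 1:20) {
    idx <- withr::with_seed(910 + rep, sort(sample(20, 4)))
    sets <- list(s = rk$gene[idx])
    got <- preranked_gsea(rk, sets, n_permutations = 10, min_size = 2,
                          seed = 1)
    expect_equal(got$es, brute_es(rk$rho, idx), tolerance = 1e-12, info = rep)
  }
  # larger random rankings and sizes, exponents 0 and 1
  for (rep in 1:10) {
    withr::with_seed(950 + rep, {
      rho2 <- stats::rnorm(100)
      m <- sample(5:30, 1)
    })
    rk2 <- toy_ranking(rho2)
    idx2 <- withr::with_seed(960 + rep, sort(sample(100, m)))
    for (expo in c(0, 1)) {
      got2 <- preranked_gsea(rk2, list(s = rk2$gene[idx2]),
                             n_permutations = 10, weight_exponent = expo,
                             seed = 1)
      expect_equal(got2$es, brute_es(rk2$rho, idx2, exponent = expo),
                   tolerance = 1e-12, info = paste(rep, expo))
    }
  }
})

test_that("enrichment scores agree with the independent fgsea implementation", {
  for (rep in 1:6) {
    withr::with_seed(1000 + rep, {
      rho <- stats::rnorm(200)
      m <- sample(8:40, 1)
    })
    rk <- toy_ranking(rho)
    idx <- withr::with_seed(1010 + rep, sort(sample(200, m)))
    ours <- preranked_gsea(rk, list(s = rk$gene[idx]), n_permutations = 10,
                           seed = 1)$es
    stats_vec <- stats::setNames(rk$rho, rk$gene)
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = idx, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9, info = rep)
  }
})

test_that("enrichment score properties: range, top-set positivity, reversal", {
  rho <- withr::with_seed(1101, sort(stats::rnorm(50), decreasing = TRUE))
  rk <- toy_ranking(rho)
  top <- list(top10 = rk$gene[1:10])
  res <- preranked_gsea(rk, top, n_permutations = 200, seed = 3)
  expect_gt(res$es, 0)
  # running-sum maximum sits at the last of the ten top genes
  expect_identical(res$leading_edge, paste(rk$gene[1:10], collapse = "/"))
  for (rep in 1:10) {
    withr::with_seed(1110 + rep, {
      r2 <- stats::rnorm(60)
      idx <- sort(sample(60, 12))
    })
    rk2 <- toy_ranking(r2)
    set <- list(s = rk2$gene[idx])
    for (expo in c(0, 1)) {
      es <- preranked_gsea(rk2, set, n_permutations = 10,
                           weight_exponent = expo, seed = 1)$es
      expect_true(es >= -1 && es <= 1)
      # reversing the ranking flips the enrichment side
      rk_rev <- toy_ranking(-r2)
      es_rev <- preranked_gsea(rk_rev, set, n_permutations = 10,
                               weight_exponent = expo, seed = 1)$es
      if (expo == 0) expect_equal(es_rev, -es, tolerance = 1e-12)
      else expect_true(sign(es_rev) != sign(es) || es == 0)
    }
  }
})

test_that("permutation p-values respect the +1 smoothing floor and seeds", {
  f <- simulate_feature_matrix(60, seed = 1201)
  fv <- stats::setNames(f$interaction_tumor_stroma, f$patient_id)
  sim <- simulate_expression(fv, n_genes = 400, n_correlated = 20,
                             planted_set_size = 10, n_decoy_sets = 5,
                             decoy_set_size = 10, seed = 1202)
  rk <- rank_genes(sim$expression, fv)
  enr <- preranked_gsea(rk, sim$sets, n_permutations = 99, seed = 7)
  expect_true(all(enr$p >= 1 / 100 & enr$p <= 1))
  expect_true(all(enr$padj >= enr$p))
  expect_identical(preranked_gsea(rk, sim$sets, n_permutations = 99, seed = 7),
                   enr)
  # size filtering: no surviving set warns and returns empty
  expect_warning(
    empty <- preranked_gsea(rk, sim$sets, n_permutations = 9, min_size = 50),
    "no gene set survives")
  expect_identical(nrow(empty), 0L)
})

test_that("patient-ID shuffling preserves values and reruns the analysis", {
  f <- simulate_feature_matrix(40, seed = 1301)
  fv <- stats::setNames(f$interaction_tumor_stroma, f$patient_id)
  sim <- simulate_expression(fv, n_genes = 300, n_correlated = 20,
                             planted_set_size = 10, n_decoy_sets = 4,
                             decoy_set_size = 10, seed = 1302)
  ctl <- shuffle_control(sim$expression, fv, sim$sets, seed = 5,
                         n_permutations = 99)
  expect_setequal(names(ctl$permutation), unname(ctl$permutation))
  expect_false(identical(names(ctl$permutation), unname(ctl$permutation)))
  ctl2 <- shuffle_control(sim$expression, fv, sim$sets, seed = 5,
                          n_permutations = 99)
  expect_identical(ctl2$permutation, ctl$permutation)
  expect_identical(ctl2$enrichment, ctl$enrichment)
  expect_true(all(c("set", "es", "p", "padj") %in% names(ctl$enrichment)))
})

test_that("marker panel summaries equal a direct group-by recomputation", {
  pans <- marker_panels()
  expect_true(all(lengths(pans) >= 1))
  expect_true(all(unlist(pans) == toupper(unlist(pans))))
  withr::with_seed(1401, {
    n <- 50
    fv <- stats::setNames(stats::runif(n), sprintf("P%02d", 1:n))
    up <- 5 * fv + stats::rnorm(n, sd = 0.2)   # increases with the feature
    flat <- stats::rnorm(n)                    # independent of the feature
    ex <- rbind(ACTA2 = up, PECAM1 = flat)
    colnames(ex) <- names(fv)
  })
  expect_warning(res <- marker_panel_summary(ex, fv, n_bins = 5),
                 "not in matrix")
  acta <- res$bins[res$bins$gene == "ACTA2", ]
  expect_true(all(diff(acta$mean_z[order(acta$bin)]) > 0))
  pec <- res$bins[res$bins$gene == "PECAM1", ]
  expect_true(all(abs(pec$mean_z) < 1))
  expect_setequal(res$missing, setdiff(unlist(pans), c("ACTA2", "PECAM1")))
  # group-by oracle: recompute one bin mean directly
  z <- (ex["ACTA2", ] - mean(ex["ACTA2", ])) / stats::sd(ex["ACTA2", ])
  bin_direct <- floor((rank(fv, ties.method = "first") - 1) * 5 / n) + 1
  for (b in 1:5)
    expect_equal(acta$mean_z[acta$bin == b], mean(z[bin_direct == b]),
                 info = b)
  expect_equal(res$correlations$rho[res$correlations$gene == "ACTA2"],
               unname(stats::cor(ex["ACTA2", ], fv, method = "spearman")))
  expect_error(marker_panel_summary(ex, fv, n_bins = 51), "exceeds")
})
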