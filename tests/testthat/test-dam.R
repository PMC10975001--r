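test_that("log2_fold_change matches direct evaluation and rejects bad input", {
  expect_equal(log2_fold_change(100, 200, 1e-12), 1, tolerance = 1e-9)
  expect_equal(log2_fold_change(57, 57, 0.5), 0)
  expect_equal(log2_fold_change(0, 800, 1), log2(801))
  expect_equal(log2(801), 9.645658, tolerance = 1e-6)
  expect_error(log2_fold_change(-1, 5, 1), "non-negative")
  expect_error(log2_fold_change(1, 5, 0), "pseudo")
})

test_that("opls-da on a single separating feature gives R2Y = 1 and label-shaped scores", {
  y <- c(-1, -1, -1, 1, 1, 1)
  x <- matrix(c(1, 1, 1, 5, 5, 5), nrow = 1,
              dimnames = list("f1", paste0("s", 1:6)))
  m <- fit_opls_da(x, y, n_orthogonal = 0L)
  expect_equal(m$r2y, 1)
  expect_equal(cor(m$scores, y), 1)
  # requesting orthogonal components degrades gracefully: none exist
  m1 <- fit_opls_da(x, y, n_orthogonal = 1L)
  expect_equal(m1$n_orthogonal, 0L)
})

test_that("opls-da is label-equivariant and enforces preconditions", {
  set.seed(42)
  x <- matrix(rnorm(10 * 8, mean = 10), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  y <- rep(c(-1, 1), each = 4)
  m <- fit_opls_da(x, y)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  mp <- fit_opls_da(x[, perm], y[perm])
  expect_equal(mp$scores, m$scores[perm], tolerance = 1e-10)
  expect_error(fit_opls_da(x, y, n_orthogonal = 7L), "n_orthogonal")
  expect_error(fit_opls_da(x[, 1:4], c(-1, -1, -1, 1)), ">= 2 samples")
  x0 <- rbind(x, flat = rep(3, 8))
  expect_warning(m0 <- fit_opls_da(x0, y), "zero-variance")
  expect_equal(m0$excluded, "flat")
})

test_that("predictive scores stay orthogonal to orthogonal scores and noise features get small loadings", {
  set.seed(42)
  n <- 20
  y <- rep(c(-1, 1), each = n / 2)
  base <- outer(rep(1, 10), ifelse(y > 0, 8, 2))
  x <- base * exp(matrix(rnorm(10 * n, 0, 0.01), 10))
  x <- rbind(x, noise = 5 * exp(rnorm(n, 0, 0.01)))
  rownames(x) <- c(paste0("f", 1:10), "noise")
  colnames(x) <- paste0("s", 1:n)
  m <- fit_opls_da(x, y, n_orthogonal = 1L)
  expect_lt(abs(sum(m$scores * m$orthogonal$scores[, 1])), 1e-8)
  expect_lt(abs(m$loadings["noise"]), 0.1)
  expect_lt(abs(m$weights["noise"]), 0.1)
})

test_that("vip scores satisfy the normalisation identity and symmetry", {
  set.seed(7)
  y <- rep(c(-1, 1), each = 5)
  # identical informative features -> all VIP exactly 1
  sig <- ifelse(y > 0, 4, 1)
  x <- matrix(rep(sig, each = 6), nrow = 6) +
    matrix(rnorm(60, 0, 1e-4), nrow = 6)
  x <- x[rep(1, 6), ]  # truly identical rows
  rownames(x) <- paste0("f", 1:6)
  colnames(x) <- paste0("s", 1:10)
  m <- fit_opls_da(x, y, n_orthogonal = 0L)
  expect_equal(unname(vip_scores(m)), rep(1, 6), tolerance = 1e-8)

  # identity mean(VIP^2) = 1 for arbitrary fits, with and without
  # orthogonal components in the formula
  x2 <- matrix(rlnorm(12 * 10), nrow = 12,
               dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  m2 <- fit_opls_da(x2, y, n_orthogonal = 2L)
  expect_equal(mean(vip_scores(m2)^2), 1, tolerance = 1e-8)
  expect_equal(mean(vip_scores(m2, include_orthogonal = TRUE)^2), 1,
               tolerance = 1e-8)
})

test_that("vip matches the independently coded textbook oracle", {
  set.seed(123)
  x <- matrix(rlnorm(10 * 6, meanlog = 2), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  y <- c(-1, -1, -1, 1, 1, 1)
  for (k in 0:1) {
    got <- vip_scores(fit_opls_da(x, y, n_orthogonal = k))
    expect_equal(got, vip_oracle(x, y, n_orthogonal = k),
                 tolerance = 1e-8)
  }
})

test_that("screen_dams applies inclusive thresholds and recovers planted effects", {
  # rule check on constructed compartment means
  means <- rbind(up = c(100, 400, 50, 50), flat = c(80, 80, 80, 80),
                 down = c(400, 100, 60, 60))
  colnames(means) <- COMPARTMENTS
  set.seed(1)
  ft <- ft_from_means(means, jitter = 0.02)
  d <- screen_dams(ft, c("TH", "THC"))
  expect_equal(d$regulation[match(c("up", "flat", "down"), d$feature_id)],
               c("up", "not_significant", "down"))

  # planted recovery: 20 four-fold features among 1000
  exp <- generate_experiment(sim_params(
    n_genes = 10L, n_metabolites = 1000L, n_common_dams = 20L,
    n_mobile_th_to_p = 0L, n_mobile_p_to_th = 0L,
    n_haustoria_genes = 0L, n_correlated_pairs = 0L,
    n_transferred_host_to_parasite = 0L,
    n_transferred_parasite_to_host = 0L,
    genome_length = 2000L, seed = 5L))
  d <- screen_dams(exp$metabolites, c("TH", "THC"))
  called <- d$feature_id[d$regulation != "not_significant"]
  expect_setequal(called, names(exp$truth$common_dam_types))
  up_truth <- exp$truth$dam_up$TH_vs_THC
  expect_setequal(d$feature_id[d$regulation == "up"], up_truth)
})

test_that("screen_dams is invariant to feature and sample order and monotone in effect size", {
  set.seed(3)
  means <- matrix(rlnorm(40, 8), 10,
                  dimnames = list(paste0("m", 1:10), COMPARTMENTS))
  means[1, "THC"] <- means[1, "TH"] * 4
  ft <- ft_from_means(means, jitter = 0.03)
  d <- screen_dams(ft, c("TH", "THC"))

  shuffled <- ft_subset(ft, features = rev(rownames(ft$values)),
                        samples = rev(colnames(ft$values)))
  d2 <- screen_dams(shuffled, c("TH", "THC"))
  d2 <- d2[match(d$feature_id, d2$feature_id), ]
  expect_equal(d2$log2fc, d$log2fc, tolerance = 1e-12)
  expect_equal(d2$vip, d$vip, tolerance = 1e-10)
  expect_equal(d2$regulation, d$regulation)

  # raising a planted fold change never flips up -> not_significant
  # (fixed noise: the same jitter matrix is applied at every fold)
  calls <- sapply(c(2, 4, 8, 16), function(f) {
    m <- means
    m[1, "THC"] <- m[1, "TH"] * f
    set.seed(99)
    dd <- screen_dams(ft_from_means(m, jitter = 0.03), c("TH", "THC"))
    dd$regulation[dd$feature_id == "m1"]
  })
  expect_true(all(diff(calls == "up") >= 0))   # monotone, no flip back
  expect_equal(calls[4], "up")
})

test_that("pca_qc is deterministic, handles degenerate tables, and separates synthetic compartments", {
  means <- matrix(rlnorm(80, 8), 20,
                  dimnames = list(paste0("m", 1:20), COMPARTMENTS))
  # give each compartment its own signature on half the features
  for (j in 1:4) means[(j - 1) * 5 + 1:5, j] <- means[(j - 1) * 5 + 1:5, j] * 6
  set.seed(8)
  ft <- ft_from_means(means, jitter = 0.05)
  pc <- pca_qc(ft)
  sil <- mean_silhouette(pc$scores[, 1:2], ft$compartments)
  expect_gt(sil, 0.5)
  # duplicated sample -> identical scores
  v <- ft$values
  v <- cbind(v, TH_dup = v[, "TH_1"])
  ft2 <- feature_table(v, c(ft$compartments, TH_dup = "TH"), "metabolite")
  pc2 <- pca_qc(ft2)
  expect_equal(pc2$scores["TH_dup", ], pc2$scores["TH_1", ])
  # single feature -> PC1 explains everything
  ft1 <- ft_subset(ft, features = "m1")
  expect_equal(pca_qc(ft1)$explained_variance[1], 1)
})

test_that("hypergeometric enrichment is exact and saturates correctly", {
  # N = 10, K = 5, n = 5, k = 5 -> 1 / choose(10, 5)
  uni <- letters[1:10]
  res <- hypergeometric_enrichment(letters[1:5], uni,
                                   list(t1 = letters[1:5]))
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$p_value, 0.003968254, tolerance = 1e-6)
  # k = 0 and empty terms give p = 1
  res2 <- hypergeometric_enrichment(letters[6:10], uni,
                                    list(t1 = letters[1:5],
                                         t2 = character()))
  expect_equal(res2$p_value, c(1, 1))
  expect_true(res2$empty_term[2])
  # selected = universe -> every term saturated at p = 1
  res3 <- hypergeometric_enrichment(uni, uni,
                                    list(t1 = letters[1:5],
                                         t2 = letters[2:9]))
  expect_equal(res3$p_value, c(1, 1))
  expect_error(hypergeometric_enrichment(c("zz"), uni, list(t = uni)),
               "subset")
})

test_that("coregulation classes intersect the two screens by feature", {
  dams_th <- dams_from_types(c("jasmonic", "tartaric", "only_th"),
                             c("up", "up", "down"), "TH_vs_THC")
  dams_p <- dams_from_types(c("jasmonic", "tartaric", "only_p"),
                            c("up", "down", "up"), "P_vs_PC")
  cr <- coregulation_classes(dams_th, dams_p)
  expect_equal(nrow(cr), 2L)
  expect_equal(cr$type_pair[cr$feature_id == "jasmonic"], "up/up")
  expect_equal(cr$type_pair[cr$feature_id == "tartaric"], "up/down")
  # disjoint significant sets -> empty
  expect_equal(nrow(coregulation_classes(
    dams_from_types("a", "up", "TH_vs_THC"),
    dams_from_types("b", "up", "P_vs_PC"))), 0L)
})

test_that("the differential-expression stand-in flags strong changes and ignores flat genes", {
  means <- rbind(up4 = c(10, 40, 10, 10), flat = c(25, 25, 25, 25),
                 down4 = c(40, 10, 20, 20))
  colnames(means) <- COMPARTMENTS
  set.seed(21)
  ft <- ft_from_means(means, kind = "gene", jitter = 0.03)
  de <- diff_expression_standin(ft, c("TH", "THC"))
  expect_true(de$upregulated[de$feature_id == "up4"])
  expect_true(de$downregulated[de$feature_id == "down4"])
  expect_false(any(de[de$feature_id == "flat",
                      c("upregulated", "downregulated")] == TRUE))
})
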