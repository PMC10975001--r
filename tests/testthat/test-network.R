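test_that("common_chimera_genes intersects with stable ordering", {
  expect_equal(common_chimera_genes(c("c", "a", "b"), c("b", "d", "c")),
               c("b", "c"))
  expect_equal(common_chimera_genes(c("a"), c("b")), character(0))
  set.seed(2)
  shared <- sprintf("u%03d", sample(999, 30))
  thc <- c(shared, sprintf("t%03d", 1:40))
  pc <- c(sprintf("p%03d", 1:25), shared)
  expect_setequal(common_chimera_genes(thc, pc), shared)
})

test_that("haustoria selection combines upregulation with the intact predicate", {
  # printed exemplar: ACT11-like means pass the intact predicate under
  # "any" (P = 0.0 < 0.3) despite TH = 0.3; a gene high in both intact
  # compartments never qualifies
  t4 <- compartment_means(load_table4())
  act11 <- t4["Cluster-30463.1", ]
  expect_equal(unname(act11), c(0.3, 5.2, 1.7, 0.0))
  expect_true(hausflow:::intact_below(act11, 0.3, "any"))
  expect_false(hausflow:::intact_below(act11, 0.3, "both"))
  high <- c(TH = 50, THC = 400, PC = 300, P = 50)
  expect_false(hausflow:::intact_below(high, 0.3, "any"))
  expect_false(hausflow:::intact_below(high, 0.3, "both"))
  # TCTP-like row (TH = 8295) shows why "both" contradicts the printed
  # selection: only "any" admits it
  tctp <- t4["Cluster-37697.0", ]
  expect_true(hausflow:::intact_below(tctp, 0.3, "any"))
  expect_false(hausflow:::intact_below(tctp, 0.3, "both"))

  means <- rbind(haus = c(0.05, 20, 20, 0.05),
                 high_intact = c(50, 400, 300, 50),
                 one_side = c(0.05, 20, 10, 10))
  colnames(means) <- COMPARTMENTS
  set.seed(6)
  ft <- ft_from_means(means, kind = "gene", jitter = 0.03)
  sel <- stats::setNames(select_haustoria_genes(ft)$qualifies,
                         rownames(means))
  expect_true(sel[["haus"]])
  expect_false(sel[["high_intact"]])   # fails intact predicate
  expect_false(sel[["one_side"]])      # not upregulated on the host side
})

test_that("planted haustoria genes are recovered exactly at low noise", {
  e <- generate_experiment(sim_params(
    n_genes = 200L, n_metabolites = 10L, n_mobile_th_to_p = 0L,
    n_mobile_p_to_th = 0L, n_haustoria_genes = 12L, n_common_dams = 0L,
    n_correlated_pairs = 0L, n_transferred_host_to_parasite = 0L,
    n_transferred_parasite_to_host = 0L, genome_length = 2000L,
    seed = 3L))
  sel <- select_haustoria_genes(e$genes)
  expect_setequal(sel$feature_id[sel$qualifies], e$truth$haustoria_genes)
})

test_that("pearson_network retains perfect correlations and applies strict thresholds", {
  g <- matrix(c(1, 2, 3, 4, 5, 6), 1,
              dimnames = list("geneA", paste0("s", 1:6)))
  m <- 2 * g
  rownames(m) <- "metB"
  comps <- stats::setNames(rep(c("THC", "PC"), each = 3), colnames(g))
  gt <- feature_table(g, comps, "gene")
  mt <- feature_table(m, comps, "metabolite")
  e <- pearson_network(gt, mt)
  expect_equal(nrow(e), 1L)
  expect_equal(e$pcc, 1)
  expect_equal(e$sign, "pos")
  expect_equal(e$p_value, .Machine$double.xmin)

  # strictness: pcc_min equal to the observed |r| excludes the edge
  set.seed(10)
  m2 <- matrix(g + rnorm(6, 0, 0.8), 1, dimnames = list("metC",
                                                        colnames(g)))
  mt2 <- feature_table(m2, comps, "metabolite")
  r_obs <- cor(g[1, ], m2[1, ])
  expect_equal(nrow(pearson_network(gt, mt2, pcc_min = abs(r_obs),
                                    p_max = 1)), 0L)
  expect_equal(nrow(pearson_network(gt, mt2,
                                    pcc_min = abs(r_obs) - 1e-9,
                                    p_max = 1)), 1L)

  # errors and warnings
  expect_error(pearson_network(ft_subset(gt, samples = c("s1", "s2")),
                               ft_subset(mt, samples = c("s1", "s2"))),
               ">= 3 shared samples")
  const <- feature_table(matrix(5, 1, 6, dimnames = list("flat",
                                                         colnames(g))),
                         comps, "metabolite")
  expect_warning(pearson_network(gt, const), "constant")
})

test_that("the edge set is invariant to joint sample permutation and affine maps", {
  set.seed(14)
  comps <- stats::setNames(rep(c("THC", "PC"), each = 3),
                           paste0("s", 1:6))
  g <- matrix(rlnorm(5 * 6, 3), 5,
              dimnames = list(paste0("g", 1:5), names(comps)))
  m <- matrix(rlnorm(4 * 6, 8), 4,
              dimnames = list(paste0("m", 1:4), names(comps)))
  m[1, ] <- g[1, ] * 3 + 2                       # planted positive edge
  m[2, ] <- -0.5 * g[2, ] + max(g[2, ]) * 2      # planted negative edge
  gt <- feature_table(g, comps, "gene")
  mt <- feature_table(m, comps, "metabolite")
  edges <- pearson_network(gt, mt)
  expect_true(all(c("pos", "neg") %in%
                    edges$sign[edges$gene_id %in% c("g1", "g2")]))

  perm <- sample(names(comps))
  edges_p <- pearson_network(
    feature_table(g[, perm], comps[perm], "gene"),
    feature_table(m[, perm], comps[perm], "metabolite"))
  expect_equal(edges_p, edges, tolerance = 1e-12)

  # r(x, a*y + b) = sign(a) * r(x, y)
  for (a in c(2.5, -1.25)) {
    r0 <- cor(g[3, ], m[3, ])
    r1 <- cor(g[3, ], a * m[3, ] + 7)
    expect_equal(r1, sign(a) * r0, tolerance = 1e-12)
  }
})

test_that("t-transform p-values track a permutation null loosely at n = 6", {
  # the permutation distribution at n = 6 has only 720 atoms, so exact
  # agreement with the t density is impossible (see the acceptance
  # suite); here we pin the sound weaker property: agreement within 0.05
  set.seed(2024)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    r <- cor(x, y)
    p_t <- pearson_p(r, 6)
    rp <- replicate(20000, cor(x, sample(y)))
    p_perm <- (1 + sum(abs(rp) >= abs(r) - 1e-12)) / 20001
    expect_lt(abs(p_t - p_perm), 0.05)
  }
})

test_that("planted latent pairs are recovered at >= 95% over many seeded replicates", {
  hits <- 0L; total <- 0L; false_edges <- 0L; null_pairs <- 0L
  for (s in 1:60) {
    e <- generate_experiment(sim_params(
      n_genes = 14L, n_metabolites = 14L, n_mobile_th_to_p = 0L,
      n_mobile_p_to_th = 0L, n_haustoria_genes = 0L, n_common_dams = 0L,
      n_correlated_pairs = 6L, n_transferred_host_to_parasite = 0L,
      n_transferred_parasite_to_host = 0L, genome_length = 2000L,
      seed = s))
    chim <- colnames(e$genes$values)[
      e$genes$compartments %in% c("THC", "PC")]
    tr <- e$truth$correlated_pairs
    # restrict to the flat pair features: partner pairs measure
    # sensitivity, non-partner crossings give a clean independence null
    edges <- suppressWarnings(
      pearson_network(ft_subset(e$genes, features = tr$gene_id),
                      ft_subset(e$metabolites,
                                features = tr$metabolite_id),
                      samples = chim))
    key <- paste(edges$gene_id, edges$metabolite_id)
    tkey <- paste(tr$gene_id, tr$metabolite_id)
    hits <- hits + sum(tkey %in% key)
    total <- total + length(tkey)
    false_edges <- false_edges + sum(!(key %in% tkey))
    null_pairs <- null_pairs + nrow(tr)^2 - nrow(tr)
    # recovered signs match the planted signs
    m <- match(tkey, key)
    ok <- !is.na(m)
    expect_equal(edges$sign[m[ok]], tr$sign[ok])
  }
  expect_gte(hits / total, 0.95)
  # false edges consistent with the p < 0.05 retention rule under
  # independence (generous binomial band around 0.05)
  expect_lt(false_edges / null_pairs, 0.09)
  expect_gt(false_edges / null_pairs, 0.02)
})
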