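# shared fixture builders and independent oracles

ext_file <- function(name) {
  path <- system.file("extdata", name, package = "hausflow")
  if (!nzchar(path)) stop("missing extdata fixture: ", name)
  path
}

single_rep_map <- function() {
  read_sample_map(ext_file("four_compartments_single.tsv"))
}

load_table2 <- function() {
  read_feature_table(ext_file("table2_transferred_metabolites.tsv"),
                     single_rep_map(), "metabolite",
                     meta_cols = "category")
}

load_table3 <- function() {
  read_feature_table(ext_file("table3_mobile_genes_fpkm.tsv"),
                     single_rep_map(), "gene", meta_cols = "gene")
}

load_table4 <- function() {
  read_feature_table(ext_file("table4_haustoria_genes_fpkm.tsv"),
                     single_rep_map(), "gene", meta_cols = "gene")
}

load_table1 <- function() {
  utils::read.delim(ext_file("table1_common_dams.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# features x samples table over the 4 x n_reps design from a matrix of
# compartment means, without noise
ft_from_means <- function(means, n_reps = 3, kind = "metabolite",
                          jitter = 0) {
  comps <- rep(COMPARTMENTS, each = n_reps)
  samples <- paste(comps, seq_len(n_reps), sep = "_")
  v <- means[, comps, drop = FALSE]
  if (jitter > 0) v <- v * exp(matrix(rnorm(length(v), 0, jitter),
                                      nrow(v)))
  colnames(v) <- samples
  feature_table(v, stats::setNames(comps, samples), kind)
}

# Turn Table 1's regulation labels into screen_dams-shaped records with
# synthetic-but-consistent effect sizes (the printed table carries calls,
# not raw intensities).
dams_from_types <- function(ids, types, comparison) {
  data.frame(feature_id = ids, comparison = comparison,
             log2fc = ifelse(types == "up", 2, -2),
             vip = 1.5, regulation = types,
             stringsAsFactors = FALSE)
}

# independently coded OPLS-DA VIP oracle: scalar-loop implementation of
# autoscaling, orthogonal deflation and the textbook VIP formula
vip_oracle <- function(x, y, n_orthogonal = 1) {
  X <- t(x)
  n <- nrow(X); p <- ncol(X)
  for (j in seq_len(p)) {
    m <- sum(X[, j]) / n
    s <- sqrt(sum((X[, j] - m)^2) / (n - 1))
    X[, j] <- (X[, j] - m) / s
  }
  yc <- y - sum(y) / n
  proj_w <- function(X) {
    w <- numeric(p)
    for (j in seq_len(p)) w[j] <- sum(X[, j] * yc)
    w / sqrt(sum(w * w))
  }
  for (o in seq_len(n_orthogonal)) {
    w <- proj_w(X)
    t1 <- numeric(n)
    for (i in seq_len(n)) t1[i] <- sum(X[i, ] * w)
    pl <- numeric(p)
    for (j in seq_len(p)) pl[j] <- sum(X[, j] * t1) / sum(t1 * t1)
    wo <- pl - sum(w * pl) * w
    if (sqrt(sum(wo * wo)) < 1e-10) break
    wo <- wo / sqrt(sum(wo * wo))
    to <- numeric(n)
    for (i in seq_len(n)) to[i] <- sum(X[i, ] * wo)
    po <- numeric(p)
    for (j in seq_len(p)) po[j] <- sum(X[, j] * to) / sum(to * to)
    for (i in seq_len(n)) for (j in seq_len(p))
      X[i, j] <- X[i, j] - to[i] * po[j]
  }
  w <- proj_w(X)
  # single predictive component: VIP_j = sqrt(p) * |w_j| / ||w||
  vip <- numeric(p)
  for (j in seq_len(p)) vip[j] <- sqrt(p * w[j]^2)
  stats::setNames(vip, rownames(x))
}

# mean silhouette width over euclidean distances (hand-rolled to stay
# independent of clustering packages)
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  mean(vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

write_blast_lines <- function(path, rows) {
  # rows: data.frame query, subject, evalue, bitscore
  lines <- sprintf("%s\t%s\t98.5\t100\t1\t0\t1\t100\t1\t100\t%s\t%s",
                   rows$query, rows$subject,
                   format(rows$evalue, scientific = TRUE),
                   format(rows$bitscore))
  writeLines(lines, path)
  path
}
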