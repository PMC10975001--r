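#' Log2 fold change of group means
#'
#' `log2((mean_test + pseudo) / (mean_ref + pseudo))`. Group means are
#' computed over replicates with missing cells treated as 0 before the
#' pseudo-shift.
#'
#' @param mean_ref,mean_test Non-negative group means (vectorised).
#' @param pseudo Positive pseudo-value guarding against zeros.
#' @return Numeric log2 fold change(s), positive when the test group is
#'   higher.
#' @export
log2_fold_change <- function(mean_ref, mean_test, pseudo) {
  if (any(mean_ref < 0, na.rm = TRUE) || any(mean_test < 0, na.rm = TRUE))
    stop("group means must be non-negative")
  if (any(pseudo <= 0)) stop("pseudo must be > 0")
  log2((mean_test + pseudo) / (mean_ref + pseudo))
}

default_pseudo <- function(ft) {
  v <- ft$values
  nz <- v[!is.na(v) & v > 0]
  if (!length(nz)) return(1)
  min(nz) / 2
}

comparison_label <- function(comparison)
  paste0(comparison[1L], "_vs_", comparison[2L])

#' Screen differentially accumulated features
#'
#' For one two-compartment comparison, computes per-feature log2 fold
#' change of compartment means and OPLS-DA VIP, and calls regulation:
#' `up` when `log2fc >= fc_min` and `vip >= vip_min`, `down` when
#' `log2fc <= -fc_min` and `vip >= vip_min`, else `not_significant`.
#' Both thresholds are inclusive. The defaults `vip_min = 1`,
#' `fc_min = 1` are the conventional DAM cutoffs for widely targeted
#' metabolomics.
#'
#' @param ft A [feature_table].
#' @param comparison Length-2 character vector
#'   `c(reference_compartment, test_compartment)`, e.g. `c("TH", "THC")`.
#' @param vip_min,fc_min Inclusive thresholds on VIP and |log2FC|.
#' @param pseudo Pseudo-value for the fold change; default half the
#'   smallest non-zero abundance in the table.
#' @param n_orthogonal Orthogonal components for the OPLS-DA fit.
#' @param aggregate `"mean"` or `"median"` replicate aggregation.
#' @return A `data.frame` with one row per feature: `feature_id`,
#'   `comparison`, `log2fc`, `vip`, `regulation`. Zero-variance features
#'   (excluded from the OPLS fit) carry `vip = 0`.
#' @export
screen_dams <- function(ft, comparison, vip_min = 1, fc_min = 1,
                        pseudo = NULL, n_orthogonal = 1L,
                        aggregate = "mean") {
  stopifnot(length(comparison) == 2L)
  missing_comp <- setdiff(comparison, unique(ft$compartments))
  if (length(missing_comp))
    stop("compartment absent from table: ", missing_comp[1L])
  if (is.null(pseudo)) pseudo <- default_pseudo(ft)
  sub <- ft_subset(ft, samples =
                     sample_ids(ft)[ft$compartments %in% comparison])
  if (nrow(sub$values) == 0L)
    return(data.frame(feature_id = character(),
                      comparison = character(), log2fc = numeric(),
                      vip = numeric(), regulation = character()))
  means <- compartment_means(sub, fun = aggregate)
  lfc <- log2_fold_change(means[, comparison[1L]],
                          means[, comparison[2L]], pseudo)
  y <- ifelse(sub$compartments == comparison[2L], 1, -1)
  model <- withCallingHandlers(
    fit_opls_da(sub, y, n_orthogonal = n_orthogonal),
    warning = function(w) {
      if (grepl("zero-variance", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  vip <- rep(0, nrow(sub$values))
  names(vip) <- feature_ids(sub)
  vv <- vip_scores(model)
  vip[names(vv)] <- vv
  regulation <- rep("not_significant", length(lfc))
  regulation[lfc >= fc_min & vip >= vip_min] <- "up"
  regulation[lfc <= -fc_min & vip >= vip_min] <- "down"
  data.frame(feature_id = feature_ids(sub),
             comparison = comparison_label(comparison),
             log2fc = unname(lfc), vip = unname(vip),
             regulation = regulation, stringsAsFactors = FALSE)
}

#' Cross-comparison co-regulation classes
#'
#' Intersects the significant features of two DAM screens (parasite side
#' `TH vs THC`, host side `P vs PC`) and labels each shared feature with
#' its regulation pair, e.g. `up/up` or `up/down`. Features shared by
#' both chimera responses are candidate haustoria-formation metabolites.
#'
#' @param dams_th,dams_p DAM tables from [screen_dams()] for the two
#'   comparisons.
#' @return A `data.frame` with `feature_id`, `type_th`, `type_p`,
#'   `type_pair`, restricted to features significant in both screens.
#' @export
coregulation_classes <- function(dams_th, dams_p) {
  sig_th <- dams_th[dams_th$regulation != "not_significant", ]
  sig_p <- dams_p[dams_p$regulation != "not_significant", ]
  common <- intersect(sig_th$feature_id, sig_p$feature_id)
  t_th <- sig_th$regulation[match(common, sig_th$feature_id)]
  t_p <- sig_p$regulation[match(common, sig_p$feature_id)]
  data.frame(feature_id = common, type_th = t_th, type_p = t_p,
             type_pair = paste(t_th, t_p, sep = "/"),
             stringsAsFactors = FALSE)
}

#' Principal component analysis for sample QC
#'
#' Centred, unit-variance-scaled PCA of samples (missing cells as 0;
#' zero-variance features dropped). Sign convention: within each
#' component the loading of largest magnitude (first on ties) is made
#' positive, so scores are reproducible across platforms.
#'
#' @param ft A [feature_table] with >= 3 samples.
#' @param scale. Unit-variance scale features (default `TRUE`).
#' @return List with `scores` (samples x PCs), `loadings`,
#'   `explained_variance` (proportions), `sdev`.
#' @export
pca_qc <- function(ft, scale. = TRUE) {
  v <- ft$values
  v[is.na(v)] <- 0
  if (ncol(v) < 3L) stop("PCA QC needs >= 3 samples")
  keep <- apply(v, 1L, stats::sd) > 0
  v <- v[keep, , drop = FALSE]
  if (!nrow(v)) stop("no feature with non-zero variance")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = scale.)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}

#' Hypergeometric (over-representation) enrichment
#'
#' Exact upper-tail hypergeometric test per term: with population
#' `N = |universe|`, `K = |term in universe|`, draw `n = |selected|`,
#' observe `k = |term in selected|`; `p = P(X >= k)`. Terms absent from
#' the universe get `p = 1` and are flagged. Benjamini-Hochberg adjusted
#' q-values are included.
#'
#' @param selected Character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param universe Character vector, the tested population.
#' @param term_map Named list `term -> character vector of feature ids`.
#' @return `data.frame`: `term`, `K`, `k`, `n`, `N`, `p_value`,
#'   `q_value`, `empty_term`.
#' @export
hypergeometric_enrichment <- function(selected, universe, term_map) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (length(setdiff(selected, universe)))
    stop("selected must be a subset of universe")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(term_map), function(tm) {
    ids <- intersect(term_map[[tm]], universe)
    K <- length(ids)
    k <- length(intersect(ids, selected))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, K = K, k = k, n = n, N = N, p_value = p,
               empty_term = K == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), K = integer(), k = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), empty_term = logical()))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[c("term", "K", "k", "n", "N", "p_value", "q_value", "empty_term")]
}

#' Differential-expression stand-in predicate
#'
#' Count-model differential testing needs raw read counts, which an
#' FPKM-level pipeline does not carry. This stand-in calls a gene
#' differential when `|log2FC| >= fc_min` (group means of raw FPKM,
#' pseudo-shifted) with a Welch t-test on `log2(FPKM + pseudo)` passing
#' Benjamini-Hochberg `q < q_max` across all genes in the table.
#'
#' @param ft A gene [feature_table].
#' @param comparison `c(reference_compartment, test_compartment)`.
#' @param fc_min Inclusive |log2FC| threshold (default 1).
#' @param q_max Exclusive BH-adjusted q threshold (default 0.05).
#' @param pseudo Pseudo-value; default half the smallest non-zero value.
#' @return `data.frame`: `feature_id`, `log2fc`, `p_value`, `q_value`,
#'   `upregulated`, `downregulated`.
#' @export
diff_expression_standin <- function(ft, comparison, fc_min = 1,
                                    q_max = 0.05, pseudo = NULL) {
  stopifnot(length(comparison) == 2L)
  if (is.null(pseudo)) pseudo <- default_pseudo(ft)
  v <- ft$values
  v[is.na(v)] <- 0
  ref <- v[, ft$compartments == comparison[1L], drop = FALSE]
  tst <- v[, ft$compartments == comparison[2L], drop = FALSE]
  if (!ncol(ref) || !ncol(tst))
    stop("compartment absent from table: ", comparison_label(comparison))
  lfc <- log2_fold_change(rowMeans(ref), rowMeans(tst), pseudo)
  p <- welch_p(log2(ref + pseudo), log2(tst + pseudo))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = feature_ids(ft) %||% character(0),
             log2fc = unname(lfc),
             p_value = unname(p), q_value = unname(q),
             upregulated = unname(lfc >= fc_min & q < q_max),
             downregulated = unname(lfc <= -fc_min & q < q_max),
             stringsAsFactors = FALSE)
}

# row-wise Welch t-test p-values; degenerate rows (zero pooled standard
# error) get p = 1 when the means agree and p = 0 otherwise
welch_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, length(m1))
  zero <- se2 == 0
  p[zero & m1 != m2] <- 0
  ok <- !zero
  if (any(ok)) {
    tstat <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) +
                         (v2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * stats::pt(-abs(tstat), df)
  }
  p
}
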