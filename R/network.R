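#' Genes shared by the two chimera assemblies
#'
#' Set intersection of the (origin-filtered) unigene id sets of the
#' parasite-side and host-side chimeras, returned in stable lexicographic
#' (C collation) order.
#'
#' @param thc_ids,pc_ids Character vectors of unigene ids.
#' @return Sorted character vector of shared ids.
#' @export
common_chimera_genes <- function(thc_ids, pc_ids) {
  sort(intersect(unique(thc_ids), unique(pc_ids)), method = "radix")
}

#' Select haustoria-formation-associated genes
#'
#' A gene qualifies when it is upregulated in both chimeras relative to
#' the matching intact root (`TH -> THC` and `P -> PC`, via the
#' documented differential-expression stand-in predicate,
#' [diff_expression_standin()]) and its intact-compartment FPKM is below
#' `fpkm_intact_max`. `intact_mode = "any"` (default) requires
#' `min(FPKM_TH, FPKM_P) < fpkm_intact_max` — a gene essentially silent
#' in at least one parasitism-free root; `"both"` requires both intact
#' compartments below the cutoff.
#'
#' @param ft A gene [feature_table] covering all four compartments.
#' @param genes Optional character vector restricting the candidate set
#'   (e.g. [common_chimera_genes()] output); the multiple-testing
#'   correction runs within this set.
#' @param fpkm_intact_max Intact-compartment FPKM ceiling (default 0.3).
#' @param intact_mode `"any"` (default) or `"both"`, see above.
#' @param fc_min,q_max Thresholds of the upregulation stand-in.
#' @param pseudo Pseudo-value for fold changes; default derived from the
#'   table.
#' @return `data.frame`: `feature_id`, `fpkm_th/thc/pc/p`,
#'   `upregulated_thc`, `upregulated_pc`, `intact_min_fpkm`, `qualifies`.
#' @export
select_haustoria_genes <- function(ft, genes = NULL,
                                   fpkm_intact_max = 0.3,
                                   intact_mode = c("any", "both"),
                                   fc_min = 1, q_max = 0.05,
                                   pseudo = NULL) {
  intact_mode <- match.arg(intact_mode)
  if (!is.null(genes)) ft <- ft_subset(ft, features = genes)
  de_th <- diff_expression_standin(ft, c("TH", "THC"), fc_min, q_max,
                                   pseudo)
  de_p <- diff_expression_standin(ft, c("P", "PC"), fc_min, q_max,
                                  pseudo)
  m <- compartment_means(ft)
  intact_min <- pmin(m[, "TH"], m[, "P"])
  intact_ok <- if (intact_mode == "any")
    intact_min < fpkm_intact_max
  else
    pmax(m[, "TH"], m[, "P"]) < fpkm_intact_max
  qualifies <- de_th$upregulated & de_p$upregulated & intact_ok
  data.frame(feature_id = rownames(m) %||% character(0),
             fpkm_th = m[, "TH"], fpkm_thc = m[, "THC"],
             fpkm_pc = m[, "PC"], fpkm_p = m[, "P"],
             upregulated_thc = de_th$upregulated,
             upregulated_pc = de_p$upregulated,
             intact_min_fpkm = unname(intact_min),
             qualifies = unname(qualifies),
             row.names = NULL, stringsAsFactors = FALSE)
}

# intact-compartment predicate on a named vector of four means; used by
# select_haustoria_genes and exercised directly in the tests
intact_below <- function(means, fpkm_intact_max = 0.3,
                         intact_mode = c("any", "both")) {
  intact_mode <- match.arg(intact_mode)
  if (intact_mode == "any")
    min(means[["TH"]], means[["P"]]) < fpkm_intact_max
  else
    max(means[["TH"]], means[["P"]]) < fpkm_intact_max
}

#' Gene-metabolite Pearson correlation network
#'
#' For every gene x metabolite pair, the Pearson correlation across the
#' shared samples and a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Edges are retained under strict thresholds `|r| > pcc_min` and
#' `p < p_max`. A perfect correlation (`r = +/-1`) is retained with the
#' smallest representable positive p-value.
#'
#' @param gene_ft Gene [feature_table] restricted to the selected genes.
#' @param metab_ft Metabolite [feature_table] restricted to the selected
#'   metabolites (missing cells treated as 0).
#' @param samples Character vector of shared sample ids over which to
#'   correlate; default the intersection of the two tables' samples. At
#'   least 3 are required.
#' @param pcc_min,p_max Strict retention thresholds (defaults 0.80 and
#'   0.05).
#' @param adjust `"none"` (default; the raw p-value is thresholded) or
#'   `"BH"` (threshold applied to Benjamini-Hochberg q over all pairs).
#' @return `data.frame` of retained edges: `gene_id`, `metabolite_id`,
#'   `pcc`, `p_value`, `sign` (`pos`/`neg`), ordered lexicographically.
#'   Constant vectors are dropped with a warning.
#' @export
pearson_network <- function(gene_ft, metab_ft, samples = NULL,
                            pcc_min = 0.80, p_max = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(samples))
    samples <- intersect(sample_ids(gene_ft), sample_ids(metab_ft))
  n <- length(samples)
  if (n < 3L) stop("pearson_network needs >= 3 shared samples, got ", n)
  g <- gene_ft$values[, samples, drop = FALSE]
  m <- metab_ft$values[, samples, drop = FALSE]
  g[is.na(g)] <- 0
  m[is.na(m)] <- 0
  keep_g <- apply(g, 1L, stats::sd) > 0
  keep_m <- apply(m, 1L, stats::sd) > 0
  if (any(!keep_g))
    warning("dropping ", sum(!keep_g), " constant gene vector(s)")
  if (any(!keep_m))
    warning("dropping ", sum(!keep_m), " constant metabolite vector(s)")
  g <- g[keep_g, , drop = FALSE]
  m <- m[keep_m, , drop = FALSE]
  empty <- data.frame(gene_id = character(), metabolite_id = character(),
                      pcc = numeric(), p_value = numeric(),
                      sign = character())
  if (!nrow(g) || !nrow(m)) return(empty)
  r <- stats::cor(t(g), t(m))
  p <- pearson_p(r, n)
  edges <- data.frame(
    gene_id = rep(rownames(g), times = ncol(r)),
    metabolite_id = rep(colnames(r), each = nrow(r)),
    pcc = as.vector(r), p_value = as.vector(p),
    stringsAsFactors = FALSE)
  crit_p <- if (adjust == "BH")
    stats::p.adjust(edges$p_value, method = "BH") else edges$p_value
  keep <- abs(edges$pcc) > pcc_min & crit_p < p_max
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges)) return(empty)
  edges$sign <- ifelse(edges$pcc >= 0, "pos", "neg")
  edges <- edges[order(edges$gene_id, edges$metabolite_id,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @rdname pearson_network
#' @param r Pearson correlation(s).
#' @param n Sample size used for `r`.
#' @export
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, .Machine$double.xmin,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
  if (is.matrix(r)) p <- matrix(p, nrow(r), dimnames = dimnames(r))
  p
}
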