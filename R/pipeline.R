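#' Pipeline configuration with study-default thresholds
#'
#' Every numeric cutoff defaults to the value used in the four-compartment
#' study design this pipeline implements: DAMs at `VIP >= 1` and
#' `|log2FC| >= 1`; mobile genes at compartment-mean `FPKM >= 3`
#' (inclusive presence); haustoria genes at intact `FPKM < 0.3`; network
#' edges at `|PCC| > 0.80` and `p < 0.05`; alignment hits at
#' `E-value <= 1e-10`.
#'
#' @param vip_min,fc_min DAM thresholds (inclusive).
#' @param fpkm_min Mobile-gene presence threshold.
#' @param fpkm_intact_max Haustoria intact-compartment ceiling.
#' @param pcc_min,p_max Network retention thresholds (strict).
#' @param evalue_max Alignment E-value cutoff (inclusive).
#' @param detection_limit Metabolite detection limit for presence calls.
#' @param intact_mode `"any"` or `"both"` intact predicate for haustoria
#'   genes.
#' @param zero_is_missing Collapse measured zeros into missing on read.
#' @param aggregation Replicate aggregation, `"mean"` or `"median"`.
#' @param network_samples `"chimera"` (default: correlate across THC + PC
#'   replicates, where haustoria features are defined) or `"all"`.
#' @param n_orthogonal Orthogonal OPLS-DA components.
#' @param network_adjust `"none"` or `"BH"` for network p-values.
#' @param seed Seed forwarded to any simulation step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vip_min = 1, fc_min = 1, fpkm_min = 3,
                            fpkm_intact_max = 0.3, pcc_min = 0.80,
                            p_max = 0.05, evalue_max = 1e-10,
                            detection_limit = 0,
                            intact_mode = "any",
                            zero_is_missing = FALSE,
                            aggregation = "mean",
                            network_samples = "chimera",
                            n_orthogonal = 1L,
                            network_adjust = "none",
                            seed = 1L) {
  cfg <- as.list(environment())
  pos <- c("vip_min", "fc_min", "fpkm_min", "fpkm_intact_max", "pcc_min",
           "p_max", "evalue_max")
  bad <- pos[vapply(cfg[pos], function(x) !is.numeric(x) || x <= 0,
                    logical(1L))]
  if (length(bad)) stop("threshold must be positive: ", bad[1L])
  stopifnot(intact_mode %in% c("any", "both"),
            aggregation %in% c("mean", "median"),
            network_samples %in% c("chimera", "all"),
            network_adjust %in% c("none", "BH"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes differential-metabolite screening, transferred-metabolite and
#' mobile-gene classification, haustoria gene selection and the
#' gene-metabolite correlation network, and returns a run report of
#' per-stage counts. Identical inputs and configuration give an identical
#' report and (when `out_dir` is set) byte-identical output files.
#'
#' @param genes Gene [feature_table] (FPKM).
#' @param metabolites Metabolite [feature_table] (intensities).
#' @param config A [pipeline_config].
#' @param origin_calls Optional origin table ([assign_from_hits()] /
#'   [kmer_assign()]) used to pre-filter mobile-gene candidates.
#' @param out_dir Optional output directory; stage tables are written as
#'   TSV (plus SIF for the network). On error, partial outputs are
#'   removed.
#' @return List of class `run_report`: per-stage counts (`n_dams` per
#'   comparison, `n_common_dams`, `n_transferred` by direction,
#'   `n_mobile` by direction, `n_haustoria_genes`, `n_edges`), the stage
#'   result tables, and output paths when written.
#' @export
run_pipeline <- function(genes, metabolites, config = pipeline_config(),
                         origin_calls = NULL, out_dir = NULL) {
  stopifnot(is_feature_table(genes), is_feature_table(metabolites))
  written <- character(0)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on_fail <- function(stage) function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }

  ## stage 1: DAM screen on both chimera comparisons
  res <- tryCatch({
    dams_th <- screen_dams(metabolites, c("TH", "THC"),
                           vip_min = config$vip_min,
                           fc_min = config$fc_min,
                           n_orthogonal = config$n_orthogonal,
                           aggregate = config$aggregation)
    dams_p <- screen_dams(metabolites, c("P", "PC"),
                          vip_min = config$vip_min,
                          fc_min = config$fc_min,
                          n_orthogonal = config$n_orthogonal,
                          aggregate = config$aggregation)
    coreg <- coregulation_classes(dams_th, dams_p)
    list(dams_th = dams_th, dams_p = dams_p, coreg = coreg)
  }, error = on_fail("dam_screen"))
  emit(res$dams_th, "dams_TH_vs_THC.tsv")
  emit(res$dams_p, "dams_P_vs_PC.tsv")
  emit(res$coreg, "common_dams.tsv")

  ## stage 2: mobility classification
  mob <- tryCatch({
    transfer <- classify_transfer(metabolites,
                                  detection_limit = config$detection_limit)
    mobile <- detect_mobile_genes(genes, fpkm_min = config$fpkm_min,
                                  origin_calls = origin_calls,
                                  aggregate = config$aggregation)
    list(transfer = transfer, mobile = mobile)
  }, error = on_fail("mobility"))
  emit(mob$transfer[mob$transfer$direction != "none", ],
       "transferred_metabolites.tsv")
  emit(mob$mobile[mob$mobile$direction != "none", ], "mobile_genes.tsv")

  ## stage 3: haustoria genes + correlation network
  net <- tryCatch({
    haus <- select_haustoria_genes(genes,
                                   fpkm_intact_max = config$fpkm_intact_max,
                                   intact_mode = config$intact_mode,
                                   fc_min = config$fc_min)
    haus_ids <- haus$feature_id[haus$qualifies]
    met_ids <- res$coreg$feature_id
    edges <- if (length(haus_ids) && length(met_ids)) {
      shared <- intersect(sample_ids(genes), sample_ids(metabolites))
      samples <- if (config$network_samples == "chimera")
        shared[genes$compartments[shared] %in% c("THC", "PC")]
      else shared
      suppressWarnings(pearson_network(
        ft_subset(genes, features = haus_ids),
        ft_subset(metabolites, features = met_ids),
        samples = samples, pcc_min = config$pcc_min,
        p_max = config$p_max, adjust = config$network_adjust))
    } else {
      data.frame(gene_id = character(), metabolite_id = character(),
                 pcc = numeric(), p_value = numeric(),
                 sign = character())
    }
    list(haus = haus, edges = edges)
  }, error = on_fail("haustoria_network"))
  emit(net$haus[net$haus$qualifies, ], "haustoria_genes.tsv")
  if (!is.null(out_dir)) {
    write_edge_table(net$edges, file.path(out_dir, "network_edges.tsv"),
                     "edge_tsv")
    write_edge_table(net$edges, file.path(out_dir, "network.sif"), "sif")
    written <- c(written, file.path(out_dir, c("network_edges.tsv",
                                               "network.sif")))
  }

  report <- list(
    n_genes = nrow(genes$values),
    n_metabolites = nrow(metabolites$values),
    n_dams = list(
      TH_vs_THC = sum(res$dams_th$regulation != "not_significant"),
      P_vs_PC = sum(res$dams_p$regulation != "not_significant")),
    n_common_dams = nrow(res$coreg),
    n_transferred = list(
      host_to_parasite = sum(mob$transfer$direction == "host_to_parasite"),
      parasite_to_host = sum(mob$transfer$direction == "parasite_to_host")),
    n_mobile = list(
      th_to_p = sum(mob$mobile$direction == "th_to_p"),
      p_to_th = sum(mob$mobile$direction == "p_to_th")),
    n_haustoria_genes = sum(net$haus$qualifies),
    n_edges = nrow(net$edges),
    tables = list(dams_th = res$dams_th, dams_p = res$dams_p,
                  common_dams = res$coreg, transfer = mob$transfer,
                  mobile = mob$mobile, haustoria = net$haus,
                  edges = net$edges),
    outputs = written)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  features: %d genes, %d metabolites\n",
              x$n_genes, x$n_metabolites))
  cat(sprintf("  DAMs: %d (TH vs THC), %d (P vs PC); common: %d\n",
              x$n_dams$TH_vs_THC, x$n_dams$P_vs_PC, x$n_common_dams))
  cat(sprintf("  transferred metabolites: %d host->parasite, %d parasite->host\n",
              x$n_transferred$host_to_parasite,
              x$n_transferred$parasite_to_host))
  cat(sprintf("  mobile genes: %d th->p, %d p->th\n",
              x$n_mobile$th_to_p, x$n_mobile$p_to_th))
  cat(sprintf("  haustoria genes: %d; network edges: %d\n",
              x$n_haustoria_genes, x$n_edges))
  invisible(x)
}

#' Serialise a run report's counts as JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(report, path) {
  counts <- report[c("n_genes", "n_metabolites", "n_dams",
                     "n_common_dams", "n_transferred", "n_mobile",
                     "n_haustoria_genes", "n_edges")]
  jsonlite::write_json(counts, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
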