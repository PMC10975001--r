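#' Parameters of the synthetic four-compartment experiment
#'
#' Defaults mirror the study design being emulated: four compartments
#' (TH, THC, PC, P) with three biological replicates each; 44 + 6 mobile
#' genes, 4 + 1 transferred metabolites, 56 common differentially
#' accumulated metabolites and a planted four-fold effect size.
#' Abundance scales match the printed data: metabolite peak intensities
#' around `exp(10)` (tens of thousands) and gene FPKM around
#' `exp(gene_log_mean)` (tens to hundreds).
#'
#' @param n_genes,n_metabolites Total feature counts (planted features
#'   included).
#' @param n_reps_per_compartment Biological replicates per compartment
#'   (>= 2; default 3).
#' @param n_mobile_th_to_p,n_mobile_p_to_th Planted mobile genes per
#'   direction (defaults 44 and 6).
#' @param n_transferred_host_to_parasite,n_transferred_parasite_to_host
#'   Planted transferred metabolites per direction (defaults 4 and 1).
#' @param n_haustoria_genes Planted haustoria-formation genes
#'   (default 20).
#' @param n_common_dams Metabolites planted as differential in both
#'   chimera comparisons (default 56).
#' @param n_correlated_pairs Gene-metabolite pairs sharing a latent
#'   factor across the chimera replicates (default 10). Pair members are
#'   dedicated features with equal means in all four compartments, so
#'   they trigger no other classifier; see the methods vignette for why
#'   they are not stacked onto the haustoria genes.
#' @param base_abundance_log_mean,log_sd Log-normal location/scale of
#'   metabolite base intensity (defaults 10 and 1).
#' @param gene_log_mean Log-normal location of expressed gene FPKM
#'   (default `log(50)`).
#' @param noise_cv Multiplicative replicate noise, coefficient of
#'   variation in (0, 1) (default 0.05).
#' @param detection_limit Metabolite intensity below which a cell is
#'   censored to missing (default 100; must be positive when transferred
#'   metabolites are planted).
#' @param fold_change_planted Planted fold change (> 1, default 4: twice
#'   the DAM |log2FC| >= 1 margin).
#' @param latent_effect Relative amplitude of the shared latent factor in
#'   correlated pairs (default 0.35, giving population |r| around 0.97).
#' @param genome_length Length of each synthetic reference genome
#'   (default 20000).
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 1000L, n_metabolites = 300L,
                       n_reps_per_compartment = 3L,
                       n_mobile_th_to_p = 44L, n_mobile_p_to_th = 6L,
                       n_transferred_host_to_parasite = 4L,
                       n_transferred_parasite_to_host = 1L,
                       n_haustoria_genes = 20L, n_common_dams = 56L,
                       n_correlated_pairs = 10L,
                       base_abundance_log_mean = 10, log_sd = 1,
                       gene_log_mean = log(50), noise_cv = 0.05,
                       detection_limit = 100, fold_change_planted = 4,
                       latent_effect = 0.35, genome_length = 20000L,
                       seed = 1L) {
  p <- as.list(environment())
  counts <- c("n_genes", "n_metabolites", "n_reps_per_compartment",
              "n_mobile_th_to_p", "n_mobile_p_to_th",
              "n_transferred_host_to_parasite",
              "n_transferred_parasite_to_host", "n_haustoria_genes",
              "n_common_dams", "n_correlated_pairs", "genome_length")
  for (nm in counts) p[[nm]] <- as.integer(p[[nm]])
  if (p$n_reps_per_compartment < 2L)
    stop("n_reps_per_compartment must be >= 2")
  if (p$noise_cv <= 0 || p$noise_cv >= 1)
    stop("noise_cv must be in (0, 1)")
  if (p$fold_change_planted <= 1)
    stop("fold_change_planted must be > 1")
  if (p$log_sd <= 0 || p$detection_limit < 0)
    stop("scales must be positive")
  n_planted_genes <- p$n_mobile_th_to_p + p$n_mobile_p_to_th +
    p$n_haustoria_genes + p$n_correlated_pairs
  if (n_planted_genes > p$n_genes)
    stop("planted gene counts exceed n_genes")
  n_planted_mets <- p$n_transferred_host_to_parasite +
    p$n_transferred_parasite_to_host + p$n_common_dams +
    p$n_correlated_pairs
  if (n_planted_mets > p$n_metabolites)
    stop("planted metabolite counts exceed n_metabolites")
  if (p$detection_limit <= 0 &&
      (p$n_transferred_host_to_parasite +
         p$n_transferred_parasite_to_host) > 0L)
    stop("planted transferred metabolites need detection_limit > 0")
  structure(p, class = "sim_params")
}

#' Generate a synthetic four-compartment experiment with known truth
#'
#' Produces a gene FPKM table and a metabolite intensity table over the
#' four compartments, two synthetic reference genomes with unigene
#' sequences sampled verbatim from them (random orientation), and the
#' planted ground truth. Background abundances are log-normal with
#' multiplicative replicate noise of coefficient of variation
#' `noise_cv`; planted features are placed with at least a two-fold
#' margin on every decision threshold (mobile genes: present means
#' >= 2 x 3 FPKM, absent <= 1.5; haustoria genes: intact means below
#' 0.15, chimera means strongly upregulated; transferred metabolites:
#' censored below the detection limit in exactly one intact
#' compartment). Metabolite cells below `detection_limit` are emitted as
#' missing; gene FPKM is never censored. Identical parameters (including
#' the seed) give identical output.
#'
#' @param params A [sim_params] object.
#' @return List with elements `genes` and `metabolites`
#'   ([feature_table]s), `genomes` (named list `parasite_ref`,
#'   `host_ref`), `unigenes` (named character vector of sequences) and
#'   `truth` (planted ground truth: `mobile_genes`,
#'   `transferred_metabolites`, `haustoria_genes`, `dam_up` / `dam_down`
#'   per comparison, `correlated_pairs`, `gene_origin`).
#' @export
generate_experiment <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  p <- params
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(p$seed)

  reps <- p$n_reps_per_compartment
  samples <- paste(rep(COMPARTMENTS, each = reps), seq_len(reps),
                   sep = "_")
  comps <- rep(COMPARTMENTS, each = reps)
  names(comps) <- samples
  sd_noise <- sqrt(log(1 + p$noise_cv^2))

  gene_ids <- sprintf("gene_%04d", seq_len(p$n_genes))
  met_ids <- sprintf("met_%04d", seq_len(p$n_metabolites))

  ## ---- gene role assignment (disjoint planted blocks, then background)
  idx <- seq_len(p$n_genes)
  i_haus <- utils::head(idx, p$n_haustoria_genes)
  idx <- setdiff(idx, i_haus)
  i_thp <- utils::head(idx, p$n_mobile_th_to_p)
  idx <- setdiff(idx, i_thp)
  i_pth <- utils::head(idx, p$n_mobile_p_to_th)
  idx <- setdiff(idx, i_pth)
  i_corr_g <- utils::head(idx, p$n_correlated_pairs)
  i_bg <- setdiff(idx, i_corr_g)
  # background origin alternates so both genomes are represented
  bg_parasite <- i_bg[seq_along(i_bg) %% 2L == 1L]
  bg_host <- setdiff(i_bg, bg_parasite)

  fpkm_min <- 3
  expressed <- function(n) pmax(stats::rlnorm(n, p$gene_log_mean,
                                              p$log_sd), 2 * fpkm_min)
  low <- function(n) pmin(stats::rlnorm(n, log(0.1), 0.5), fpkm_min / 2)
  silent <- function(n) pmin(stats::rlnorm(n, log(0.05), 0.3), 0.15)

  gmeans <- matrix(0, p$n_genes, 4L,
                   dimnames = list(gene_ids, COMPARTMENTS))
  gmeans[bg_parasite, c("TH", "THC")] <- expressed(length(bg_parasite))
  gmeans[bg_parasite, c("PC", "P")] <- low(length(bg_parasite))
  gmeans[bg_host, c("PC", "P")] <- expressed(length(bg_host))
  gmeans[bg_host, c("TH", "THC")] <- low(length(bg_host))
  # mobile genes keep chimera == matching intact mean so they never look
  # chimera-upregulated; the across-species compartment sits lower, near
  # the presence threshold (cf. the printed mobile-gene tables)
  near_thresh <- function(n) pmax(stats::rlnorm(n, log(10), 0.5),
                                  2 * fpkm_min)
  gmeans[i_thp, c("TH", "THC")] <- expressed(length(i_thp))
  gmeans[i_thp, "PC"] <- near_thresh(length(i_thp))
  gmeans[i_thp, "P"] <- low(length(i_thp))
  gmeans[i_pth, c("PC", "P")] <- expressed(length(i_pth))
  gmeans[i_pth, "THC"] <- near_thresh(length(i_pth))
  gmeans[i_pth, "TH"] <- low(length(i_pth))
  gmeans[i_haus, "TH"] <- silent(length(i_haus))
  gmeans[i_haus, "P"] <- silent(length(i_haus))
  haus_expr <- pmax(stats::rlnorm(length(i_haus), log(20), p$log_sd / 2),
                    2)
  gmeans[i_haus, "THC"] <- haus_expr
  gmeans[i_haus, "PC"] <- haus_expr   # equal chimera means: haustoria
                                      # genes stay mutually independent
  # latent-pair genes are flat across all four compartments, so the
  # latent variance cannot disturb any threshold classifier
  gmeans[i_corr_g, ] <- expressed(length(i_corr_g))

  ## ---- metabolite role assignment
  idx <- seq_len(p$n_metabolites)
  i_dam <- utils::head(idx, p$n_common_dams)
  idx <- setdiff(idx, i_dam)
  i_h2p <- utils::head(idx, p$n_transferred_host_to_parasite)
  idx <- setdiff(idx, i_h2p)
  i_p2h <- utils::head(idx, p$n_transferred_parasite_to_host)
  idx <- setdiff(idx, i_p2h)
  i_corr_m <- utils::head(idx, p$n_correlated_pairs)  # flat metabolites
  i_mbg <- setdiff(idx, i_corr_m)

  mbase <- pmax(stats::rlnorm(p$n_metabolites, p$base_abundance_log_mean,
                              p$log_sd), 4 * p$detection_limit)
  mmeans <- matrix(mbase, p$n_metabolites, 4L,
                   dimnames = list(met_ids, COMPARTMENTS))
  f <- p$fold_change_planted
  # common DAMs cycle through the four co-regulation classes
  dam_types <- c("up/up", "down/down", "up/down", "down/up")
  types <- rep(dam_types, length.out = length(i_dam))
  for (j in seq_along(i_dam)) {
    tp <- strsplit(types[j], "/", fixed = TRUE)[[1L]]
    i <- i_dam[j]
    mmeans[i, "THC"] <- if (tp[1L] == "up") mmeans[i, "TH"] * f else
      mmeans[i, "TH"] / f
    mmeans[i, "PC"] <- if (tp[2L] == "up") mmeans[i, "P"] * f else
      mmeans[i, "P"] / f
  }
  for (i in i_h2p) {                  # absent in TH, present elsewhere
    mmeans[i, "TH"] <- p$detection_limit / 10
  }
  for (i in i_p2h) {                  # absent in P, present elsewhere
    mmeans[i, "P"] <- p$detection_limit / 10
  }

  ## ---- replicate noise + latent factors
  noise <- function(n) exp(stats::rnorm(n, 0, sd_noise))
  gvals <- gmeans[, comps, drop = FALSE] *
    matrix(noise(p$n_genes * length(samples)), p$n_genes)
  mvals <- mmeans[, comps, drop = FALSE] *
    matrix(noise(p$n_metabolites * length(samples)), p$n_metabolites)
  colnames(gvals) <- colnames(mvals) <- samples

  chim <- samples[comps %in% c("THC", "PC")]
  pair_sign <- character(0)
  if (p$n_correlated_pairs > 0L) {
    pair_sign <- rep(c("pos", "neg"), length.out = p$n_correlated_pairs)
    for (j in seq_len(p$n_correlated_pairs)) {
      z <- stats::rnorm(length(chim))
      s <- if (pair_sign[j] == "pos") 1 else -1
      gvals[i_corr_g[j], chim] <- gvals[i_corr_g[j], chim] *
        pmax(1 + p$latent_effect * z, 0.05)
      mvals[i_corr_m[j], chim] <- mvals[i_corr_m[j], chim] *
        pmax(1 + s * p$latent_effect * z, 0.05)
    }
  }

  mvals[mvals < p$detection_limit] <- NA_real_

  gene_origin <- rep(NA_character_, p$n_genes)
  gene_origin[c(bg_parasite, i_thp, i_haus, i_corr_g)] <- "parasite_ref"
  gene_origin[c(bg_host, i_pth)] <- "host_ref"
  names(gene_origin) <- gene_ids

  genomes <- list(
    parasite_ref = random_genome(p$genome_length),
    host_ref = random_genome(p$genome_length))
  unigenes <- vapply(gene_ids, function(g) {
    sample_unigene(genomes[[gene_origin[[g]]]])
  }, character(1L))

  truth <- list(
    mobile_genes = stats::setNames(
      c(rep("th_to_p", length(i_thp)), rep("p_to_th", length(i_pth))),
      gene_ids[c(i_thp, i_pth)]),
    transferred_metabolites = stats::setNames(
      c(rep("host_to_parasite", length(i_h2p)),
        rep("parasite_to_host", length(i_p2h))),
      met_ids[c(i_h2p, i_p2h)]),
    haustoria_genes = gene_ids[i_haus],
    dam_up = list(
      TH_vs_THC = met_ids[i_dam[startsWith(types, "up")]],
      P_vs_PC = met_ids[i_dam[endsWith(types, "up")]]),
    dam_down = list(
      TH_vs_THC = met_ids[i_dam[startsWith(types, "down")]],
      P_vs_PC = met_ids[i_dam[endsWith(types, "down")]]),
    common_dam_types = stats::setNames(types, met_ids[i_dam]),
    correlated_pairs = data.frame(
      gene_id = gene_ids[i_corr_g],
      metabolite_id = met_ids[i_corr_m],
      sign = pair_sign, stringsAsFactors = FALSE),
    gene_origin = gene_origin)

  list(genes = feature_table(gvals, comps, "gene"),
       metabolites = feature_table(mvals, comps, "metabolite"),
       genomes = genomes, unigenes = unigenes, truth = truth)
}

random_genome <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")

# verbatim substring of the source genome, randomly reverse-complemented
sample_unigene <- function(genome, min_len = 300L, max_len = 1000L) {
  len <- sample(seq(min_len, max_len), 1L)
  start <- sample(nchar(genome) - len + 1L, 1L)
  s <- substring(genome, start, start + len - 1L)
  if (stats::runif(1) < 0.5)
    s <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
  s
}

#' Write a synthetic experiment to disk
#'
#' Writes the two feature tables with a shared sample map, the two
#' reference genomes and the unigene FASTA, and the ground truth as JSON.
#'
#' @param experiment Output of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes_fpkm.tsv"),
             metabolites = file.path(dir, "metabolite_intensity.tsv"),
             samples = file.path(dir, "samples.tsv"),
             parasite = file.path(dir, "genome_parasite.fa"),
             host = file.path(dir, "genome_host.fa"),
             unigenes = file.path(dir, "unigenes.fa"),
             truth = file.path(dir, "truth.json"))
  write_feature_table(experiment$genes, paths[["genes"]])
  write_feature_table(experiment$metabolites, paths[["metabolites"]])
  write_sample_map(experiment$genes, paths[["samples"]])
  write_fasta(c(parasite_ref = experiment$genomes$parasite_ref),
              paths[["parasite"]])
  write_fasta(c(host_ref = experiment$genomes$host_ref), paths[["host"]])
  write_fasta(experiment$unigenes, paths[["unigenes"]])
  truth <- experiment$truth
  truth$mobile_genes <- as.list(truth$mobile_genes)
  truth$transferred_metabolites <- as.list(truth$transferred_metabolites)
  truth$common_dam_types <- as.list(truth$common_dam_types)
  truth$gene_origin <- as.list(truth$gene_origin)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
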