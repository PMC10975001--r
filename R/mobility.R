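#' Classify transferred metabolites from four-compartment presence
#'
#' A metabolite is *transferred* when it is undetected in exactly one of
#' the two intact compartments but detected in the other three samples:
#' absent in `TH` (intact parasite) with presence elsewhere implies
#' movement from host to parasite; absent in `P` (intact host) implies
#' the opposite direction. Any other presence pattern gives `none`.
#'
#' Presence in a compartment requires detection (non-missing intensity
#' strictly above `detection_limit`) in at least `min_detect_reps`
#' replicates; the default demands every replicate, which makes absence
#' calls conservative.
#'
#' @param ft A metabolite [feature_table] covering all four compartments.
#' @param detection_limit Intensity at or below which a cell counts as
#'   undetected (default 0; missing cells always count as undetected).
#' @param min_detect_reps Replicates that must be detected for presence;
#'   default all replicates of the compartment.
#' @return `data.frame` with one row per metabolite: `feature_id`,
#'   `direction` (`host_to_parasite`, `parasite_to_host`, `none`),
#'   presence booleans `present_th/thc/pc/p`, and per-compartment mean
#'   intensities (`NA` when nothing was detected).
#' @export
classify_transfer <- function(ft, detection_limit = 0,
                              min_detect_reps = NULL) {
  missing_comp <- setdiff(COMPARTMENTS, unique(ft$compartments))
  if (length(missing_comp))
    stop("compartment missing from table: ", missing_comp[1L])
  v <- ft$values
  detected <- !is.na(v) & v > detection_limit
  pres <- vapply(COMPARTMENTS, function(cc) {
    idx <- ft$compartments == cc
    need <- if (is.null(min_detect_reps)) sum(idx) else
      min(min_detect_reps, sum(idx))
    rowSums(detected[, idx, drop = FALSE]) >= need
  }, logical(nrow(v)))
  if (nrow(v) == 1L) pres <- matrix(pres, 1L,
                                    dimnames = list(rownames(v),
                                                    COMPARTMENTS))
  means <- vapply(COMPARTMENTS, function(cc) {
    m <- rowMeans(v[, ft$compartments == cc, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) means <- matrix(means, 1L,
                                     dimnames = list(rownames(v),
                                                     COMPARTMENTS))
  direction <- rep("none", nrow(v))
  direction[!pres[, "TH"] & pres[, "THC"] & pres[, "PC"] & pres[, "P"]] <-
    "host_to_parasite"
  direction[pres[, "TH"] & pres[, "THC"] & pres[, "PC"] & !pres[, "P"]] <-
    "parasite_to_host"
  data.frame(feature_id = rownames(v) %||% character(0),
             direction = direction,
             present_th = pres[, "TH"], present_thc = pres[, "THC"],
             present_pc = pres[, "PC"], present_p = pres[, "P"],
             mean_th = means[, "TH"], mean_thc = means[, "THC"],
             mean_pc = means[, "PC"], mean_p = means[, "P"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect mobile genes from four-compartment FPKM thresholds
#'
#' A transcript is called mobile from parasite to host (`th_to_p`) when
#' its mean FPKM is below `fpkm_min` in the intact host (`P`) but at or
#' above `fpkm_min` in the other three compartments — the transcript of
#' parasite origin detected inside the host chimera. The symmetric
#' pattern (below threshold only in intact parasite `TH`) gives
#' `p_to_th`. The presence boundary is inclusive: a compartment mean of
#' exactly `fpkm_min` counts as present.
#'
#' @param ft A gene [feature_table] covering all four compartments.
#' @param fpkm_min Presence threshold on compartment-mean FPKM
#'   (default 3).
#' @param origin_calls Optional origin table ([assign_from_hits()] /
#'   [kmer_assign()]); when supplied, only genes with an unambiguous
#'   genome assignment (`parasite_ref` or `host_ref`) are considered.
#' @param aggregate Replicate aggregation, `"mean"` (default) or
#'   `"median"`; missing cells count as 0.
#' @return `data.frame`: `feature_id`, `direction` (`th_to_p`,
#'   `p_to_th`, `none`), per-compartment FPKM summaries
#'   `fpkm_th/thc/pc/p`, and `origin` (assigned genome or `NA`).
#' @export
detect_mobile_genes <- function(ft, fpkm_min = 3, origin_calls = NULL,
                                aggregate = "mean") {
  missing_comp <- setdiff(COMPARTMENTS, unique(ft$compartments))
  if (length(missing_comp))
    stop("compartment missing from table: ", missing_comp[1L])
  origin <- rep(NA_character_, nrow(ft$values))
  names(origin) <- feature_ids(ft)
  if (!is.null(origin_calls)) {
    ok <- origin_calls$assigned_genome %in% c("parasite_ref", "host_ref")
    keep <- intersect(feature_ids(ft), origin_calls$query_id[ok])
    ft <- ft_subset(ft, features = keep)
    origin <- stats::setNames(
      origin_calls$assigned_genome[match(keep, origin_calls$query_id)],
      keep)
  }
  m <- compartment_means(ft, fun = aggregate)
  present <- m >= fpkm_min
  direction <- rep("none", nrow(m))
  direction[present[, "TH"] & present[, "THC"] & present[, "PC"] &
              !present[, "P"]] <- "th_to_p"
  direction[!present[, "TH"] & present[, "THC"] & present[, "PC"] &
              present[, "P"]] <- "p_to_th"
  data.frame(feature_id = rownames(m) %||% character(0),
             direction = direction,
             fpkm_th = m[, "TH"], fpkm_thc = m[, "THC"],
             fpkm_pc = m[, "PC"], fpkm_p = m[, "P"],
             origin = unname(origin[rownames(m)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
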