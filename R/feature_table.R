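#' Compartment labels of the four-group design
#'
#' The sampling design has four root compartments: `TH` (intact parasite),
#' `THC` (parasite chimera from the symbiotic root system), `PC` (host
#' chimera) and `P` (intact host).
#'
#' @format Character vector of length four, in fixed order `TH, THC, PC, P`.
#' @export
COMPARTMENTS <- c("TH", "THC", "PC", "P")

#' Table dialect for delimited feature tables
#'
#' @param sep Field separator (default tab).
#' @param missing Character markers parsed as missing cells.
#' @param missing_out Marker emitted for missing cells on write.
#' @param zero_is_missing If `TRUE`, a measured `0` is collapsed into
#'   missing on read. Default `FALSE`: `0` is a measured zero, distinct
#'   from an undetected (missing) cell.
#'
#' @details Thousands separators (`"35,397"`) are accepted on input and
#'   never emitted.
#' @return A list of class `table_dialect`.
#' @export
table_dialect <- function(sep = "\t", missing = c("", "NA", "-"),
                          missing_out = "NA", zero_is_missing = FALSE) {
  structure(list(sep = sep, missing = missing, missing_out = missing_out,
                 zero_is_missing = isTRUE(zero_is_missing)),
            class = "table_dialect")
}

#' Construct a feature abundance table
#'
#' A `feature_table` holds a features x samples matrix of non-negative
#' abundances (raw MS peak intensity for metabolites, FPKM for genes),
#' a sample -> compartment map over the four-compartment design, and
#' optional per-feature metadata.
#'
#' @param values Numeric matrix, features in rows, samples in columns;
#'   `NA` encodes an undetected (missing) cell. Row and column names are
#'   required and must be unique.
#' @param compartments Character vector (or factor) of length
#'   `ncol(values)`, each one of [COMPARTMENTS]; may be named by sample id.
#' @param kind `"metabolite"` or `"gene"`.
#' @param meta Optional `data.frame` of per-feature annotation keyed by
#'   `feature_id` (e.g. compound category).
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, compartments,
                          kind = c("metabolite", "gene"), meta = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  fid <- rownames(values)
  if (is.null(fid) && nrow(values) == 0L) fid <- character(0)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("values must have feature row names and sample column names")
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  compartments <- stats::setNames(as.character(compartments),
                                  names(compartments))
  if (!is.null(names(compartments))) {
    miss <- setdiff(sid, names(compartments))
    if (length(miss))
      stop("sample without compartment mapping: ", miss[1L])
    compartments <- compartments[sid]
  }
  if (length(compartments) != length(sid))
    stop("need one compartment per sample")
  bad <- setdiff(unique(compartments), COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment label: ", bad[1L])
  if (any(values < 0, na.rm = TRUE))
    stop("negative abundance value in table")
  names(compartments) <- sid
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"feature_id" %in% names(meta))
      stop("meta must contain a feature_id column")
  }
  structure(list(values = values, compartments = compartments,
                 kind = kind, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$compartments, levels = COMPARTMENTS))
  cat("  samples per compartment:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  missing cells:", n_na, "\n")
  invisible(x)
}

#' @rdname feature_table
#' @param x An object.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

#' @export
dim.feature_table <- function(x) dim(x$values)

feature_ids <- function(ft) rownames(ft$values)
sample_ids <- function(ft) colnames(ft$values)

#' Subset a feature table by feature and/or sample
#'
#' @param ft A [feature_table].
#' @param features Optional character vector of feature ids to keep
#'   (order respected).
#' @param samples Optional character vector of sample ids to keep.
#' @return A [feature_table].
#' @export
ft_subset <- function(ft, features = NULL, samples = NULL) {
  v <- ft$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    if (length(miss)) stop("unknown feature id: ", miss[1L])
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss)) stop("unknown sample id: ", miss[1L])
    v <- v[, samples, drop = FALSE]
  }
  feature_table(v, ft$compartments[colnames(v)], ft$kind, ft$meta)
}

#' Per-compartment replicate aggregation
#'
#' Aggregates replicate samples within each compartment. Missing cells are
#' treated as zero before aggregation (undetected implies abundance below
#' the detection limit, hence effectively zero for group summaries).
#'
#' @param ft A [feature_table].
#' @param fun Aggregation: `"mean"` (default) or `"median"`.
#' @param na_as_zero Replace missing with 0 before aggregating
#'   (default `TRUE`).
#' @return Numeric matrix, features x the compartments present in `ft`
#'   (ordered as in [COMPARTMENTS]).
#' @export
compartment_means <- function(ft, fun = c("mean", "median"),
                              na_as_zero = TRUE) {
  fun <- match.arg(fun)
  v <- ft$values
  if (na_as_zero) v[is.na(v)] <- 0
  comps <- intersect(COMPARTMENTS, unique(ft$compartments))
  f <- if (fun == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  out <- vapply(comps, function(cc) {
    f(v[, ft$compartments == cc, drop = FALSE])
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1L, dimnames =
                                     list(rownames(v), comps))
  if (nrow(v) == 0L) out <- matrix(0, 0L, length(comps),
                                   dimnames = list(NULL, comps))
  out
}

parse_abundance <- function(x, dialect) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  is_missing <- x %in% dialect$missing
  num <- suppressWarnings(as.numeric(gsub(",", "", x[!is_missing],
                                          fixed = TRUE)))
  if (anyNA(num))
    stop("non-numeric abundance value: ",
         x[!is_missing][which(is.na(num))[1L]])
  out[!is_missing] <- num
  if (dialect$zero_is_missing) out[!is.na(out) & out == 0] <- NA_real_
  out
}

#' Read a delimited feature table
#'
#' First column holds the feature id, the header row holds sample ids.
#' Missing cells are parsed per the dialect; thousands separators are
#' stripped.
#'
#' @param path Path to a delimited text file.
#' @param sample_map Either a named character vector `sample_id ->
#'   compartment`, or the path of a two-column (sample, compartment)
#'   delimited file with or without header.
#' @param kind `"metabolite"` or `"gene"`.
#' @param dialect A [table_dialect].
#' @param meta_cols Character vector of column names to divert into
#'   `meta` rather than the abundance matrix (e.g. `"category"`).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, sample_map,
                               kind = c("metabolite", "gene"),
                               dialect = table_dialect(),
                               meta_cols = NULL) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, sep = dialect$sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, strip.white = TRUE)
  if (ncol(raw) < 1L) stop("empty table: ", path)
  fid <- raw[[1L]]
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  meta <- NULL
  if (!is.null(meta_cols) && length(meta_cols)) {
    keep <- intersect(meta_cols, names(raw))
    meta <- cbind(data.frame(feature_id = fid, stringsAsFactors = FALSE),
                  raw[keep])
    raw <- raw[setdiff(names(raw), keep)]
  }
  sid <- names(raw)[-1L]
  vals <- vapply(raw[-1L], parse_abundance, numeric(length(fid)),
                 dialect = dialect)
  if (length(fid) == 1L) vals <- matrix(vals, nrow = 1L)
  if (length(fid) == 0L) vals <- matrix(numeric(0), 0L, length(sid))
  dimnames(vals) <- list(fid, sid)
  if (is.character(sample_map) && length(sample_map) == 1L &&
      is.null(names(sample_map)) && file.exists(sample_map))
    sample_map <- read_sample_map(sample_map)
  feature_table(vals, sample_map, kind, meta)
}

#' @rdname read_feature_table
#' @export
read_sample_map <- function(path) {
  sm <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          strip.white = TRUE)
  if (identical(tolower(sm[1L, 1L]), "sample")) sm <- sm[-1L, , drop = FALSE]
  if (ncol(sm) < 2L) stop("sample map needs two columns: ", path)
  stats::setNames(sm[[2L]], sm[[1L]])
}

#' Write a feature table as delimited text
#'
#' Inverse of [read_feature_table()]: `read(write(ft))` reproduces `ft`
#' exactly, including the position of missing cells. Thousands separators
#' are never emitted.
#'
#' @param ft A [feature_table].
#' @param path Output path.
#' @param dialect A [table_dialect]; missing cells are written as
#'   `dialect$missing_out`.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(ft, path, dialect = table_dialect()) {
  v <- ft$values
  chr <- matrix(vapply(v, function(x) {
    if (is.na(x)) dialect$missing_out else format(x, scientific = FALSE,
                                                  trim = TRUE, digits = 15)
  }, character(1L)), nrow = nrow(v), dimnames = dimnames(v))
  df <- cbind(data.frame(feature_id = rownames(v),
                         stringsAsFactors = FALSE),
              as.data.frame(chr, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
write_sample_map <- function(ft, path) {
  utils::write.table(
    data.frame(sample = sample_ids(ft),
               compartment = unname(ft$compartments)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
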