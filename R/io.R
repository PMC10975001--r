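#' Read BLAST tabular hits and filter by E-value
#'
#' Parses standard 12-column tabular alignment output (`-outfmt 6`:
#' query, subject, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore), maps each subject to a reference
#' genome, and drops hits above the E-value threshold. The threshold is
#' inclusive: a hit with `evalue == evalue_max` is retained.
#'
#' @param path Path to a tabular alignment file.
#' @param subject_map Named character vector `subject_id -> genome`, with
#'   genome one of `"parasite_ref"`, `"host_ref"`; or a two-column file.
#' @param evalue_max Maximum E-value retained (default `1e-10`).
#' @return A `data.frame` of origin hits with columns `query_id`,
#'   `subject_id`, `subject_genome`, `bitscore`, `evalue`.
#' @export
read_blast_tab <- function(path, subject_map, evalue_max = 1e-10) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (is.character(subject_map) && length(subject_map) == 1L &&
      is.null(names(subject_map)) && file.exists(subject_map))
    subject_map <- read_sample_map(subject_map)
  bad_genome <- setdiff(unique(subject_map), c("parasite_ref", "host_ref"))
  if (length(bad_genome))
    stop("subject map genome must be parasite_ref or host_ref, got: ",
         bad_genome[1L])
  if (!length(lines))
    return(data.frame(query_id = character(), subject_id = character(),
                      subject_genome = character(),
                      bitscore = numeric(), evalue = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("malformed alignment line ", which(nf != 12L)[1L],
         ": expected 12 fields, got ", nf[nf != 12L][1L])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  unmapped <- setdiff(unique(m[, 2L]), names(subject_map))
  if (length(unmapped))
    stop("unmapped subject id: ", unmapped[1L])
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     subject_genome = unname(subject_map[m[, 2L]]),
                     bitscore = as.numeric(m[, 12L]),
                     evalue = as.numeric(m[, 11L]),
                     stringsAsFactors = FALSE)
  if (anyNA(hits$evalue) || anyNA(hits$bitscore))
    stop("non-numeric evalue/bitscore in ", path)
  if (any(hits$evalue < 0)) stop("negative evalue in ", path)
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

#' Read a FASTA file as a named character vector
#'
#' Ids are the first whitespace-delimited token of each header; sequences
#' are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector `id -> sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ", ids[!nzchar(seqs)][1L])
  stats::setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param seqs Named character vector `id -> sequence`.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Export a gene-metabolite network edge set
#'
#' Writes either a tab-separated edge table (columns `source`, `target`,
#' `pcc`, `p_value`, `sign`) or a SIF file whose interaction word is the
#' correlation sign (`pos` / `neg`). Rows are ordered by (source, target)
#' lexicographically (C collation), so equal edge sets produce
#' byte-identical files.
#'
#' @param edges A `data.frame` of network edges as returned by
#'   [pearson_network()].
#' @param path Output path.
#' @param format `"edge_tsv"` or `"sif"`.
#' @return Invisibly, `path`.
#' @export
write_edge_table <- function(edges, path, format = c("edge_tsv", "sif")) {
  format <- match.arg(format)
  need <- c("gene_id", "metabolite_id", "pcc", "p_value", "sign")
  if (!all(need %in% names(edges)))
    stop("edges must have columns: ", paste(need, collapse = ", "))
  old <- Sys.getlocale("LC_COLLATE")
  Sys.setlocale("LC_COLLATE", "C")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  edges <- edges[order(edges$gene_id, edges$metabolite_id), , drop = FALSE]
  if (format == "edge_tsv") {
    out <- data.frame(source = edges$gene_id, target = edges$metabolite_id,
                      pcc = format(edges$pcc, digits = 15, trim = TRUE),
                      p_value = format(edges$p_value, digits = 15,
                                       trim = TRUE),
                      sign = edges$sign)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(sprintf("%s %s %s", edges$gene_id, edges$sign,
                       edges$metabolite_id), path)
  }
  invisible(path)
}
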