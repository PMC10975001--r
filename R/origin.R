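#' Assign unigenes to a source genome from alignment hits
#'
#' Per query, the best hit for each genome is chosen by bitscore
#' (tie-break: lower E-value, then subject id lexicographic), and the
#' query is assigned to the genome with the higher best bitscore. If the
#' two best bitscores differ by less than `tie_tol` the call is
#' `ambiguous`; a query with no retained hit is `unassigned`.
#'
#' @param hits Origin hits from [read_blast_tab()] (already E-value
#'   filtered).
#' @param queries Optional character vector of all query ids; queries
#'   without hits are reported as `unassigned`. Defaults to the queries
#'   present in `hits`.
#' @param tie_tol Bitscore difference below which both-genome hits are
#'   declared ambiguous.
#' @return `data.frame`: `query_id`, `assigned_genome` (`parasite_ref`,
#'   `host_ref`, `ambiguous`, `unassigned`), `score` (winning best
#'   bitscore; `NA` when unassigned), `margin` (best minus second-best;
#'   equals `score` when only one genome is hit).
#' @export
assign_from_hits <- function(hits, queries = NULL, tie_tol = 1e-6) {
  if (is.null(queries)) queries <- unique(hits$query_id)
  best_by_genome <- function(h) {
    # deterministic best hit: bitscore desc, evalue asc, subject id asc
    o <- order(-h$bitscore, h$evalue, h$subject_id, method = "radix")
    h[o[1L], ]
  }
  rows <- lapply(queries, function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    if (!nrow(h))
      return(data.frame(query_id = q, assigned_genome = "unassigned",
                        score = NA_real_, margin = NA_real_,
                        stringsAsFactors = FALSE))
    best <- lapply(split(h, h$subject_genome), best_by_genome)
    scores <- vapply(best, function(b) b$bitscore, numeric(1L))
    resolve_call(q, scores["parasite_ref"], scores["host_ref"], tie_tol)
  })
  do.call(rbind, rows)
}

resolve_call <- function(q, score_parasite, score_host, tie_tol) {
  sp <- if (is.na(score_parasite)) -Inf else score_parasite
  sh <- if (is.na(score_host)) -Inf else score_host
  if (is.finite(sp) && is.finite(sh)) {
    margin <- abs(sp - sh)
    assigned <- if (margin < tie_tol) "ambiguous" else
      if (sp > sh) "parasite_ref" else "host_ref"
    score <- max(sp, sh)
  } else {
    assigned <- if (is.finite(sp)) "parasite_ref" else "host_ref"
    score <- max(sp, sh)
    margin <- score
  }
  data.frame(query_id = q, assigned_genome = assigned, score = score,
             margin = margin, stringsAsFactors = FALSE)
}

#' Assign unigenes to a source genome by canonical k-mer containment
#'
#' Desk-scale alternative to alignment-based origin filtering. Each
#' query's canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement, so orientation does not matter) are looked up in
#' the canonical k-mer set of each reference genome; the score is the
#' contained fraction in `[0, 1]`. Assignment and ambiguity follow
#' [assign_from_hits()] with containment in place of bitscore; a query
#' whose best score is below `min_score` is `unassigned`.
#'
#' @param unigenes Named character vector `id -> sequence`
#'   (see [read_fasta()]).
#' @param genome_parasite,genome_host Reference genome sequences
#'   (character, one string each or named vectors of contigs).
#' @param k Odd k-mer size in `[11, 31]` (default 21: long enough for
#'   specificity between diverged plant genomes, short enough to tolerate
#'   about 1% sequence divergence).
#' @param min_score Containment below which a query is unassigned
#'   (default 0.5).
#' @param tie_tol Containment difference declaring a tie (default 1e-6).
#' @return As [assign_from_hits()]. Queries shorter than `k` are
#'   `unassigned` with a warning and `NA` score.
#' @export
kmer_assign <- function(unigenes, genome_parasite, genome_host, k = 21L,
                        min_score = 0.5, tie_tol = 1e-6) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stop("k must be odd and in [11, 31]")
  set_p <- genome_kmer_set(genome_parasite, k)
  set_h <- genome_kmer_set(genome_host, k)
  short <- names(unigenes)[nchar(unigenes) < k]
  if (length(short))
    warning(length(short), " query(ies) shorter than k=", k,
            " left unassigned: ", paste(utils::head(short, 5L),
                                        collapse = ", "))
  rows <- lapply(names(unigenes), function(id) {
    km <- canonical_kmers(unigenes[[id]], k)
    if (!length(km))
      return(data.frame(query_id = id, assigned_genome = "unassigned",
                        score = NA_real_, margin = NA_real_,
                        stringsAsFactors = FALSE))
    sp <- mean(km %in% set_p)
    sh <- mean(km %in% set_h)
    if (max(sp, sh) < min_score)
      return(data.frame(query_id = id, assigned_genome = "unassigned",
                        score = max(sp, sh), margin = abs(sp - sh),
                        stringsAsFactors = FALSE))
    out <- resolve_call(id, sp, sh, tie_tol)
    out$margin <- abs(sp - sh)          # both scores always defined here
    out
  })
  do.call(rbind, rows)
}

# canonical (strand-collapsed) k-mers of one sequence; k-mers touching a
# non-ACGT letter are masked out
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rc_full <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("[^ACGT]", "N", seq))))
  rev_starts <- n - k + 2L - starts
  rev <- substring(rc_full, rev_starts, rev_starts + k - 1L)
  can <- pmin(fwd, rev)
  can[!grepl("[^ACGT]", can)]
}

genome_kmer_set <- function(genome, k) {
  unique(unlist(lapply(unname(genome), canonical_kmers, k = k),
                use.names = FALSE))
}
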