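# Similarity screen (filter 1): exact Smith-Waterman local alignment of each
# candidate against the characterized seed enzymes, gated on percent identity
# and query coverage. This replaces a heuristic blastp screen with an exact
# DP using the same decision variables (BLOSUM62, gap open 11 / extend 1).

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with BLOSUM62 and affine gap penalties (a gap of length g
#' costs \code{gap_open + g * gap_extend}). X scores 0 against everything
#' and counts as a mismatch. Traceback ties prefer diagonal, then up, then
#' left; among equal-scoring end cells the smallest query, then subject,
#' position wins.
#'
#' @param query,subject Single protein records (one-row data frames from
#'   \code{\link{protein_records}}) or plain sequence strings.
#' @param gap_open,gap_extend Affine penalties in half-bit BLOSUM62 units.
#' @return A list of class \code{local_alignment} with elements
#'   \code{query_id}, \code{subject_id}, \code{aligned_query},
#'   \code{aligned_subject}, \code{identity_pct} (identical columns over all
#'   alignment columns, gap columns included), \code{query_coverage_pct}
#'   (aligned query span over query length) and \code{raw_score}. A best
#'   score of 0 or less yields an empty alignment with identity and
#'   coverage 0.
#' @export
local_align <- function(query, subject, gap_open = 11, gap_extend = 1) {
  qid <- if (is.data.frame(query)) query$id[[1]] else "query"
  sid <- if (is.data.frame(subject)) subject$id[[1]] else "subject"
  qs <- if (is.data.frame(query)) query$sequence[[1]] else query
  ss <- if (is.data.frame(subject)) subject$sequence[[1]] else subject
  stopifnot(nchar(qs) > 0, nchar(ss) > 0)
  sub <- blosum62_x()
  qi <- match(seq_chars(qs), AA_X) - 1L
  si <- match(seq_chars(ss), AA_X) - 1L
  res <- .sw_align_cpp(qi, si, sub, gap_open, gap_extend)
  ncol_aln <- length(res$q_ops)
  if (ncol_aln == 0L) {
    aq <- as_ <- ""
    identity <- 0
    coverage <- 0
  } else {
    qres <- seq_chars(substr(qs, res$q_start, res$q_end))
    sres <- seq_chars(substr(ss, res$s_start, res$s_end))
    aqv <- rep("-", ncol_aln)
    asv <- rep("-", ncol_aln)
    aqv[res$q_ops == 1L] <- qres
    asv[res$s_ops == 1L] <- sres
    ident <- sum(aqv == asv & aqv != "-" & aqv != "X")
    identity <- 100 * ident / ncol_aln
    coverage <- 100 * (res$q_end - res$q_start + 1L) / nchar(qs)
    aq <- paste(aqv, collapse = "")
    as_ <- paste(asv, collapse = "")
  }
  structure(list(query_id = qid, subject_id = sid,
                 aligned_query = aq, aligned_subject = as_,
                 identity_pct = identity, query_coverage_pct = coverage,
                 raw_score = res$score,
                 query_start = res$q_start, query_end = res$q_end,
                 subject_start = res$s_start, subject_end = res$s_end),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment %s vs %s: score %.1f, identity %.2f%%, coverage %.2f%%\n",
              x$query_id, x$subject_id, x$raw_score, x$identity_pct,
              x$query_coverage_pct))
  invisible(x)
}

#' Align candidates against seeds and tabulate best hits
#'
#' @param candidates,seeds Protein record data frames.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Data frame with one row per (candidate, seed) pair whose local
#'   alignment has positive score: \code{query_id}, \code{seed_id},
#'   \code{identity_pct}, \code{coverage_pct}, \code{score}.
#' @export
similarity_hits <- function(candidates, seeds, cfg = pipeline_config()) {
  stopifnot(nrow(seeds) > 0)
  rows <- vector("list", nrow(candidates) * nrow(seeds))
  n <- 0L
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(seeds))) {
      al <- local_align(candidates[i, , drop = FALSE],
                        seeds[j, , drop = FALSE],
                        cfg$sw_gap_open, cfg$sw_gap_extend)
      if (al$raw_score > 0) {
        n <- n + 1L
        rows[[n]] <- data.frame(query_id = al$query_id,
                                seed_id = al$subject_id,
                                identity_pct = al$identity_pct,
                                coverage_pct = al$query_coverage_pct,
                                score = al$raw_score,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L) {
    return(data.frame(query_id = character(), seed_id = character(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Similarity filter (filter 1)
#'
#' A candidate survives iff some seed alignment exceeds both thresholds
#' strictly (identity > \code{min_identity_pct} and query coverage >
#' \code{min_coverage_pct}).
#'
#' @param candidates,seeds Protein record data frames.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param hits Optional precomputed \code{\link{similarity_hits}} table.
#' @return Character vector of surviving candidate ids (input order).
#' @export
similarity_filter <- function(candidates, seeds, cfg = pipeline_config(),
                              hits = NULL) {
  stopifnot(nrow(seeds) > 0)
  if (nrow(candidates) == 0L) return(character())
  if (is.null(hits)) hits <- similarity_hits(candidates, seeds, cfg)
  keep <- hits$identity_pct > cfg$min_identity_pct &
    hits$coverage_pct > cfg$min_coverage_pct
  ids <- unique(hits$query_id[keep])
  candidates$id[candidates$id %in% ids]
}
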