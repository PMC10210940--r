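# Tandem gene duplication detection from scaffold gene order. Two STC genes
# form a tandem pair when they lie on the same scaffold of the same genome
# within `window` gene positions of each other (counting all annotated
# genes, strand-agnostic). Clusters are connected components of the pair
# graph.

#' Detect tandem STC gene arrangements
#'
#' @param loci Gene-locus table (see \code{\link{gene_loci}}).
#' @param stc_calls Named character vector mapping STC protein id to clade
#'   label (1-4 or "unclassified"), or a clade-call data frame.
#' @param window Maximum ordinal distance for a tandem pair.
#' @return A list of class \code{tandem_report}: \code{n_stc},
#'   \code{n_in_tandem}, \code{fraction_in_tandem}, \code{n_tandem_pairs},
#'   \code{n_pairs_classified}, \code{n_pairs_same_clade},
#'   \code{fraction_pairs_same_clade} (over pairs whose both members carry a
#'   clade 1-4; pairs involving unclassified genes are counted in
#'   \code{n_pairs_with_unclassified}), \code{n_genes_same_clade} and
#'   \code{fraction_genes_same_clade} (classified in-tandem genes sharing a
#'   clade with at least one partner), and \code{clusters} (ordinal-sorted
#'   protein-id groups).
#' @export
detect_tandem <- function(loci, stc_calls, window = 4L) {
  window <- as.integer(window)
  stopifnot(window >= 0L)
  if (is.data.frame(stc_calls)) {
    stc_calls <- setNames(stc_calls$clade, stc_calls$protein_id)
  }
  stc_ids <- names(stc_calls)
  missing <- setdiff(stc_ids, loci$protein_id)
  if (length(missing)) {
    stop("STC id missing from gene-order table: ", missing[[1L]],
         call. = FALSE)
  }
  stc <- loci[loci$protein_id %in% stc_ids, , drop = FALSE]
  stc <- stc[order(stc$genome_id, stc$scaffold, stc$ordinal), , drop = FALSE]
  n_stc <- nrow(stc)
  # pair discovery within genome+scaffold groups
  pairs <- list()
  grp <- split(seq_len(n_stc), paste(stc$genome_id, stc$scaffold, sep = "\r"))
  for (ix in grp) {
    if (length(ix) < 2L) next
    for (a in seq_len(length(ix) - 1L)) {
      for (b in (a + 1L):length(ix)) {
        i <- ix[a]; j <- ix[b]
        if (abs(stc$ordinal[j] - stc$ordinal[i]) <= window) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
      }
    }
  }
  n_pairs <- length(pairs)
  in_tandem <- unique(unlist(pairs))
  n_in <- length(in_tandem)
  # connected components via union-find
  parent <- seq_len(n_stc)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in pairs) {
    ra <- find(p[1L]); rb <- find(p[2L])
    if (ra != rb) parent[min(ra, rb)] <- max(ra, rb)
  }
  roots <- vapply(seq_len(n_stc), find, integer(1))
  clusters <- lapply(split(seq_len(n_stc), roots), function(ix) {
    if (length(ix) < 2L) return(NULL)
    ix <- ix[order(stc$ordinal[ix])]
    stc$protein_id[ix]
  })
  clusters <- Filter(Negate(is.null), unname(clusters))
  # same-clade statistics
  clade_of <- stc_calls[stc$protein_id]
  classified <- clade_of %in% CLADES
  pair_stats <- vapply(pairs, function(p) {
    c(both = classified[p[1L]] && classified[p[2L]],
      same = classified[p[1L]] && classified[p[2L]] &&
        clade_of[p[1L]] == clade_of[p[2L]])
  }, logical(2))
  n_pairs_classified <- if (n_pairs) sum(pair_stats["both", ]) else 0L
  n_pairs_same <- if (n_pairs) sum(pair_stats["same", ]) else 0L
  # gene-phrased statistic: classified in-tandem genes sharing a clade with
  # at least one tandem partner
  same_gene <- rep(FALSE, n_stc)
  for (p in pairs) {
    if (classified[p[1L]] && classified[p[2L]] &&
        clade_of[p[1L]] == clade_of[p[2L]]) {
      same_gene[p] <- TRUE
    }
  }
  n_genes_classified_in_tandem <- sum(classified[in_tandem])
  n_genes_same <- sum(same_gene)
  structure(list(
    n_stc = n_stc,
    n_in_tandem = n_in,
    fraction_in_tandem = if (n_stc) n_in / n_stc else 0,
    n_tandem_pairs = n_pairs,
    n_pairs_classified = as.integer(n_pairs_classified),
    n_pairs_same_clade = as.integer(n_pairs_same),
    fraction_pairs_same_clade =
      if (n_pairs_classified) n_pairs_same / n_pairs_classified else NA_real_,
    n_pairs_with_unclassified = as.integer(n_pairs - n_pairs_classified),
    n_genes_same_clade = as.integer(n_genes_same),
    fraction_genes_same_clade =
      if (n_genes_classified_in_tandem) n_genes_same / n_genes_classified_in_tandem
      else NA_real_,
    clusters = clusters), class = "tandem_report")
}

#' @export
print.tandem_report <- function(x, ...) {
  cat(sprintf("tandem report: %d STC, %d in tandem (%.1f%%), %d pairs, %s same-clade pairs\n",
              x$n_stc, x$n_in_tandem, 100 * x$fraction_in_tandem,
              x$n_tandem_pairs,
              if (is.na(x$fraction_pairs_same_clade)) "NA"
              else sprintf("%.1f%%", 100 * x$fraction_pairs_same_clade)))
  invisible(x)
}

#' Serialize a tandem report to JSON
#'
#' @param report A \code{tandem_report}.
#' @param path Optional output path; if NULL the JSON string is returned.
#' @return JSON text (invisibly when written to a file).
#' @export
tandem_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
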