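# Motif machinery: metal-binding motif filter (filter 2), discriminative
# motif discovery (exact k-mers highly represented in one clade and absent
# from the others), and motif-based reassignment of unclassified sequences.

#' Motif pattern syntax
#'
#' Patterns are strings over the 20 residue letters plus \code{x} (matches
#' any residue, including the unknown residue X) and bracketed alternative
#' groups such as \code{[DN]}. Literal positions match exactly; the unknown
#' residue X never matches a literal.
#'
#' @param pattern Pattern string.
#' @param description Optional free-text description.
#' @return An object of class \code{motif_pattern}.
#' @export
motif_pattern <- function(pattern, description = "") {
  positions <- parse_motif_pattern(pattern)
  if (length(positions) < 2L) {
    stop("motif patterns must have length >= 2", call. = FALSE)
  }
  structure(list(pattern = pattern, positions = positions,
                 description = description),
            class = "motif_pattern")
}

# parse to a list of per-position allowed residue sets (NULL = wildcard)
parse_motif_pattern <- function(pattern) {
  chars <- seq_chars(pattern)
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      grp <- character()
      while (j <= length(chars) && chars[[j]] != "]") {
        grp <- c(grp, chars[[j]])
        j <- j + 1L
      }
      if (j > length(chars) || length(grp) == 0L) {
        stop("unterminated group in motif pattern: ", pattern, call. = FALSE)
      }
      if (!all(grp %in% AA)) {
        stop("invalid residue in motif group: ", pattern, call. = FALSE)
      }
      out[[length(out) + 1L]] <- grp
      i <- j + 1L
    } else if (ch == "x") {
      out[[length(out) + 1L]] <- NULL_WILDCARD
      i <- i + 1L
    } else if (ch %in% AA) {
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("invalid character '", ch, "' in motif pattern: ", pattern,
           call. = FALSE)
    }
  }
  out
}

NULL_WILDCARD <- "*"

# conserved metal-binding patterns of class-I terpene cyclases
METAL_NTERM_A <- "[DN]Dxx[DE]"
METAL_NTERM_B <- "DDxxxE"
METAL_CTERM <- "NxxxSxxxE"

#' The conserved metal-binding motif patterns
#'
#' N-terminal (D/N)DxxD/E or DDxxxE and C-terminal NxxxSxxxE, the
#' Mg2+-coordinating signatures of class-I terpene cyclases.
#'
#' @return Named list of pattern strings.
#' @export
metal_motifs <- function() {
  list(nterm_a = METAL_NTERM_A, nterm_b = METAL_NTERM_B,
       cterm = METAL_CTERM)
}

#' Find motif matches in a sequence
#'
#' Reports all (possibly overlapping) 1-based match start positions. The
#' N-terminal region is the first half of the sequence (matches starting at
#' positions 1..floor(L/2)); the C-terminal region is the rest.
#'
#' @param seq A normalized residue string.
#' @param pattern A \code{\link{motif_pattern}} or pattern string.
#' @param region \code{"anywhere"}, \code{"nterm"} or \code{"cterm"}.
#' @return Integer vector of match start positions (1-based).
#' @export
find_pattern <- function(seq, pattern, region = c("anywhere", "nterm", "cterm")) {
  region <- match.arg(region)
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  chars <- seq_chars(seq)
  L <- length(chars)
  k <- length(pattern$positions)
  if (k > L) return(integer())
  starts <- integer()
  for (s in seq_len(L - k + 1L)) {
    ok <- TRUE
    for (p in seq_len(k)) {
      allowed <- pattern$positions[[p]]
      ch <- chars[[s + p - 1L]]
      if (identical(allowed, NULL_WILDCARD)) next
      if (!ch %in% allowed) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  half <- L %/% 2L
  if (region == "nterm") starts <- starts[starts <= half]
  if (region == "cterm") starts <- starts[starts > half]
  starts
}

#' Metal-binding motif filter (filter 2)
#'
#' A sequence survives iff it has an N-terminal match of (D/N)DxxD/E or
#' DDxxxE and a C-terminal match of NxxxSxxxE. This is the conjunction that
#' rejects prenyltransferase-like proteins, which carry DDxxD but lack the
#' C-terminal NSE triad.
#'
#' @param records Protein record data frame.
#' @return Character vector of surviving ids (input order).
#' @export
metal_binding_filter <- function(records) {
  if (nrow(records) == 0L) return(character())
  keep <- vapply(records$sequence, function(s) {
    nterm <- length(find_pattern(s, METAL_NTERM_A, "nterm")) > 0L ||
      length(find_pattern(s, METAL_NTERM_B, "nterm")) > 0L
    if (!nterm) return(FALSE)
    length(find_pattern(s, METAL_CTERM, "cterm")) > 0L
  }, logical(1), USE.NAMES = FALSE)
  records$id[keep]
}

# all distinct exact k-mers of a sequence for k in [kmin, kmax]
seq_kmers <- function(s, kmin, kmax) {
  L <- nchar(s)
  out <- character()
  for (k in kmin:kmax) {
    if (k > L) break
    out <- c(out, substring(s, 1:(L - k + 1L), k:L))
  }
  unique(out)
}

#' Discover discriminative motifs
#'
#' Finds every exact substring of length \code{motif_kmin}..\code{motif_kmax}
#' present in at least \code{motif_min_freq} of the positive sequences and in
#' none of the negative sequences. Only maximal motifs are reported: a motif
#' is dropped when a one-residue extension (within the length bounds) is
#' supported by exactly the same positives. Results are sorted by positive
#' frequency (descending), length (descending), then lexicographically.
#'
#' K-mers containing the unknown residue X are never reported (X carries no
#' motif information), but X-containing negatives still count for absence.
#'
#' @param positives,negatives Protein record data frames.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param clade Optional clade label attached to the result.
#' @return Data frame with columns \code{pattern}, \code{positive_freq},
#'   \code{n_pos_with}, \code{n_neg_with} (always 0) and \code{clade}.
#' @export
discover_motifs <- function(positives, negatives, cfg = pipeline_config(),
                            clade = "unclassified") {
  stopifnot(nrow(positives) > 0)
  if (nrow(negatives) == 0L) {
    stop("negative set is empty: discrimination undefined", call. = FALSE)
  }
  kmin <- cfg$motif_kmin
  kmax <- cfg$motif_kmax
  pos_sets <- lapply(positives$sequence, seq_kmers, kmin = kmin, kmax = kmax)
  neg_kmers <- unique(unlist(lapply(negatives$sequence, seq_kmers,
                                    kmin = kmin, kmax = kmax)))
  npos <- length(pos_sets)
  support <- table(unlist(pos_sets))
  min_count <- ceiling(cfg$motif_min_freq * npos)
  cand <- names(support)[support >= min_count]
  cand <- cand[!grepl("X", cand, fixed = TRUE)]
  cand <- setdiff(cand, neg_kmers)
  if (length(cand) == 0L) {
    return(empty_motif_table())
  }
  # supporting positive index sets, for the maximality rule
  supp_set <- lapply(cand, function(m) {
    which(vapply(pos_sets, function(ks) m %in% ks, logical(1)))
  })
  names(supp_set) <- cand
  keep <- vapply(cand, function(m) {
    if (nchar(m) >= kmax) return(TRUE)
    exts <- c(paste0(AA, m), paste0(m, AA))
    exts <- exts[exts %in% cand]
    for (e in exts) {
      if (identical(supp_set[[e]], supp_set[[m]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  cand <- cand[keep]
  freq <- vapply(cand, function(m) length(supp_set[[m]]) / npos, numeric(1))
  ord <- order(-freq, -nchar(cand), cand)
  data.frame(pattern = cand[ord],
             positive_freq = unname(freq[ord]),
             n_pos_with = vapply(cand[ord], function(m) length(supp_set[[m]]),
                                 integer(1), USE.NAMES = FALSE),
             n_neg_with = 0L,
             clade = clade,
             stringsAsFactors = FALSE)
}

empty_motif_table <- function() {
  data.frame(pattern = character(), positive_freq = numeric(),
             n_pos_with = integer(), n_neg_with = integer(),
             clade = character(), stringsAsFactors = FALSE)
}

#' Reassign unclassified sequences by clade signature motifs
#'
#' A sequence containing motifs of exactly one clade is reassigned to that
#' clade (evidence \code{"motif"}); sequences matching motifs of several
#' clades, or none, stay unclassified.
#'
#' @param unclassified Protein record data frame.
#' @param clade_motifs Motif table as returned by
#'   \code{\link{discover_motifs}} (rows for all four clades pooled), or a
#'   named list of such tables.
#' @return A clade-call data frame (see \code{\link{clade_calls}}).
#' @export
reassign_by_motif <- function(unclassified, clade_motifs) {
  if (is.list(clade_motifs) && !is.data.frame(clade_motifs)) {
    clade_motifs <- do.call(rbind, clade_motifs)
  }
  as_clade(clade_motifs$clade)
  if (!all(CLADES %in% clade_motifs$clade)) {
    warning("clade motif table does not cover all four clades",
            call. = FALSE)
  }
  calls <- lapply(seq_len(nrow(unclassified)), function(i) {
    s <- unclassified$sequence[[i]]
    hit_clades <- unique(clade_motifs$clade[
      vapply(clade_motifs$pattern, function(m) grepl(m, s, fixed = TRUE),
             logical(1), USE.NAMES = FALSE)])
    if (length(hit_clades) == 1L) {
      clade_calls(unclassified$id[[i]], hit_clades, "motif")
    } else {
      clade_calls(unclassified$id[[i]], "unclassified", "motif")
    }
  })
  if (length(calls) == 0L) return(clade_calls(character(), character(), character()))
  do.call(rbind, calls)
}

#' Construct a clade-call table
#'
#' @param protein_id Character vector of protein ids.
#' @param clade Clade labels (1-4 or "unclassified").
#' @param evidence One of \code{"distance_cluster"}, \code{"motif"},
#'   \code{"hmm_best_score"} per call.
#' @param score Bit score; required iff evidence is
#'   \code{"hmm_best_score"}, must be NA otherwise.
#' @return Data frame with those four columns.
#' @export
clade_calls <- function(protein_id, clade, evidence, score = NA_real_) {
  clade <- as_clade(clade)
  n <- length(protein_id)
  evidence <- rep_len(evidence, n)
  score <- rep_len(as.numeric(score), n)
  ok_ev <- evidence %in% c("distance_cluster", "motif", "hmm_best_score")
  if (!all(ok_ev)) stop("invalid evidence value", call. = FALSE)
  if (any(evidence == "hmm_best_score" & is.na(score)) ||
      any(evidence != "hmm_best_score" & !is.na(score))) {
    stop("score must be present iff evidence is hmm_best_score",
         call. = FALSE)
  }
  data.frame(protein_id = as.character(protein_id), clade = clade,
             evidence = evidence, score = score, stringsAsFactors = FALSE)
}
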