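# Profile hidden Markov models: construction from trimmed alignments,
# glocal bit-score scoring (Viterbi / Forward), proteome search with a
# gathering threshold, best-score clade assignment, second-generation
# refinement, and a plain-text serialization.
#
# Architecture: nodes 1..L each have match (M), insert (I) and delete (D)
# states, plus an insert state I0 before node 1. Begin (B) and end (E) are
# silent. Transition bundles per node k (row k+1 of the transition matrix,
# columns MM MI MD IM II DM DD):
#   k = 0:      B->M1  B->I0  B->D1   I0->M1  I0->I0   (DM/DD unused)
#   1 <= k < L: Mk->Mk+1  Mk->Ik  Mk->Dk+1  Ik->Mk+1  Ik->Ik  Dk->Mk+1  Dk->Dk+1
#   k = L:      ML->E  ML->IL  (MD = 0)  IL->E  IL->IL  DL->E  (DD = 0)
# Scoring is glocal: the model is traversed from B to E while sequence
# flanks are emitted at background frequencies and contribute 0 bits.

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Construct a profile HMM object
#'
#' @param match_emissions L x 20 matrix of match emission probabilities
#'   (columns in \code{\link{aa_alphabet}} order).
#' @param insert_emissions (L+1) x 20 matrix; row k+1 is insert state k.
#' @param transitions (L+1) x 7 matrix, columns MM MI MD IM II DM DD; row
#'   k+1 holds the node-k bundles described above.
#' @param background Length-20 background distribution (default uniform).
#' @param name Model name.
#' @param clade Clade label the model represents.
#' @return An object of class \code{profile_hmm}.
#' @export
profile_hmm <- function(match_emissions, insert_emissions, transitions,
                        background = rep(0.05, 20), name = "model",
                        clade = "unclassified") {
  match_emissions <- as.matrix(match_emissions)
  insert_emissions <- as.matrix(insert_emissions)
  transitions <- as.matrix(transitions)
  L <- nrow(match_emissions)
  stopifnot(L >= 1L, ncol(match_emissions) == 20L,
            nrow(insert_emissions) == L + 1L, ncol(insert_emissions) == 20L,
            nrow(transitions) == L + 1L, ncol(transitions) == 7L,
            length(background) == 20L)
  colnames(transitions) <- TRANS_NAMES
  hmm <- structure(list(name = name, clade = as_clade(clade), L = L,
                        match_emissions = unname(match_emissions),
                        insert_emissions = unname(insert_emissions),
                        transitions = transitions,
                        background = as.numeric(background)),
                   class = "profile_hmm")
  validate_profile_hmm(hmm)
}

validate_profile_hmm <- function(hmm, tol = 1e-12) {
  L <- hmm$L
  chk <- function(x, what) {
    bad <- abs(x - 1) > tol
    if (any(bad)) {
      stop(what, " ", which(bad)[[1L]], " sums to ",
           format(x[bad][[1L]], digits = 17), ", expected 1", call. = FALSE)
    }
  }
  chk(rowSums(hmm$match_emissions), "match emission row")
  chk(rowSums(hmm$insert_emissions), "insert emission row")
  chk(sum(hmm$background), "background row")
  tr <- hmm$transitions
  chk(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]), "match transition bundle")
  chk(rowSums(tr[, c("IM", "II"), drop = FALSE]), "insert transition bundle")
  if (L >= 1L) {
    # delete bundles exist for nodes 1..L (rows 2..L+1)
    chk(rowSums(tr[-1L, c("DM", "DD"), drop = FALSE]), "delete transition bundle")
  }
  if (tr[L + 1L, "MD"] != 0 || tr[L + 1L, "DD"] != 0) {
    stop("node L cannot transition to a delete state", call. = FALSE)
  }
  hmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM '%s' (clade %s): %d match states\n",
              x$name, x$clade, x$L))
  invisible(x)
}

#' Build a profile HMM from a trimmed alignment
#'
#' Columns with gap fraction below 0.5 become match states. Emissions are
#' observed counts with a +1 Laplace pseudocount over the 20 residues
#' (unknown residues X are ignored); transitions are observed state-path
#' counts with +1 per legal outgoing edge. Background is uniform (0.05).
#'
#' @param m An \code{\link{msa}} with at least two rows.
#' @param name Model name.
#' @param clade Clade label.
#' @return A \code{\link{profile_hmm}}.
#' @export
build_hmm <- function(m, name = "model", clade = "unclassified") {
  stopifnot(length(m$ids) >= 2L)
  mat <- msa_matrix(m)
  nr <- nrow(mat)
  gapfrac <- colMeans(mat == "-")
  is_match <- gapfrac < 0.5
  L <- sum(is_match)
  if (L == 0L) stop("no match states", call. = FALSE)
  node_of_col <- cumsum(is_match)          # node index per column (match col -> its node)

  match_counts <- matrix(0, L, 20L)
  insert_counts <- matrix(0, L + 1L, 20L)
  # legal-edge template per node row
  tcounts <- matrix(0, L + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  legal <- matrix(FALSE, L + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  legal[, c("MM", "MI", "IM", "II")] <- TRUE
  if (L >= 1L) {
    legal[seq_len(L), "MD"] <- TRUE                  # nodes 0..L-1 open deletes
    legal[1L + seq_len(L), c("DM")] <- TRUE          # nodes 1..L leave deletes
    if (L >= 2L) legal[1L + seq_len(L - 1L), "DD"] <- TRUE
  }

  # I<->D moves are not representable in the plan7-style edge set; such
  # observed moves are simply not counted (the +1 pseudocounts keep every
  # legal edge usable).
  add_edge <- function(row, edge) {
    if (edge %in% TRANS_NAMES && legal[row, edge]) {
      tcounts[row, edge] <<- tcounts[row, edge] + 1
    }
  }
  for (r in seq_len(nr)) {
    state <- "M"; node <- 0L
    for (j in seq_len(ncol(mat))) {
      ch <- mat[r, j]
      if (is_match[j]) {
        k <- node_of_col[j]
        if (ch == "-") {
          add_edge(node + 1L, paste0(state, "D"))
          state <- "D"
        } else {
          add_edge(node + 1L, paste0(state, "M"))
          state <- "M"
          ix <- aa_index(ch)
          if (!is.na(ix)) match_counts[k, ix] <- match_counts[k, ix] + 1
        }
        node <- k
      } else if (ch != "-") {
        add_edge(node + 1L, paste0(state, "I"))
        state <- "I"
        ix <- aa_index(ch)
        if (!is.na(ix)) insert_counts[node + 1L, ix] <- insert_counts[node + 1L, ix] + 1
      }
    }
    # exit to E counts as a ->M transition at node L
    add_edge(L + 1L, paste0(state, "M"))
  }

  match_em <- (match_counts + 1) / (rowSums(match_counts) + 20)
  insert_em <- (insert_counts + 1) / (rowSums(insert_counts) + 20)
  trans <- matrix(0, L + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  bundles <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
  for (k in seq_len(L + 1L)) {
    for (b in bundles) {
      lg <- b[legal[k, b]]
      if (length(lg) == 0L) next
      cnt <- tcounts[k, lg] + 1
      trans[k, lg] <- cnt / sum(cnt)
    }
  }
  profile_hmm(match_em, insert_em, trans, rep(0.05, 20), name, clade)
}

# log2-odds matrices used by the C++ scorer
hmm_log_tables <- function(hmm) {
  lb <- log2(hmm$background)
  list(lmatch = log2(hmm$match_emissions) - rep(lb, each = hmm$L),
       lins = log2(hmm$insert_emissions) - rep(lb, each = hmm$L + 1L),
       ltr = log2(hmm$transitions))
}

#' Score a sequence against a profile HMM
#'
#' Glocal log2-odds score in bits: the model must be traversed end to end;
#' unaligned sequence flanks are emitted at background frequencies and
#' contribute 0 bits. \code{viterbi} scores the best state path,
#' \code{forward} the sum over all paths (so forward >= viterbi always).
#' The unknown residue X emits background in every state (0 bits).
#'
#' @param hmm A \code{\link{profile_hmm}}.
#' @param seq A protein record row or a plain sequence string.
#' @param mode \code{"viterbi"} or \code{"forward"}.
#' @return Bit score (numeric scalar).
#' @export
score_sequence <- function(hmm, seq, mode = c("viterbi", "forward")) {
  mode <- match.arg(mode)
  s <- if (is.data.frame(seq)) seq$sequence[[1]] else seq
  stopifnot(nchar(s) > 0)
  tabs <- hmm_log_tables(hmm)
  codes <- aa_index(seq_chars(s)) - 1L
  codes[is.na(codes)] <- -1L
  .hmm_score_cpp(tabs$lmatch, tabs$lins, tabs$ltr, codes,
                 if (mode == "viterbi") 0L else 1L)
}

#' Search a proteome with profile HMMs
#'
#' Viterbi-scores every sequence against every model and keeps hits at or
#' above the gathering threshold.
#'
#' @param hmms List of \code{\link{profile_hmm}} models.
#' @param proteome Protein record data frame.
#' @param threshold Gathering threshold in bits.
#' @return Data frame with columns \code{protein_id}, \code{model_name},
#'   \code{clade}, \code{bit_score}, sorted by protein then descending
#'   score.
#' @export
hmm_search <- function(hmms, proteome, threshold = 25) {
  stopifnot(length(hmms) >= 1L)
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  rows <- list()
  tabs <- lapply(hmms, hmm_log_tables)
  for (i in seq_len(nrow(proteome))) {
    codes <- aa_index(seq_chars(proteome$sequence[[i]])) - 1L
    codes[is.na(codes)] <- -1L
    for (h in seq_along(hmms)) {
      sc <- .hmm_score_cpp(tabs[[h]]$lmatch, tabs[[h]]$lins, tabs[[h]]$ltr,
                           codes, 0L)
      if (sc >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = proteome$id[[i]], model_name = hmms[[h]]$name,
          clade = hmms[[h]]$clade, bit_score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(), model_name = character(),
                      clade = character(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$protein_id, -out$bit_score, out$clade), , drop = FALSE]
}

#' Assign clades from HMM hits by best score
#'
#' Each protein gets the clade of its highest-scoring model. An exact score
#' tie across different clades leaves the protein unclassified, with a
#' warning.
#'
#' @param hits Hit table from \code{\link{hmm_search}}.
#' @return A clade-call data frame (evidence \code{"hmm_best_score"}).
#' @export
assign_by_best_score <- function(hits) {
  if (nrow(hits) == 0L) {
    return(clade_calls(character(), character(), character()))
  }
  calls <- lapply(split(hits, hits$protein_id), function(h) {
    best <- max(h$bit_score)
    top <- unique(h$clade[h$bit_score == best])
    if (length(top) > 1L) {
      warning("score tie across clades for ", h$protein_id[[1]],
              "; left unclassified", call. = FALSE)
      clade_calls(h$protein_id[[1]], "unclassified", "hmm_best_score",
                  score = best)
    } else {
      clade_calls(h$protein_id[[1]], top, "hmm_best_score", score = best)
    }
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}

#' Build second-generation models from first-generation hits
#'
#' For each clade: pool the top \code{top_k} basidiomycete-derived and top
#' \code{top_k} ascomycete-derived sequences by best bit score (all
#' available if fewer), align, trim, and rebuild the model.
#'
#' @param gen1_hmms List of first-generation models (one per clade).
#' @param all_hits Hit table from \code{\link{hmm_search}} with the
#'   generation-1 models.
#' @param proteins Protein record data frame covering every hit id (the
#'   \code{division} column drives the per-division selection).
#' @param top_k Sequences per division per clade.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Named list of four second-generation \code{\link{profile_hmm}}s.
#' @export
refine_generation2 <- function(gen1_hmms, all_hits, proteins, top_k = 100L,
                               cfg = pipeline_config()) {
  top_k <- as.integer(top_k)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  calls <- assign_by_best_score(all_hits)
  calls <- calls[calls$clade %in% CLADES, , drop = FALSE]
  missing <- setdiff(CLADES, unique(calls$clade))
  if (length(missing)) {
    stop("no hits for clade ", paste(missing, collapse = ", "), call. = FALSE)
  }
  prot_ix <- match(calls$protein_id, proteins$id)
  if (anyNA(prot_ix)) {
    stop("hit id missing from protein table: ",
         calls$protein_id[is.na(prot_ix)][[1L]], call. = FALSE)
  }
  calls$division <- proteins$division[prot_ix]
  out <- list()
  for (cl in CLADES) {
    cc <- calls[calls$clade == cl, , drop = FALSE]
    picked <- character()
    for (div in c("basidiomycete", "ascomycete")) {
      cd <- cc[cc$division == div, , drop = FALSE]
      cd <- cd[order(-cd$score, cd$protein_id), , drop = FALSE]
      picked <- c(picked, head(cd$protein_id, top_k))
    }
    # sequences from unlabelled divisions are used only if nothing else is
    if (length(picked) < 2L) {
      cd <- cc[order(-cc$score, cc$protein_id), , drop = FALSE]
      picked <- unique(c(picked, head(cd$protein_id, max(2L, top_k))))
    }
    train <- proteins[match(picked, proteins$id), , drop = FALSE]
    aln <- progressive_align(setNames(train$sequence, train$id),
                             cfg$gap_open, cfg$gap_extend)
    aln <- trim_msa(aln, cfg$trim_gap_threshold)
    out[[cl]] <- build_hmm(aln, name = paste0("gen2-clade", cl), clade = cl)
  }
  out
}
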