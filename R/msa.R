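# Progressive multiple alignment: guide tree from 3-mer count distances
# (UPGMA), then profile-profile global alignment with affine gaps along the
# tree. BLOSUM62 is rescaled to unit mean diagonal (MAFFT-style matrix
# normalization) so the penalties gap open 2.3 / gap extend 0.63 are on the
# matrix scale: opening a gap costs about three average matches.

# BLOSUM62 scaled so the average diagonal (exact self-match) score is 1
profile_submatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- blosum62_x()[AA, AA]
      cache <<- b / mean(diag(b))
    }
    cache
  }
})

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of sequence ids.
#' @param rows Equal-length gapped residue strings (gap = \code{-}).
#' @return An object of class \code{msa}.
#' @export
msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(ids) >= 1L)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length", call. = FALSE)
  m <- structure(list(ids = as.character(ids), rows = as.character(rows),
                      column_count = w),
                 class = "msa")
  mat <- msa_matrix(m)
  if (m$column_count > 0L && any(colSums(mat != "-") == 0L)) {
    stop("alignment contains an all-gap column", call. = FALSE)
  }
  m
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids),
              x$column_count))
  invisible(x)
}

# character matrix view (rows x columns)
msa_matrix <- function(m) {
  do.call(rbind, lapply(m$rows, seq_chars))
}

#' Remove gaps from alignment rows
#'
#' @param m An \code{\link{msa}}.
#' @return Character vector of ungapped sequences, named by id.
#' @export
degap <- function(m) {
  setNames(gsub("-", "", m$rows, fixed = TRUE), m$ids)
}

# 3-mer count profile matrix (n x 20^3), for guide-tree distances
kmer_counts <- function(seqs, k = 3L) {
  idx <- lapply(seqs, function(s) {
    ch <- aa_index(seq_chars(s))  # X -> NA, dropped below
    L <- length(ch)
    if (L < k) return(integer())
    v <- ch[1:(L - k + 1L)]
    for (j in 2:k) v <- (v - 1L) * 20L + ch[j:(L - k + j)]
    v[!is.na(v)]
  })
  out <- matrix(0, nrow = length(seqs), ncol = 20L^k)
  for (i in seq_along(idx)) {
    t <- tabulate(idx[[i]], nbins = 20L^k)
    out[i, ] <- t
  }
  out
}

# cosine distance on 3-mer counts: fast, adequate for a guide tree
kmer_distance <- function(seqs) {
  x <- kmer_counts(seqs)
  s <- tcrossprod(x)
  nrm <- sqrt(diag(s))
  nrm[nrm == 0] <- 1
  d <- 1 - s / outer(nrm, nrm)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# frequency profile of an msa (columns x 20), gaps and X carry no mass;
# normalized by the number of rows
msa_profile <- function(m) {
  mat <- msa_matrix(m)
  nr <- nrow(mat)
  prof <- matrix(0, nrow = ncol(mat), ncol = 20L)
  for (j in seq_len(ncol(mat))) {
    ix <- aa_index(mat[, j])
    ix <- ix[!is.na(ix)]
    if (length(ix)) {
      t <- tabulate(ix, nbins = 20L)
      prof[j, ] <- t / nr
    }
  }
  prof
}

# merge two msas along a profile-alignment op path
merge_msas <- function(a, b, ops) {
  arows <- lapply(a$rows, seq_chars)
  brows <- lapply(b$rows, seq_chars)
  na <- a$column_count
  nb <- b$column_count
  w <- length(ops)
  ai <- 0L; bi <- 0L
  a_take <- integer(w); b_take <- integer(w)
  for (t in seq_len(w)) {
    if (ops[t] == 0L) { ai <- ai + 1L; bi <- bi + 1L; a_take[t] <- ai; b_take[t] <- bi }
    else if (ops[t] == 1L) { ai <- ai + 1L; a_take[t] <- ai; b_take[t] <- 0L }
    else { bi <- bi + 1L; a_take[t] <- 0L; b_take[t] <- bi }
  }
  stopifnot(ai == na, bi == nb)
  expand <- function(row, take) {
    out <- rep("-", w)
    out[take > 0L] <- row[take[take > 0L]]
    paste(out, collapse = "")
  }
  msa(c(a$ids, b$ids),
      c(vapply(arows, expand, character(1), take = a_take),
        vapply(brows, expand, character(1), take = b_take)))
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from cosine distances on 3-mer count vectors,
#' then merges sequence profiles along the tree with global affine-gap
#' profile-profile alignment (BLOSUM62 in bit units). Deterministic: ties in
#' the DP prefer diagonal, then the first profile, then the second.
#'
#' @param seqs Protein record data frame (or named character vector).
#' @param gap_open,gap_extend Affine penalties in bit-scaled matrix units.
#' @return An \code{\link{msa}}; degapping its rows reproduces the inputs.
#' @export
progressive_align <- function(seqs, gap_open = 2.3, gap_extend = 0.63) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    ss <- seqs$sequence
  } else {
    ids <- names(seqs)
    ss <- unname(seqs)
  }
  stopifnot(length(ss) >= 1L)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  if (length(ss) == 1L) return(msa(ids, ss))
  sub_bits <- profile_submatrix()
  leaves <- lapply(seq_along(ss), function(i) msa(ids[i], ss[i]))
  pair_merge <- function(a, b) {
    ops <- .profile_align_cpp(msa_profile(a), msa_profile(b), sub_bits,
                              gap_open, gap_extend)
    merge_msas(a, b, ops)
  }
  if (length(ss) == 2L) {
    final <- pair_merge(leaves[[1L]], leaves[[2L]])
  } else {
    d <- kmer_distance(ss)
    dimnames(d) <- list(ids, ids)
    tree <- upgma(d)
    node_msa <- vector("list", nrow(tree$merge))
    for (step in seq_len(nrow(tree$merge))) {
      l <- tree$merge[step, 1L]
      r <- tree$merge[step, 2L]
      a <- if (l < 0L) leaves[[-l]] else node_msa[[l]]
      b <- if (r < 0L) leaves[[-r]] else node_msa[[r]]
      node_msa[[step]] <- pair_merge(a, b)
    }
    final <- node_msa[[nrow(tree$merge)]]
  }
  ord <- match(ids, final$ids)
  msa(final$ids[ord], final$rows[ord])
}

#' Trim poorly aligned columns
#'
#' Keeps exactly the columns whose gap fraction is at most
#' \code{gap_threshold}; row order is preserved. Idempotent.
#'
#' @param m An \code{\link{msa}}.
#' @param gap_threshold Maximum tolerated gap fraction per column.
#' @return The trimmed \code{\link{msa}}.
#' @export
trim_msa <- function(m, gap_threshold = 0.5) {
  mat <- msa_matrix(m)
  gapfrac <- colMeans(mat == "-")
  keep <- gapfrac <= gap_threshold
  if (!any(keep)) stop("alignment fully trimmed", call. = FALSE)
  rows <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  msa(m$ids, rows)
}
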