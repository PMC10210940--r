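# Physicochemical-category distances, UPGMA dendrograms, and cluster-based
# clade assignment against characterized reference enzymes.

# protdist-style physicochemical categories
AA_CATEGORY <- local({
  cats <- list(c("C"),
               c("M", "V", "L", "I"),
               c("G", "A", "S", "T", "P"),
               c("F", "Y", "W"),
               c("N", "D", "E", "Q"),
               c("H", "K", "R"))
  v <- integer(0)
  for (i in seq_along(cats)) v[cats[[i]]] <- i
  v
})

DIST_CAP <- 10.0

#' Category-penalized distance matrix from an alignment
#'
#' For each sequence pair, over the columns where both rows carry residues:
#' a site scores 0 when identical, 0.5 when different residues of the same
#' physicochemical category (C | MVLI | GASTP | FYW | NDEQ | HKR), and 1
#' otherwise; the unknown residue X always scores 1. The raw proportion D is
#' corrected to d = -ln(1 - D) and capped at 10. A pair with no shared
#' non-gap columns gets the cap, with a warning.
#'
#' @param m An \code{\link{msa}} with at least two rows.
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
category_distance <- function(m) {
  stopifnot(length(m$ids) >= 2L)
  mat <- msa_matrix(m)
  n <- nrow(mat)
  res <- matrix(0, n, n, dimnames = list(m$ids, m$ids))
  cat_idx <- AA_CATEGORY[mat]
  dim(cat_idx) <- dim(mat)
  is_res <- mat != "-"
  is_x <- mat == "X"
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- is_res[i, ] & is_res[j, ]
      nsites <- sum(both)
      if (nsites == 0L) {
        warned <- TRUE
        d <- DIST_CAP
      } else {
        a <- mat[i, both]; b <- mat[j, both]
        ca <- cat_idx[i, both]; cb <- cat_idx[j, both]
        xs <- is_x[i, both] | is_x[j, both]
        score <- ifelse(xs, 1,
                        ifelse(a == b, 0,
                               ifelse(!is.na(ca) & !is.na(cb) & ca == cb,
                                      0.5, 1)))
        D <- mean(score)
        d <- if (D >= 1 - exp(-DIST_CAP)) DIST_CAP else -log(1 - D)
      }
      res[i, j] <- d
      res[j, i] <- d
    }
  }
  if (warned) {
    warning("pair(s) with no shared non-gap columns set to the distance cap",
            call. = FALSE)
  }
  res
}

#' UPGMA dendrogram
#'
#' Standard unweighted pair-group average clustering. Heights are ultrametric
#' node heights (half the average distance between the merged clusters). Ties
#' in the minimum distance are broken by the lexicographically smallest pair
#' of cluster labels, a cluster being labelled by its smallest member id, so
#' the tree is invariant to input order.
#'
#' @param d Symmetric distance matrix with ids as dimnames.
#' @return A list of class \code{stc_dendrogram} with \code{labels},
#'   \code{merge} (hclust convention: negative entries are leaves, positive
#'   entries earlier merge steps), \code{height} (ultrametric, i.e. merge
#'   distance / 2) and \code{leaf_sets} (leaf indices under each internal
#'   node).
#' @export
upgma <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  n <- nrow(d)
  # active cluster bookkeeping
  active <- seq_len(n)                 # positions into cur
  cur <- -seq_len(n)                   # hclust codes of active clusters
  sizes <- rep(1L, n)
  minlab <- labels                     # smallest member label per cluster
  leaf_ix <- as.list(seq_len(n))
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  leaf_sets <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    mval <- min(D)
    idx <- which(D == mval, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    # tie-break: lexicographically smallest (sorted) label pair
    keys <- apply(idx, 1L, function(p) {
      lab <- sort(c(minlab[p[1L]], minlab[p[2L]]))
      paste(lab, collapse = "\r")
    })
    pick <- idx[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    a <- cur[i]; b <- cur[j]
    # hclust merge row convention: leaves (negative) first, then by value
    row <- sort(c(a, b))
    merge[step, ] <- row
    height[step] <- mval / 2
    leaf_sets[[step]] <- sort(c(leaf_ix[[i]], leaf_ix[[j]]))
    # UPGMA update: size-weighted average into position i, drop j
    ni <- sizes[i]; nj <- sizes[j]
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- Inf
    D <- D[-j, -j, drop = FALSE]
    cur[i] <- step
    sizes[i] <- ni + nj
    minlab[i] <- min(minlab[i], minlab[j])
    leaf_ix[[i]] <- leaf_sets[[step]]
    cur <- cur[-j]; sizes <- sizes[-j]; minlab <- minlab[-j]
    leaf_ix <- leaf_ix[-j]
  }
  structure(list(labels = labels, merge = merge, height = height,
                 leaf_sets = leaf_sets),
            class = "stc_dendrogram")
}

#' @export
print.stc_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, root height %.4f\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Convert to an hclust object
#'
#' Heights are doubled (hclust stores the merge distance, not the
#' ultrametric node height).
#'
#' @param tree An \code{stc_dendrogram}.
#' @return An object of class \code{hclust}.
#' @export
as_hclust <- function(tree) {
  ord <- integer()
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(tree$merge[node, 1L]), walk(tree$merge[node, 2L]))
  }
  structure(list(merge = tree$merge, height = tree$height * 2,
                 order = walk(nrow(tree$merge)), labels = tree$labels,
                 method = "average", call = match.call(),
                 dist.method = "category"),
            class = "hclust")
}

#' Assign candidates to clades by dendrogram clustering
#'
#' Pools candidates with the labelled reference enzymes, runs the alignment
#' / trimming / category-distance / UPGMA pipeline, and assigns each
#' candidate the clade of its smallest enclosing cluster that contains at
#' least one reference - provided all references in that cluster share one
#' clade; otherwise the candidate stays unclassified.
#'
#' @param candidates Protein record data frame.
#' @param references Protein record data frame of characterized enzymes.
#' @param ref_clades Named vector mapping reference id to clade (1-4); every
#'   clade must have at least one reference.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return A clade-call data frame (evidence \code{"distance_cluster"}).
#' @export
assign_clades_by_clustering <- function(candidates, references, ref_clades,
                                        cfg = pipeline_config()) {
  stopifnot(nrow(references) >= 1L)
  ref_clades <- setNames(as_clade(ref_clades), names(ref_clades))
  if (!all(references$id %in% names(ref_clades))) {
    stop("every reference needs a clade label", call. = FALSE)
  }
  missing_clades <- setdiff(CLADES, ref_clades[references$id])
  if (length(missing_clades)) {
    stop("no reference for clade ", paste(missing_clades, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(candidates) == 0L) {
    return(clade_calls(character(), character(), character()))
  }
  pool <- rbind(candidates[, c("id", "sequence")],
                references[, c("id", "sequence")])
  aln <- progressive_align(setNames(pool$sequence, pool$id),
                           cfg$gap_open, cfg$gap_extend)
  aln <- trim_msa(aln, cfg$trim_gap_threshold)
  dm <- category_distance(aln)
  tree <- upgma(dm)
  is_ref <- tree$labels %in% references$id
  calls <- lapply(candidates$id, function(id) {
    leaf <- match(id, tree$labels)
    clade <- "unclassified"
    for (step in order(tree$height)) {
      set <- tree$leaf_sets[[step]]
      if (!leaf %in% set) next
      refs_in <- tree$labels[set][is_ref[set]]
      if (length(refs_in) == 0L) next
      cl <- unique(ref_clades[refs_in])
      if (length(cl) == 1L) clade <- cl
      break
    }
    clade_calls(id, clade, "distance_cluster")
  })
  do.call(rbind, calls)
}
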