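# End-to-end pipeline: similarity screen -> metal-binding motif filter ->
# length filter -> distance-based clade assignment -> discriminative motif
# discovery and reassignment -> generation-1 HMMs -> proteome search ->
# generation-2 refinement -> final calls -> tandem report.

#' Length filter (filter 3)
#'
#' Keeps sequences whose length L satisfies the exclusive window
#' \code{min_len_aa} < L < \code{max_len_aa}.
#'
#' @param records Protein record data frame.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Character vector of surviving ids (input order).
#' @export
length_filter <- function(records, cfg = pipeline_config()) {
  L <- nchar(records$sequence)
  records$id[L > cfg$min_len_aa & L < cfg$max_len_aa]
}

filter_report <- function(genome_id, n_input, n_after_similarity,
                          n_after_motif, n_after_length, surviving_ids) {
  stopifnot(n_input >= n_after_similarity,
            n_after_similarity >= n_after_motif,
            n_after_motif >= n_after_length,
            n_after_length == length(surviving_ids))
  list(genome_id = genome_id, n_input = n_input,
       n_after_similarity = n_after_similarity,
       n_after_motif = n_after_motif, n_after_length = n_after_length,
       surviving_ids = surviving_ids)
}

#' Run the full STC mining pipeline
#'
#' Stages, in order: (1) similarity screen of every proteome against the
#' seed enzymes; (2) metal-binding motif filter; (3) length filter; (4)
#' distance-based clade assignment of the pooled survivors against the
#' seeds; (5) discriminative motif discovery on the classified sets and
#' motif reassignment of unclassified sequences; (6) generation-1 HMMs per
#' clade; (7) glocal HMM search of the full proteomes at the gathering
#' threshold; (8) generation-2 refinement and re-search; (9) tandem
#' analysis of the final calls when gene order is supplied.
#'
#' @param proteomes Protein record data frame (one or more genomes,
#'   distinguished by \code{genome_id}).
#' @param seeds Protein record data frame of characterized seed enzymes.
#' @param seed_clades Named vector mapping seed id to clade 1-4; all four
#'   clades must be covered.
#' @param gene_orders Optional gene-locus table for the tandem stage.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param train_with_motif_calls Include motif-reassigned sequences in the
#'   generation-1 training sets (default TRUE).
#' @param include_seeds Include the seed enzymes themselves in the
#'   generation-1 training sets (default TRUE).
#' @param verbose Log per-genome stage counts.
#' @return A list of class \code{stc_pipeline_result}: \code{filter_reports}
#'   (per genome), \code{calls_gen0} (distance + motif), \code{calls_gen1},
#'   \code{calls_gen2}, \code{motifs}, \code{models_gen1},
#'   \code{models_gen2}, \code{hits_gen1}, \code{hits_gen2} and
#'   \code{tandem} (NULL without gene order).
#' @export
run_pipeline <- function(proteomes, seeds, seed_clades, gene_orders = NULL,
                         cfg = pipeline_config(),
                         train_with_motif_calls = TRUE,
                         include_seeds = TRUE, verbose = FALSE) {
  validate_protein_records(seeds)
  seed_clades <- setNames(as_clade(seed_clades), names(seed_clades))
  if (!all(CLADES %in% seed_clades[seeds$id])) {
    stop("seeds must cover all four clades", call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))

  # --- filter cascade, per genome -----------------------------------------
  reports <- list()
  survivors <- character()
  if (nrow(proteomes)) validate_protein_records(proteomes)
  for (g in unique(proteomes$genome_id)) {
    cand <- proteomes[proteomes$genome_id == g, , drop = FALSE]
    ids1 <- similarity_filter(cand, seeds, cfg)
    cand1 <- cand[cand$id %in% ids1, , drop = FALSE]
    ids2 <- metal_binding_filter(cand1)
    cand2 <- cand1[cand1$id %in% ids2, , drop = FALSE]
    ids3 <- length_filter(cand2, cfg)
    reports[[g]] <- filter_report(g, nrow(cand), length(ids1), length(ids2),
                                  length(ids3), ids3)
    survivors <- c(survivors, ids3)
    say("genome %s: %d -> %d -> %d -> %d", g, nrow(cand), length(ids1),
        length(ids2), length(ids3))
  }
  cand <- proteomes[proteomes$id %in% survivors, , drop = FALSE]

  empty <- clade_calls(character(), character(), character())
  result <- list(filter_reports = reports, calls_gen0 = empty,
                 calls_gen1 = empty, calls_gen2 = empty,
                 motifs = empty_motif_table(), models_gen1 = list(),
                 models_gen2 = list(), hits_gen1 = NULL, hits_gen2 = NULL,
                 tandem = NULL, cfg = cfg)
  class(result) <- "stc_pipeline_result"
  if (nrow(cand) == 0L) return(result)

  # --- distance-based clade assignment ------------------------------------
  calls <- assign_clades_by_clustering(cand, seeds, seed_clades, cfg)
  say("distance assignment: %d classified, %d unclassified",
      sum(calls$clade != "unclassified"), sum(calls$clade == "unclassified"))

  # --- discriminative motifs and reassignment -----------------------------
  motif_tables <- list()
  for (cl in CLADES) {
    pos_ids <- calls$protein_id[calls$clade == cl]
    neg_ids <- calls$protein_id[calls$clade %in% setdiff(CLADES, cl)]
    if (length(pos_ids) == 0L || length(neg_ids) == 0L) next
    motif_tables[[cl]] <- discover_motifs(
      cand[match(pos_ids, cand$id), , drop = FALSE],
      cand[match(neg_ids, cand$id), , drop = FALSE], cfg, clade = cl)
  }
  motifs <- if (length(motif_tables)) do.call(rbind, unname(motif_tables))
            else empty_motif_table()
  result$motifs <- motifs
  uncl <- cand[match(calls$protein_id[calls$clade == "unclassified"],
                     cand$id), , drop = FALSE]
  if (nrow(uncl) && nrow(motifs)) {
    re <- suppressWarnings(reassign_by_motif(uncl, motifs))
    hit <- re$clade != "unclassified"
    ix <- match(re$protein_id[hit], calls$protein_id)
    calls$clade[ix] <- re$clade[hit]
    calls$evidence[ix] <- "motif"
    say("motif reassignment: %d of %d unclassified rescued", sum(hit),
        nrow(uncl))
  }
  result$calls_gen0 <- calls

  # --- generation-1 models ------------------------------------------------
  gen1 <- list()
  for (cl in CLADES) {
    keep_ev <- if (train_with_motif_calls) c("distance_cluster", "motif")
               else "distance_cluster"
    ids <- calls$protein_id[calls$clade == cl & calls$evidence %in% keep_ev]
    train <- cand[match(ids, cand$id), , drop = FALSE]
    if (include_seeds) {
      train <- rbind(train,
                     seeds[seeds$id %in%
                             names(seed_clades)[seed_clades == cl], ,
                           drop = FALSE])
    }
    if (nrow(train) < 2L) {
      stop("pipeline stage gen1_models: fewer than two training sequences for clade ",
           cl, call. = FALSE)
    }
    aln <- progressive_align(setNames(train$sequence, train$id),
                             cfg$gap_open, cfg$gap_extend)
    aln <- trim_msa(aln, cfg$trim_gap_threshold)
    gen1[[cl]] <- build_hmm(aln, name = paste0("gen1-clade", cl), clade = cl)
  }
  result$models_gen1 <- gen1

  # --- generation-1 search and calls --------------------------------------
  hits1 <- hmm_search(gen1, proteomes, cfg$hmm_bit_threshold)
  result$hits_gen1 <- hits1
  result$calls_gen1 <- assign_by_best_score(hits1)
  say("gen1 search: %d hits, %d proteins called", nrow(hits1),
      nrow(result$calls_gen1))

  # --- generation-2 refinement --------------------------------------------
  gen2 <- refine_generation2(gen1, hits1, proteomes, cfg$refine_top_k, cfg)
  result$models_gen2 <- gen2
  hits2 <- hmm_search(gen2, proteomes, cfg$hmm_bit_threshold)
  result$hits_gen2 <- hits2
  result$calls_gen2 <- assign_by_best_score(hits2)
  say("gen2 search: %d hits, %d proteins called", nrow(hits2),
      nrow(result$calls_gen2))

  # --- tandem analysis ----------------------------------------------------
  if (!is.null(gene_orders) && nrow(result$calls_gen2)) {
    final <- result$calls_gen2
    result$tandem <- detect_tandem(
      gene_orders, setNames(final$clade, final$protein_id),
      cfg$tandem_window)
  }
  result
}

#' @export
print.stc_pipeline_result <- function(x, ...) {
  cat("STC pipeline result\n")
  cat(report_table1(x))
  cat(sprintf("calls: gen0 %d, gen1 %d, gen2 %d; motifs: %d\n",
              nrow(x$calls_gen0), nrow(x$calls_gen1), nrow(x$calls_gen2),
              nrow(x$motifs)))
  invisible(x)
}

#' Per-genome filter-cascade count table
#'
#' One row per genome with the candidate counts surviving each filter, plus
#' a Total row of column sums.
#'
#' @param result A \code{stc_pipeline_result}.
#' @return TSV text (columns genome, n_input, filter1, filter2, filter3).
#' @export
report_table1 <- function(result) {
  rows <- lapply(result$filter_reports, function(r) {
    data.frame(genome = r$genome_id, n_input = r$n_input,
               filter1 = r$n_after_similarity, filter2 = r$n_after_motif,
               filter3 = r$n_after_length, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(genome = character(), n_input = integer(),
                        filter1 = integer(), filter2 = integer(),
                        filter3 = integer(), stringsAsFactors = FALSE)
  total <- data.frame(genome = "Total", n_input = sum(df$n_input),
                      filter1 = sum(df$filter1), filter2 = sum(df$filter2),
                      filter3 = sum(df$filter3), stringsAsFactors = FALSE)
  df <- rbind(df, total)
  paste0(paste(colnames(df), collapse = "\t"), "\n",
         paste(apply(df, 1L, paste, collapse = "\t"), collapse = "\n"),
         "\n")
}

#' Write the call tables of a pipeline result
#'
#' @param result A \code{stc_pipeline_result}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(sub("\n$", "", report_table1(result)),
             file.path(dir, "table1.tsv"))
  for (gen in c("gen0", "gen1", "gen2")) {
    write_tsv(result[[paste0("calls_", gen)]],
              file.path(dir, paste0("calls_", gen, ".tsv")))
  }
  write_tsv(result$motifs, file.path(dir, "motifs.tsv"))
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (nm in names(result$models_gen1)) {
    write_hmm(result$models_gen1[[nm]],
              file.path(mdir, paste0("gen1-clade", nm, ".shmm")))
  }
  for (nm in names(result$models_gen2)) {
    write_hmm(result$models_gen2[[nm]],
              file.path(mdir, paste0("gen2-clade", nm, ".shmm")))
  }
  if (!is.null(result$tandem)) {
    tandem_report_json(result$tandem, file.path(dir, "tandem.json"))
  }
  invisible(dir)
}
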