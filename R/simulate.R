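# Seeded synthetic fixtures: planted clade profile HMMs carrying the
# conserved metal-binding motifs and a clade signature motif, sampled clade
# families with controllable motif penetrance, decoy proteins
# (prenyltransferase-like, unrelated, wrong-length), and genome layouts
# with tandem STC arrangements. Everything is deterministic under a seed
# and ships with a truth table sufficient to score every pipeline stage.

DEFAULT_CLADE_MOTIFS <- c("1" = "DTSGC", "2" = "LRRENS", "3" = "DLMN",
                          "4" = "FYK")

#' Simulation specification
#'
#' @param family_size Sequences sampled per clade family.
#' @param divergence Dirichlet concentration on the consensus residue of
#'   each match column; higher is more conserved. The default gives roughly
#'   50-60 percent within-family identity and background-level cross-family
#'   identity.
#' @param planted_motifs Named character vector, clade -> signature motif.
#' @param motif_penetrance Fraction of family members carrying the clade
#'   motif.
#' @param n_prenyl,n_unrelated,n_wrong_length Decoy counts.
#' @param n_scaffolds,genes_per_scaffold Genome layout dimensions.
#' @param tandem_cluster_prob Probability that an STC gene is placed as a
#'   tandem cluster of two rather than singly.
#' @param indel_prob Per-node insert/delete probability of planted models
#'   (default 0: fixed-length families whose metal motifs are never lost to
#'   deletions).
#' @param model_len_range Inclusive range the planted model lengths are
#'   drawn from; must stay inside the exclusive (250, 500) STC length
#'   window.
#' @param seed Integer seed.
#' @return A list of class \code{sim_spec}.
#' @export
sim_spec <- function(family_size = 30L, divergence = 50,
                     planted_motifs = DEFAULT_CLADE_MOTIFS,
                     motif_penetrance = 0.9,
                     n_prenyl = 20L, n_unrelated = 20L, n_wrong_length = 20L,
                     n_scaffolds = 12L, genes_per_scaffold = 130L,
                     tandem_cluster_prob = 0.4,
                     indel_prob = 0, model_len_range = c(300L, 340L),
                     seed = 1L) {
  stopifnot(family_size >= 2L, divergence > 0,
            motif_penetrance > 0, motif_penetrance <= 1,
            all(CLADES %in% names(planted_motifs)),
            indel_prob >= 0, indel_prob < 0.5,
            model_len_range[1L] > 250L, model_len_range[2L] < 500L,
            tandem_cluster_prob >= 0, tandem_cluster_prob <= 1)
  structure(list(family_size = as.integer(family_size),
                 divergence = as.numeric(divergence),
                 planted_motifs = planted_motifs[CLADES],
                 motif_penetrance = as.numeric(motif_penetrance),
                 n_prenyl = as.integer(n_prenyl),
                 n_unrelated = as.integer(n_unrelated),
                 n_wrong_length = as.integer(n_wrong_length),
                 n_scaffolds = as.integer(n_scaffolds),
                 genes_per_scaffold = as.integer(genes_per_scaffold),
                 tandem_cluster_prob = as.numeric(tandem_cluster_prob),
                 indel_prob = as.numeric(indel_prob),
                 model_len_range = as.integer(model_len_range),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Dirichlet draw with concentration `conc` on `consensus` and 1 elsewhere
rdirichlet_consensus <- function(consensus, conc) {
  alpha <- rep(1, 20)
  alpha[consensus] <- conc
  g <- rgamma(20, shape = alpha)
  g / sum(g)
}

# fixed site layout of a planted model of length L:
#   N-half metal motif [DN]Dxx[DE] planted as "DDAAE" starting at position 25
#   clade signature motif at position floor(L * 0.45)
#   C-half metal motif NxxxSxxxE planted as "NAAASAAAE" at position L - 40
planted_layout <- function(L, motif) {
  list(nterm = list(start = 25L, residues = seq_chars("DDAAE"),
                    fixed = c(TRUE, TRUE, FALSE, FALSE, TRUE)),
       clade = list(start = as.integer(floor(L * 0.45)),
                    residues = seq_chars(motif),
                    fixed = rep(TRUE, nchar(motif))),
       cterm = list(start = L - 40L, residues = seq_chars("NAAASAAAE"),
                    fixed = c(TRUE, FALSE, FALSE, FALSE, TRUE,
                              FALSE, FALSE, FALSE, TRUE)))
}

#' Build a planted clade model
#'
#' Random Dirichlet match emissions with the metal-binding motif residues
#' pinned (emission probability 1) at fixed positions in each sequence half
#' and the clade signature motif pinned at a clade-specific position.
#' Transitions are indel-free unless \code{indel_prob} is positive.
#' Deterministic under \code{seed}.
#'
#' @param clade Clade label (1-4).
#' @param length Number of match states, in the exclusive window (250, 500).
#' @param divergence Dirichlet concentration (see \code{\link{sim_spec}}).
#' @param seed Integer seed.
#' @param motif Signature motif planted for this clade.
#' @param indel_prob Per-node insert/delete probability.
#' @return A \code{\link{profile_hmm}} with attribute \code{layout} giving
#'   the planted site positions.
#' @export
make_clade_model <- function(clade, length = 320L, divergence = 50,
                             seed = 1L,
                             motif = DEFAULT_CLADE_MOTIFS[[as_clade(clade)]],
                             indel_prob = 0) {
  clade <- as_clade(clade)
  L <- as.integer(length)
  if (L <= 250L || L >= 500L) {
    stop("planted model length must lie in (250, 500)", call. = FALSE)
  }
  set.seed(seed)
  layout <- planted_layout(L, motif)
  match_em <- matrix(0, L, 20L)
  for (k in seq_len(L)) {
    cons <- sample.int(20L, 1L)
    match_em[k, ] <- rdirichlet_consensus(cons, divergence)
  }
  # pin motif residues: emission mass 1 on the planted letter ("fixed"
  # positions); non-fixed motif positions keep their random column
  for (site in layout) {
    for (p in seq_along(site$residues)) {
      if (!site$fixed[p]) next
      k <- site$start + p - 1L
      match_em[k, ] <- 0
      match_em[k, aa_index(site$residues[p])] <- 1
    }
  }
  insert_em <- matrix(0.05, L + 1L, 20L)
  trans <- matrix(0, L + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  ip <- indel_prob
  trans[, "MM"] <- 1 - 2 * ip
  trans[, "MI"] <- ip
  trans[, "MD"] <- ip
  trans[, "IM"] <- 0.9
  trans[, "II"] <- 0.1
  trans[, "DM"] <- 0.9
  trans[, "DD"] <- 0.1
  # no deletes/inserts allowed across planted motif columns, so sampled
  # sequences always carry the motifs intact
  for (site in layout) {
    ks <- site$start + seq_along(site$residues) - 1L
    rows <- unique(c(ks - 1L, ks)) + 1L
    trans[rows, "MM"] <- 1; trans[rows, "MI"] <- 0; trans[rows, "MD"] <- 0
    trans[rows, "IM"] <- 1; trans[rows, "II"] <- 0
    trans[rows, "DM"] <- 1; trans[rows, "DD"] <- 0
  }
  # node-L bundle: exits to E
  trans[L + 1L, ] <- c(1 - ip, ip, 0, 0.9, 0.1, 1, 0)
  if (ip == 0) {
    trans[L + 1L, c("MM", "MI")] <- c(1, 0)
  }
  hmm <- profile_hmm(match_em, insert_em, trans, rep(0.05, 20),
                     name = paste0("planted-clade", clade), clade = clade)
  attr(hmm, "layout") <- layout
  hmm
}

# replace any occurrence of the given exact motifs with background residues,
# except an occurrence starting exactly at `keep_at` (0 = keep nothing)
scrub_motifs <- function(seq, motifs, keep = list()) {
  chars <- seq_chars(seq)
  repeat {
    hit <- NULL
    for (m in motifs) {
      pos <- find_pattern(paste(chars, collapse = ""), motif_pattern(m),
                          "anywhere")
      keep_at <- keep[[m]]
      if (!is.null(keep_at)) pos <- setdiff(pos, keep_at)
      if (length(pos)) { hit <- list(pos = pos[[1L]], len = nchar(m)); break }
    }
    if (is.null(hit)) return(paste(chars, collapse = ""))
    ix <- hit$pos:(hit$pos + hit$len - 1L)
    chars[ix] <- AA[sample.int(20L, hit$len, replace = TRUE)]
  }
}

#' Sample a clade family from a planted model
#'
#' Samples \code{n} sequences along the model. With probability
#' \code{1 - penetrance} the clade signature motif of a sequence is knocked
#' out (resampled from background). Accidental occurrences of any planted
#' clade motif away from its designated site are scrubbed, so the motifs
#' are discriminative by construction. Division labels alternate
#' basidiomycete / ascomycete.
#'
#' @param model A planted model from \code{\link{make_clade_model}}.
#' @param n Number of sequences.
#' @param penetrance Motif penetrance in (0, 1].
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @param genome_id Genome id for the records.
#' @param all_motifs Motifs to scrub when found away from their designated
#'   site (defaults to the four planted clade motifs).
#' @param exact_penetrance If TRUE, knock the motif out of exactly
#'   \code{round((1 - penetrance) * n)} randomly chosen members, so the
#'   realized positive fraction equals the nominal penetrance; the default
#'   (FALSE) draws knockouts independently per sequence.
#' @return Protein records with attribute \code{motif_present} (logical per
#'   sequence).
#' @export
sample_family <- function(model, n, penetrance = 0.9, seed = 1L,
                          prefix = paste0("stc", model$clade, "_"),
                          genome_id = "genome1",
                          all_motifs = DEFAULT_CLADE_MOTIFS,
                          exact_penetrance = FALSE) {
  stopifnot(n >= 1L, penetrance > 0, penetrance <= 1)
  set.seed(seed)
  layout <- attr(model, "layout")
  own <- all_motifs[[model$clade]]
  seqs <- character(n)
  present <- logical(n)
  knockout <- if (exact_penetrance) {
    ko <- sample.int(n, round((1 - penetrance) * n))
    seq_len(n) %in% ko
  } else NULL
  for (i in seq_len(n)) {
    s <- sample_hmm(model)
    present[i] <- if (is.null(knockout)) runif(1) <= penetrance
                  else !knockout[i]
    chars <- seq_chars(s)
    motif_start <- layout$clade$start
    if (!present[i]) {
      ix <- motif_start + seq_along(layout$clade$residues) - 1L
      chars[ix] <- AA[sample.int(20L, length(ix), replace = TRUE)]
    }
    keep <- if (present[i]) setNames(list(motif_start), own) else list()
    seqs[i] <- scrub_motifs(paste(chars, collapse = ""), all_motifs, keep)
  }
  rec <- protein_records(paste0(prefix, seq_len(n)), seqs,
                         genome_id = genome_id,
                         division = rep_len(c("basidiomycete", "ascomycete"), n))
  attr(rec, "motif_present") <- present
  rec
}

#' Generate decoy proteins
#'
#' Three confounder classes: \code{prenyltransferase_like} decoys are
#' random-background proteins carrying an N-half DDxxD motif but never the
#' C-terminal NxxxSxxxE; \code{unrelated} decoys are plain background
#' proteins; \code{wrong_length} decoys are clade-model samples surgically
#' shortened below 250 aa or padded above 500 aa while keeping both metal
#' motifs, so the length rule always rejects them (where exactly they exit
#' the cascade depends on how far the similarity alignment extends).
#'
#' @param kind One of the three decoy classes.
#' @param n Number of decoys.
#' @param seed Integer seed.
#' @param model Planted clade model (required for \code{wrong_length}).
#' @param genome_id Genome id for the records.
#' @return Protein records.
#' @export
make_decoys <- function(kind = c("prenyltransferase_like", "unrelated",
                                 "wrong_length"),
                        n, seed = 1L, model = NULL, genome_id = "genome1") {
  kind <- match.arg(kind)
  set.seed(seed)
  rand_seq <- function(L) paste(AA[sample.int(20L, L, replace = TRUE)],
                                collapse = "")
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (kind == "prenyltransferase_like") {
      L <- sample(280:380, 1L)
      s <- rand_seq(L)
      chars <- seq_chars(s)
      at <- sample(10:(L %/% 2L - 10L), 1L)
      chars[at:(at + 4L)] <- seq_chars("DDAAD")
      # never the C-terminal triad, and no accidental N-motif elsewhere is
      # fine - the C-term absence is what the filter keys on
      seqs[i] <- scrub_motifs(paste(chars, collapse = ""),
                              c(METAL_CTERM),
                              keep = list())
    } else if (kind == "unrelated") {
      seqs[i] <- rand_seq(sample(260:450, 1L))
    } else {
      if (is.null(model)) {
        stop("wrong_length decoys need a planted model", call. = FALSE)
      }
      s <- sample_hmm(model)
      layout <- attr(model, "layout")
      L <- nchar(s)
      if (i %% 2L == 1L) {
        # shorten: delete an internal block between the clade site and the
        # C-terminal motif, final length < 250
        del_n <- L - 240L
        del_from <- layout$clade$start + nchar(DEFAULT_CLADE_MOTIFS[[model$clade]]) + 5L
        seqs[i] <- paste0(substr(s, 1L, del_from - 1L),
                          substr(s, del_from + del_n, L))
      } else {
        # lengthen: minimal random flanks pushing the total just past 500,
        # keeping the conserved core as large a fraction as possible
        pad <- max((501L - L) %/% 2L + 1L, 1L)
        seqs[i] <- paste0(rand_seq(pad), s, rand_seq(pad))
      }
    }
  }
  protein_records(paste0(substr(kind, 1L, 6L), "_", seq_len(n)), seqs,
                  genome_id = genome_id, division = "other")
}

#' Generate a complete synthetic genome fixture
#'
#' Builds the four planted clade models, samples the clade families and
#' decoys, lays all genes out on scaffolds (STC genes singly or in tandem
#' clusters of two within four gene positions, per
#' \code{tandem_cluster_prob}), and returns the proteome, gene order and a
#' truth table scoring every pipeline stage.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return List of class \code{sim_fixture}: \code{proteome} (records),
#'   \code{loci} (gene order), \code{truth} (data frame with
#'   \code{protein_id}, \code{kind}, \code{true_clade},
#'   \code{motif_present}, \code{in_tandem}), \code{models} (the planted
#'   HMMs) and \code{seeds}/\code{seed_clades} (two reference sequences per
#'   clade for clades 1-3, three for clade 4, sampled separately from the
#'   same models, mirroring the nine characterized enzymes used as
#'   queries).
#' @export
make_genome <- function(spec = sim_spec()) {
  base_seed <- spec$seed
  # planted models (one per clade)
  models <- list()
  for (cl in CLADES) {
    len <- spec$model_len_range[1L] +
      (as.integer(cl) * 7L) %% (spec$model_len_range[2L] - spec$model_len_range[1L] + 1L)
    models[[cl]] <- make_clade_model(cl, length = len,
                                     divergence = spec$divergence,
                                     seed = base_seed + as.integer(cl),
                                     motif = spec$planted_motifs[[cl]],
                                     indel_prob = spec$indel_prob)
  }
  # seed/reference enzymes: 2 per clade for clades 1-3, 3 for clade 4
  n_seed <- c("1" = 2L, "2" = 2L, "3" = 2L, "4" = 3L)
  seeds <- list()
  for (cl in CLADES) {
    fam <- sample_family(models[[cl]], n_seed[[cl]], penetrance = 1,
                         seed = base_seed + 100L + as.integer(cl),
                         prefix = paste0("ref", cl, "_"),
                         genome_id = "reference",
                         all_motifs = spec$planted_motifs)
    fam$division <- "other"
    seeds[[cl]] <- fam
  }
  seed_recs <- do.call(rbind, unname(seeds))
  seed_clades <- setNames(rep(CLADES, times = n_seed[CLADES]), seed_recs$id)
  # clade families
  fams <- list()
  motif_present <- list()
  for (cl in CLADES) {
    fam <- sample_family(models[[cl]], spec$family_size,
                         penetrance = spec$motif_penetrance,
                         seed = base_seed + 200L + as.integer(cl),
                         prefix = paste0("stc", cl, "_"),
                         genome_id = "simgenome",
                         all_motifs = spec$planted_motifs)
    fams[[cl]] <- fam
    motif_present[[cl]] <- attr(fam, "motif_present")
  }
  # decoys
  prenyl <- make_decoys("prenyltransferase_like", spec$n_prenyl,
                        seed = base_seed + 301L, genome_id = "simgenome")
  unrel <- make_decoys("unrelated", spec$n_unrelated,
                       seed = base_seed + 302L, genome_id = "simgenome")
  wrong <- make_decoys("wrong_length", spec$n_wrong_length,
                       seed = base_seed + 303L, model = models[["1"]],
                       genome_id = "simgenome")
  proteome <- rbind(do.call(rbind, unname(fams)), prenyl, unrel, wrong)
  truth <- data.frame(
    protein_id = proteome$id,
    kind = c(rep(paste0("stc_clade", CLADES), each = spec$family_size),
             rep("prenyltransferase_like", spec$n_prenyl),
             rep("unrelated", spec$n_unrelated),
             rep("wrong_length", spec$n_wrong_length)),
    true_clade = c(rep(CLADES, each = spec$family_size),
                   rep("unclassified",
                       spec$n_prenyl + spec$n_unrelated + spec$n_wrong_length)),
    motif_present = c(unlist(motif_present),
                      rep(NA, spec$n_prenyl + spec$n_unrelated +
                            spec$n_wrong_length)),
    stringsAsFactors = FALSE)
  # genome layout
  set.seed(base_seed + 400L)
  layout <- place_genes(proteome$id, truth$true_clade %in% CLADES,
                        spec$n_scaffolds, spec$genes_per_scaffold,
                        spec$tandem_cluster_prob, genome_id = "simgenome")
  truth$in_tandem <- unname(layout$in_tandem[truth$protein_id])
  structure(list(proteome = proteome, loci = layout$loci, truth = truth,
                 models = models, seeds = seed_recs,
                 seed_clades = seed_clades, spec = spec),
            class = "sim_fixture")
}

# place genes on scaffolds; STC genes go singly or as adjacent tandem pairs
# (ordinal gap 1-4); returns loci + named logical of tandem-truth membership
place_genes <- function(ids, is_stc, n_scaffolds, genes_per_scaffold,
                        tandem_cluster_prob, genome_id) {
  stc_ids <- ids[is_stc]
  other_ids <- ids[!is_stc]
  if (length(other_ids) > 1L) {
    other_ids <- other_ids[sample.int(length(other_ids))]
  }
  # decide tandem pairing of STC genes
  in_tandem <- setNames(rep(FALSE, length(ids)), ids)
  groups <- list()
  i <- 1L
  while (i <= length(stc_ids)) {
    if (i < length(stc_ids) && runif(1) < tandem_cluster_prob) {
      groups[[length(groups) + 1L]] <- stc_ids[c(i, i + 1L)]
      in_tandem[stc_ids[c(i, i + 1L)]] <- TRUE
      i <- i + 2L
    } else {
      groups[[length(groups) + 1L]] <- stc_ids[i]
      i <- i + 1L
    }
  }
  # shuffle group placement order; non-STC genes are fillers
  groups <- groups[sample.int(length(groups))]
  # 9 slots per group: a pair may span ordinals (k, k+4), and the next
  # group starts at k+9, so genes of different groups are always more than
  # the tandem window apart - the planted layout IS the detectable layout
  slots_per_group <- 9L
  total_slots <- n_scaffolds * genes_per_scaffold
  need <- length(groups) * slots_per_group + 6L * length(other_ids)
  if (need > total_slots) {
    stop("genome layout too small for the requested STC placement",
         call. = FALSE)
  }
  rows <- list()
  filler_i <- 0L
  other_i <- 0L
  gi <- 1L
  for (sc in seq_len(n_scaffolds)) {
    ord <- 1L
    while (ord <= genes_per_scaffold) {
      remaining <- genes_per_scaffold - ord + 1L
      if (gi <= length(groups) && remaining >= slots_per_group) {
        g <- groups[[gi]]; gi <- gi + 1L
        if (length(g) == 2L) {
          gap <- sample(1:4, 1L)
          pos <- c(ord, ord + gap)
        } else {
          pos <- ord
        }
        for (p in seq_along(g)) {
          rows[[length(rows) + 1L]] <- data.frame(
            genome_id = genome_id, scaffold = paste0("scaffold_", sc),
            ordinal = pos[p], strand = sample(c("+", "-"), 1L),
            protein_id = g[p], stringsAsFactors = FALSE)
        }
        # spacing slots inside a group block are anonymous filler genes, so
        # decoy proteins never sit within the tandem window of an STC gene
        for (o in setdiff(ord:(ord + slots_per_group - 1L), pos)) {
          filler_i <- filler_i + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            genome_id = genome_id, scaffold = paste0("scaffold_", sc),
            ordinal = o, strand = sample(c("+", "-"), 1L),
            protein_id = sprintf("filler_%04d", filler_i),
            stringsAsFactors = FALSE)
        }
        ord <- ord + slots_per_group
      } else if (other_i < length(other_ids) && remaining >= 6L) {
        # decoy/other proteins, each padded with five filler genes so two
        # decoys are never within the tandem window of each other either
        other_i <- other_i + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = genome_id, scaffold = paste0("scaffold_", sc),
          ordinal = ord, strand = sample(c("+", "-"), 1L),
          protein_id = other_ids[other_i], stringsAsFactors = FALSE)
        for (o in (ord + 1L):(ord + 5L)) {
          filler_i <- filler_i + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            genome_id = genome_id, scaffold = paste0("scaffold_", sc),
            ordinal = o, strand = sample(c("+", "-"), 1L),
            protein_id = sprintf("filler_%04d", filler_i),
            stringsAsFactors = FALSE)
        }
        ord <- ord + 6L
      } else {
        filler_i <- filler_i + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = genome_id, scaffold = paste0("scaffold_", sc),
          ordinal = ord, strand = sample(c("+", "-"), 1L),
          protein_id = sprintf("filler_%04d", filler_i),
          stringsAsFactors = FALSE)
        ord <- ord + 1L
      }
    }
  }
  loci <- gene_loci(do.call(rbind, rows))
  list(loci = loci, in_tandem = in_tandem)
}

#' Write a fixture to disk
#'
#' Writes \code{proteome.faa}, \code{seeds.faa}, \code{seed_clades.tsv},
#' \code{genes.tsv}, \code{truth.tsv} and the planted models under
#' \code{models/}.
#'
#' @param fixture A \code{sim_fixture} from \code{\link{make_genome}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fixture$proteome, file.path(dir, "proteome.faa"))
  write_fasta(fixture$seeds, file.path(dir, "seeds.faa"))
  writeLines(paste(names(fixture$seed_clades), fixture$seed_clades,
                   sep = "\t"),
             file.path(dir, "seed_clades.tsv"))
  write.table(fixture$loci, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(fixture$truth, file.path(dir, "truth.tsv"))
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (cl in names(fixture$models)) {
    write_hmm(fixture$models[[cl]],
              file.path(mdir, paste0("planted-clade", cl, ".shmm")))
  }
  invisible(dir)
}
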