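# Metal-binding motif rules, discriminative motif discovery, reassignment.

test_that("pattern matching honours wildcards, groups and regions", {
  s <- paste0(strrep("A", 10), "NDLLE", strrep("A", 385))  # match at 11
  expect_equal(find_pattern(s, "[DN]Dxx[DE]", "nterm"), 11L)
  expect_length(find_pattern(s, "[DN]Dxx[DE]", "cterm"), 0L)

  expect_equal(find_pattern("DDAAAE", "DDxxxE"), 1L)
  expect_equal(find_pattern("NKLASQWVE", "NxxxSxxxE"), 1L)

  # overlapping matches are all reported
  expect_equal(find_pattern("DDDDE", "[DN]Dxx[DE]"), 1L)
  expect_equal(find_pattern("ADDADDADD", "DD"), c(2L, 5L, 8L))

  # X never matches a literal but is matched by the wildcard
  expect_length(find_pattern("DXAAE", "[DN]Dxx[DE]"), 0L)
  expect_equal(find_pattern("DDXXE", "DDxx[DE]"), 1L)
})

test_that("region split is at floor(L/2)", {
  # length 9: first half = positions 1..4, second = 5..9
  expect_equal(find_pattern("AADDAAAEA", "DD", "nterm"), 3L)
  expect_length(find_pattern("AAADDAAEA", "DD", "cterm"), 0L)
  expect_equal(find_pattern("AAAADDAEA", "DD", "cterm"), 5L)
})

test_that("metal-binding filter is a strict conjunction of both termini", {
  both <- paste0(strrep("A", 20), "DDAAE", strrep("A", 150),
                 "NAAASAAAE", strrep("A", 30))
  no_cterm <- paste0(strrep("A", 20), "DDAAD", strrep("A", 180))
  no_nterm <- paste0(strrep("A", 170), "NAAASAAAE", strrep("A", 30))
  alt_nterm <- paste0(strrep("A", 20), "DDGGGE", strrep("A", 150),
                      "NAAASAAAE", strrep("A", 30))
  recs <- protein_records(c("both", "prenyl", "cterm_only", "alt"),
                          c(both, no_cterm, no_nterm, alt_nterm))
  expect_equal(metal_binding_filter(recs), c("both", "alt"))
})

test_that("prenyltransferase-like decoys are rejected by the motif filter", {
  decoys <- make_decoys("prenyltransferase_like", 15, seed = 9)
  expect_length(metal_binding_filter(decoys), 0L)
})

test_that("discovery returns the discriminative motif of the worked example", {
  pos <- protein_records(c("p1", "p2"), c("KKLRRENSA", "LRRENSWWW"))
  neg <- protein_records("n1", "KKLRRENAA")
  got <- discover_motifs(pos, neg, pipeline_config())
  expect_equal(got$pattern, "LRRENS")
  expect_equal(got$positive_freq, 1.0)
  expect_equal(got$n_neg_with, 0L)
})

test_that("discovery with positives equal to negatives finds nothing", {
  pos <- protein_records("p1", "KKLRRENSA")
  neg <- protein_records("n1", "KKLRRENSA")
  expect_equal(nrow(discover_motifs(pos, neg)), 0L)
})

test_that("discovery requires a non-empty negative set", {
  pos <- protein_records("p1", "KKLRRENSA")
  expect_error(discover_motifs(pos, pos[0, ]), "negative")
})

test_that("only maximal motifs are reported", {
  # DTSG and DTSGC share identical support; DTSGCW is rarer
  pos <- protein_records(paste0("p", 1:5),
                         c("ADTSGCWAA", "KDTSGCKKK", "WDTSGCAAK",
                           "KKDTSGCWK", "AAAKKKWWA"))
  neg <- protein_records("n1", "AKWAKWAKW")
  got <- discover_motifs(pos, neg,
                         pipeline_config(motif_min_freq = 0.75,
                                         motif_kmin = 3, motif_kmax = 5))
  expect_true("DTSGC" %in% got$pattern)
  expect_false("DTSG" %in% got$pattern)
  expect_false("TSGC" %in% got$pattern)
})

test_that("discovery matches the brute-force enumerator on small alphabets", {
  set.seed(505)
  alpha <- c("A", "C", "D", "E", "F", "G")
  for (trial in 1:25) {
    npos <- sample(3:6, 1)
    nneg <- sample(2:4, 1)
    pos <- vapply(seq_len(npos), function(i)
      rand_string(sample(10:30, 1), alpha), character(1))
    neg <- vapply(seq_len(nneg), function(i)
      rand_string(sample(10:30, 1), alpha), character(1))
    cfg <- pipeline_config(motif_min_freq = sample(c(0.5, 0.75, 1), 1),
                           motif_kmin = 3, motif_kmax = sample(4:6, 1))
    got <- discover_motifs(protein_records(paste0("p", seq_len(npos)), pos),
                           protein_records(paste0("n", seq_len(nneg)), neg),
                           cfg)
    want <- oracle_discover(pos, neg, cfg$motif_kmin, cfg$motif_kmax,
                            cfg$motif_min_freq)
    expect_setequal(got$pattern, want)
    # soundness: zero matches in every negative, rechecked by scan
    for (m in got$pattern) {
      expect_false(any(grepl(m, neg, fixed = TRUE)))
    }
  }
})

test_that("a motif planted above the frequency threshold is always recovered", {
  cfg <- pipeline_config()
  for (trial in 1:5) {
    mod <- make_clade_model("2", 300, 50, seed = 600 + trial)
    pos <- sample_family(mod, 20, penetrance = 0.9, seed = 700 + trial)
    neg_mod <- make_clade_model("4", 310, 50, seed = 800 + trial)
    neg <- sample_family(neg_mod, 20, penetrance = 0.9, seed = 900 + trial,
                         prefix = "neg_")
    planted_frac <- mean(attr(pos, "motif_present"))
    if (planted_frac >= cfg$motif_min_freq) {
      got <- discover_motifs(pos, neg, cfg)
      expect_true("LRRENS" %in% got$pattern, info = paste("trial", trial))
      # and discovery reports its true positive frequency
      expect_equal(got$positive_freq[got$pattern == "LRRENS"], planted_frac)
    }
  }
})

test_that("motif reassignment requires an unambiguous single-clade match", {
  motifs <- data.frame(
    pattern = c("DTSGC", "LRRENS", "DLMN", "FYK"),
    positive_freq = c(0.95, 1.0, 0.77, 0.92),
    n_pos_with = c(19L, 20L, 15L, 18L), n_neg_with = 0L,
    clade = c("1", "2", "3", "4"), stringsAsFactors = FALSE)
  recs <- protein_records(
    c("only2", "both34", "none"),
    c(paste0(strrep("A", 50), "LRRENS", strrep("A", 50)),
      paste0(strrep("A", 30), "FYK", strrep("A", 30), "DLMN", strrep("A", 30)),
      strrep("AK", 50)))
  calls <- reassign_by_motif(recs, motifs)
  expect_equal(calls$clade, c("2", "unclassified", "unclassified"))
  expect_equal(calls$evidence, rep("motif", 3))
})

test_that("clade-call construction enforces the score/evidence invariant", {
  expect_error(clade_calls("p", "1", "motif", score = 30), "score")
  expect_error(clade_calls("p", "1", "hmm_best_score"), "score")
  ok <- clade_calls("p", "2", "hmm_best_score", score = 31)
  expect_equal(ok$score, 31)
})
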