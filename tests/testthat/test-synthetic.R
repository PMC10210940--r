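# The seeded fixture generator: determinism, planted structure, decoys,
# layouts.

test_that("planted models are deterministic and carry their motifs", {
  m1 <- make_clade_model("2", 300, 50, seed = 5)
  m2 <- make_clade_model("2", 300, 50, seed = 5)
  expect_identical(m1$match_emissions, m2$match_emissions)
  expect_identical(m1$transitions, m2$transitions)
  # argmax at the planted motif positions equals the motif letters
  layout <- attr(m1, "layout")
  ix <- layout$clade$start + seq_along(layout$clade$residues) - 1L
  argmax <- AA20[apply(m1$match_emissions[ix, , drop = FALSE], 1, which.max)]
  expect_equal(paste(argmax, collapse = ""), "LRRENS")
  expect_error(make_clade_model("1", 200), "length")
  expect_error(make_clade_model("1", 600), "length")
})

test_that("high divergence collapses sampled sequences onto the consensus", {
  m <- make_clade_model("1", 300, 1e7, seed = 6)
  s1 <- sample_family(m, 2, penetrance = 1, seed = 8)
  expect_identical(s1$sequence[1], s1$sequence[2])
})

test_that("sampled families are deterministic and length-stable", {
  m <- make_clade_model("4", 310, 50, seed = 9)
  a <- sample_family(m, 6, penetrance = 0.9, seed = 10)
  b <- sample_family(m, 6, penetrance = 0.9, seed = 10)
  expect_identical(a$sequence, b$sequence)
  expect_identical(attr(a, "motif_present"), attr(b, "motif_present"))
  # indel-free default: every sampled length equals the model length,
  # inside the exclusive STC window
  expect_true(all(nchar(a$sequence) == 310))
  expect_equal(a$division[1:4],
               c("basidiomycete", "ascomycete", "basidiomycete", "ascomycete"))
})

test_that("penetrance controls the planted motif fraction", {
  m <- make_clade_model("2", 300, 50, seed = 11)
  fam <- sample_family(m, 400, penetrance = 0.9, seed = 12)
  present <- attr(fam, "motif_present")
  expect_equal(mean(present), 0.9, tolerance = 0.04)
  has <- grepl("LRRENS", fam$sequence, fixed = TRUE)
  expect_identical(has, present)
  # full penetrance
  fam1 <- sample_family(m, 30, penetrance = 1, seed = 13)
  expect_true(all(grepl("LRRENS", fam1$sequence, fixed = TRUE)))
})

test_that("cross-clade motif leakage is scrubbed", {
  spec_motifs <- c("1" = "DTSGC", "2" = "LRRENS", "3" = "DLMN", "4" = "FYK")
  for (cl in c("1", "3")) {
    m <- make_clade_model(cl, 300, 50, seed = 14)
    fam <- sample_family(m, 40, penetrance = 1, seed = 15)
    for (other in setdiff(names(spec_motifs), cl)) {
      expect_false(any(grepl(spec_motifs[[other]], fam$sequence,
                             fixed = TRUE)),
                   info = paste("clade", cl, "motif", other))
    }
  }
})

test_that("decoy classes have their designed failure modes", {
  prenyl <- make_decoys("prenyltransferase_like", 12, seed = 16)
  expect_length(metal_binding_filter(prenyl), 0L)
  # but they do carry an N-half DDxxD
  expect_true(all(vapply(prenyl$sequence, function(s)
    length(find_pattern(s, "DDxxD", "nterm")) > 0, logical(1))))

  mod <- make_clade_model("1", 320, 50, seed = 17)
  wrong <- make_decoys("wrong_length", 10, seed = 18, model = mod)
  L <- nchar(wrong$sequence)
  expect_true(all(L <= 250 | L >= 500))
  expect_length(length_filter(wrong), 0L)
  # they still carry both metal motifs
  expect_equal(metal_binding_filter(wrong), wrong$id)

  unrel <- make_decoys("unrelated", 10, seed = 19)
  expect_true(all(nchar(unrel$sequence) >= 260))
})

test_that("unrelated decoys stay below the gathering threshold", {
  fx <- small_families(n_per_clade = 8L)
  models <- lapply(c("1", "2", "3", "4"), function(cl) {
    fam <- fx$candidates[fx$truth == cl, ]
    build_hmm(trim_msa(progressive_align(fam)), clade = cl)
  })
  unrel <- make_decoys("unrelated", 8, seed = 20)
  hits <- hmm_search(models, unrel, threshold = 25)
  expect_equal(nrow(hits), 0L)
})

test_that("genome fixtures are byte-deterministic under the seed", {
  s <- sim_spec(family_size = 4L, n_prenyl = 3L, n_unrelated = 3L,
                n_wrong_length = 2L, n_scaffolds = 6L,
                genes_per_scaffold = 40L, seed = 77L)
  a <- make_genome(s)
  b <- make_genome(s)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$loci, b$loci)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(a, d1)
  write_fixture(b, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("tandem placement probability drives the truth layout", {
  s0 <- sim_spec(family_size = 6L, n_prenyl = 2L, n_unrelated = 2L,
                 n_wrong_length = 2L, tandem_cluster_prob = 0,
                 n_scaffolds = 6L, genes_per_scaffold = 50L, seed = 21L)
  fx0 <- make_genome(s0)
  stc <- fx0$truth[fx0$truth$true_clade != "unclassified", ]
  rep0 <- detect_tandem(fx0$loci,
                        setNames(stc$true_clade, stc$protein_id), 4)
  expect_equal(rep0$n_tandem_pairs, 0L)
  expect_false(any(fx0$truth$in_tandem[fx0$truth$true_clade != "unclassified"]))

  s1 <- sim_spec(family_size = 6L, n_prenyl = 2L, n_unrelated = 2L,
                 n_wrong_length = 2L, tandem_cluster_prob = 1,
                 n_scaffolds = 8L, genes_per_scaffold = 40L, seed = 22L)
  fx1 <- make_genome(s1)
  stc1 <- fx1$truth[fx1$truth$true_clade != "unclassified", ]
  rep1 <- detect_tandem(fx1$loci,
                        setNames(stc1$true_clade, stc1$protein_id), 4)
  expect_equal(rep1$fraction_in_tandem, 1.0)
  # fixture truth agrees with the detector on the truth calls
  expect_setequal(unlist(rep1$clusters),
                  stc1$protein_id[stc1$in_tandem])
  # planted pairs are within-family, so truth pairs share their clade
  expect_equal(rep1$fraction_pairs_same_clade, 1.0)
})
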