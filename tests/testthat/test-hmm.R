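# Profile-HMM construction, glocal scoring, search, best-score assignment,
# refinement and serialization.

one_state_hmm <- function(pA = 0.9, letter = "A") {
  me <- matrix((1 - pA) / 19, 1, 20)
  me[1, match(letter, AA20)] <- pA
  ie <- matrix(0.05, 2, 20)
  tr <- matrix(0, 2, 7)
  tr[1, ] <- c(1, 0, 0, 1, 0, 0, 0)   # B -> M1 surely
  tr[2, ] <- c(1, 0, 0, 1, 0, 1, 0)   # M1 -> E surely
  profile_hmm(me, ie, tr)
}

test_that("single-state closed forms are exact", {
  h <- one_state_hmm(0.9, "A")
  expect_equal(score_sequence(h, "A"), log2(0.9 / 0.05), tolerance = 1e-12)
  h2 <- one_state_hmm(0.1, "C")
  expect_equal(score_sequence(h2, "C"), 1.0, tolerance = 1e-12)
  # X emits background: 0 bits from emission, so score is 0
  expect_equal(score_sequence(h, "X"), 0, tolerance = 1e-12)
})

test_that("emission estimation uses +1 pseudocounts over 20 residues", {
  m <- msa(paste0("s", 1:4), c("AG", "AG", "AG", "CG"))
  h <- build_hmm(m)
  expect_equal(h$L, 2L)
  expect_equal(h$match_emissions[1, match("A", AA20)], 4 / 24)
  expect_equal(h$match_emissions[1, match("C", AA20)], 2 / 24)
  expect_equal(h$match_emissions[1, match("W", AA20)], 1 / 24)
  expect_equal(rowSums(h$match_emissions), rep(1, 2))
  expect_equal(rowSums(h$insert_emissions), rep(1, 3))
})

test_that("columns with gap fraction at or above one half become inserts", {
  # column 2 has 3 gaps of 4 rows -> insert region, so L = 2
  m <- msa(paste0("s", 1:4), c("AWG", "A-G", "A-G", "A-G"))
  h <- build_hmm(m)
  expect_equal(h$L, 2L)
  # column at exactly 0.5 gaps is also an insert (< 0.5 rule)
  m2 <- msa(paste0("s", 1:4), c("AWG", "AWG", "A-G", "A-G"))
  expect_equal(build_hmm(m2)$L, 2L)
  expect_error(build_hmm(msa(c("a", "b", "c"), c("A", "-", "-"))),
               "no match states")
})

test_that("viterbi and forward match brute-force path enumeration", {
  set.seed(909)
  for (trial in 1:40) {
    L <- sample(1:4, 1)
    h <- random_small_hmm(L, seed = 1000 + trial)
    seq <- rand_string(sample(1:6, 1))
    want <- oracle_hmm_scores(h, seq)
    expect_equal(score_sequence(h, seq, "viterbi"), unname(want["viterbi"]),
                 tolerance = 1e-9, info = paste("trial", trial, seq))
    expect_equal(score_sequence(h, seq, "forward"), unname(want["forward"]),
                 tolerance = 1e-9, info = paste("trial", trial, seq))
  }
})

test_that("forward dominates viterbi and flanks are near-free", {
  h <- random_small_hmm(4, seed = 33)
  set.seed(34)
  for (i in 1:20) {
    s <- rand_string(sample(2:8, 1))
    v <- score_sequence(h, s, "viterbi")
    f <- score_sequence(h, s, "forward")
    expect_gte(f, v - 1e-12)
    # background-residue padding cannot lower the viterbi score
    padded <- paste0(rand_string(3), s, rand_string(3))
    expect_gte(score_sequence(h, padded, "viterbi"), v - 1e-12)
  }
})

test_that("a rebuilt model recovers the planted consensus and separates true from shuffled", {
  mod <- make_clade_model("3", 300, 50, seed = 41)
  fam <- sample_family(mod, 120, penetrance = 0.9, seed = 42)
  aln <- progressive_align(fam)
  rebuilt <- build_hmm(trim_msa(aln), clade = "3")
  # per-column argmax recovery (match states align 1:1 here)
  expect_equal(rebuilt$L, mod$L)
  agree <- mean(apply(rebuilt$match_emissions, 1, which.max) ==
                  apply(mod$match_emissions, 1, which.max))
  expect_gte(agree, 0.95)
  # held-out sequences score far above the gathering threshold
  held <- sample_family(mod, 10, penetrance = 0.9, seed = 43, prefix = "h_")
  set.seed(44)
  for (s in held$sequence) {
    expect_gte(score_sequence(rebuilt, s), 25)
    shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_lt(score_sequence(rebuilt, shuf), 25)
  }
})

test_that("hmm_search applies the gathering threshold", {
  fx <- small_families(n_per_clade = 4L)
  models <- lapply(c("1", "3"), function(cl) {
    fam <- fx$candidates[fx$truth == cl, ]
    build_hmm(trim_msa(progressive_align(fam)),
              name = paste0("m", cl), clade = cl)
  })
  hits <- hmm_search(models, fx$candidates[c(1, 2, 9, 10), ], threshold = 25)
  expect_true(all(hits$bit_score >= 25))
  expect_true(all(c("1", "3") %in% hits$clade))
  expect_equal(nrow(hmm_search(models, fx$candidates[1:2, ],
                               threshold = Inf)), 0L)
})

test_that("best-score assignment takes the maximum and ties go unclassified", {
  hits <- data.frame(
    protein_id = c("p1", "p1", "p2", "p3", "p3"),
    model_name = c("a", "b", "b", "a", "c"),
    clade = c("1", "3", "2", "1", "4"),
    bit_score = c(40, 55, 31, 33, 33), stringsAsFactors = FALSE)
  expect_warning(calls <- assign_by_best_score(hits), "tie")
  expect_equal(calls$clade[calls$protein_id == "p1"], "3")
  expect_equal(calls$clade[calls$protein_id == "p2"], "2")
  expect_equal(calls$clade[calls$protein_id == "p3"], "unclassified")
  expect_equal(calls$evidence, rep("hmm_best_score", 3))
  # a same-clade tie is not ambiguous
  hits2 <- data.frame(protein_id = "q", model_name = c("a", "a2"),
                      clade = c("2", "2"), bit_score = c(30, 30),
                      stringsAsFactors = FALSE)
  expect_no_warning(calls2 <- assign_by_best_score(hits2))
  expect_equal(calls2$clade, "2")
})

test_that("refinement pools top-k per division and rejects empty clades", {
  fx <- small_families()
  models <- lapply(c("1", "2", "3", "4"), function(cl) {
    fam <- fx$candidates[fx$truth == cl, ]
    build_hmm(trim_msa(progressive_align(fam)),
              name = paste0("gen1-", cl), clade = cl)
  })
  hits <- hmm_search(models, fx$candidates, threshold = 25)
  gen2 <- refine_generation2(models, hits, fx$candidates, top_k = 3)
  expect_named(gen2, c("1", "2", "3", "4"))
  # top_k = 3 per division -> at most 6 training sequences per clade
  expect_error(refine_generation2(models, hits, fx$candidates, top_k = 0),
               "top_k")
  hits_no4 <- hits[hits$clade != "4", ]
  expect_error(refine_generation2(models, hits_no4, fx$candidates, 3),
               "clade 4")
})

test_that("generation-2 models are at least as accurate as generation 1", {
  fx <- small_families()
  gen1 <- lapply(c("1", "2", "3", "4"), function(cl) {
    fam <- fx$candidates[fx$truth == cl, ][1:6, ]  # deliberately small
    build_hmm(trim_msa(progressive_align(fam)),
              name = paste0("gen1-", cl), clade = cl)
  })
  hits1 <- hmm_search(gen1, fx$candidates, threshold = 25)
  gen2 <- refine_generation2(gen1, hits1, fx$candidates, top_k = 100)
  hits2 <- hmm_search(gen2, fx$candidates, threshold = 25)
  acc <- function(calls) {
    ix <- match(calls$protein_id, fx$candidates$id)
    mean(calls$clade == fx$truth[ix]) * nrow(calls) / nrow(fx$candidates)
  }
  a1 <- acc(assign_by_best_score(hits1))
  a2 <- acc(assign_by_best_score(hits2))
  expect_gte(a2, a1)
})

test_that("HMM text serialization round-trips bit-exactly", {
  fx <- small_families(n_per_clade = 4L)
  fam <- fx$candidates[fx$truth == "2", ]
  h <- build_hmm(trim_msa(progressive_align(fam)), name = "rt", clade = "2")
  f <- withr::local_tempfile(fileext = ".shmm")
  write_hmm(h, f)
  back <- read_hmm(f)
  expect_identical(back$match_emissions, h$match_emissions)
  expect_identical(back$insert_emissions, h$insert_emissions)
  expect_identical(unname(back$transitions), unname(h$transitions))
  expect_identical(back$background, h$background)
  expect_equal(back$name, "rt")
  expect_equal(back$clade, "2")
  # scoring through the round-trip is unchanged
  s <- fam$sequence[1]
  expect_identical(score_sequence(back, s), score_sequence(h, s))
})

test_that("malformed HMM files are rejected with a line number", {
  h <- one_state_hmm()
  f <- withr::local_tempfile(fileext = ".shmm")
  write_hmm(h, f)
  lines <- readLines(f)
  # corrupt an emission row so it no longer sums to one
  i <- grep("^MATCH 1 ", lines)[1]
  parts <- strsplit(lines[i], " ")[[1]]
  parts[3] <- sprintf("%.17g", log(0.5))
  lines[i] <- paste(parts, collapse = " ")
  writeLines(lines, f)
  expect_error(read_hmm(f), "sums to")

  writeLines(c("SHMM1", "NAME x"), f)
  expect_error(read_hmm(f), "line")

  writeLines(sub("SHMM1", "NOPE", readLines(f)), f)
  expect_error(read_hmm(f), "line 1")
})

test_that("a hand-written one-state model file scores by the closed form", {
  h <- one_state_hmm(0.9, "A")
  f <- withr::local_tempfile(fileext = ".shmm")
  write_hmm(h, f)
  expect_equal(score_sequence(read_hmm(f), "A"), log2(0.9 / 0.05),
               tolerance = 1e-12)
})
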