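# Progressive alignment, trimming, category distances, UPGMA, and
# cluster-based clade assignment.

test_that("identical sequences align without gaps", {
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  aln <- progressive_align(setNames(rep(s, 5), paste0("s", 1:5)))
  expect_equal(aln$column_count, nchar(s))
  expect_true(all(aln$rows == s))
})

test_that("two-sequence alignment equals global DP under the same scoring", {
  sub <- stcminer:::profile_submatrix()
  set.seed(606)
  for (i in 1:30) {
    a <- rand_string(sample(4:10, 1))
    b <- rand_string(sample(4:10, 1))
    aln <- progressive_align(c(x = a, y = b))
    expect_equal(msa_pair_score(aln, sub, 2.3, 0.63),
                 oracle_nw_score(a, b, sub, 2.3, 0.63),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("degapping alignment rows reproduces the inputs exactly", {
  fx <- small_families(n_per_clade = 4L)
  seqs <- setNames(fx$candidates$sequence, fx$candidates$id)
  aln <- progressive_align(seqs)
  expect_identical(degap(aln)[names(seqs)], seqs)
})

test_that("conserved same-model families align tightly", {
  mod <- make_clade_model("1", 300, 1000, seed = 13, indel_prob = 0.002)
  fam <- sample_family(mod, 3, penetrance = 1, seed = 14)
  aln <- progressive_align(fam)
  expect_lte(aln$column_count, 310)
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(mean(mat[i, ] == mat[j, ]), 0.9)
  }
})

test_that("trimming keeps columns at the gap-fraction boundary", {
  m <- msa(paste0("s", 1:4), c("A-CA", "A-CA", "AAC-", "AA-A"))
  # gap fractions: 0, 0.5, 0.25, 0.25 -> all kept at threshold 0.5
  t1 <- trim_msa(m, 0.5)
  expect_equal(t1$column_count, 4L)
  # threshold 0.25: column 2 (0.5 gaps) removed
  t2 <- trim_msa(m, 0.25)
  expect_equal(t2$column_count, 3L)
  expect_equal(t2$rows[1], "ACA")
  # 3 gaps of 4 -> removed at 0.5
  m2 <- msa(paste0("s", 1:4), c("AC", "A-", "A-", "A-"))
  expect_equal(trim_msa(m2, 0.5)$rows[1], "A")
  # idempotence and the gap-free case
  expect_identical(trim_msa(t2, 0.25)$rows, t2$rows)
  m3 <- msa(c("a", "b"), c("ACD", "ACD"))
  expect_identical(trim_msa(m3)$rows, m3$rows)
  expect_error(trim_msa(msa(c("a", "b"), c("A-", "-A")), 0.25),
               "fully trimmed")
})

test_that("trimming is column-monotone in the threshold", {
  fx <- small_families(n_per_clade = 4L)
  aln <- progressive_align(setNames(fx$candidates$sequence[1:8],
                                    fx$candidates$id[1:8]))
  prev <- -1L
  for (thr in c(0.1, 0.3, 0.5, 0.9)) {
    cols <- tryCatch(trim_msa(aln, thr)$column_count, error = function(e) 0L)
    expect_gte(cols, prev)
    prev <- cols
  }
})

test_that("category distance follows the stated site scoring", {
  expect_equal(category_distance(msa(c("a", "b"), c("CM", "CM")))["a", "b"], 0)
  # sites: identical (0) + same category M/V (0.5) -> D = 0.25
  d <- category_distance(msa(c("a", "b"), c("CM", "CV")))
  expect_equal(d["a", "b"], -log(0.75), tolerance = 1e-12)
  # all different categories -> capped
  expect_equal(category_distance(msa(c("a", "b"), c("CC", "WW")))["a", "b"], 10)
  # X counts 1.0 even against itself
  expect_equal(category_distance(msa(c("a", "b"), c("XA", "XA")))["a", "b"],
               -log(0.5), tolerance = 1e-12)
  # gaps are excluded from the shared sites
  d2 <- category_distance(msa(c("a", "b"), c("C-M", "CVM")))
  expect_equal(d2["a", "b"], 0)
})

test_that("a pair with no shared columns is capped with a warning", {
  m <- msa(c("a", "b", "c"), c("A-", "-A", "AA"))
  expect_warning(d <- category_distance(m), "no shared")
  expect_equal(d["a", "b"], 10)
})

test_that("UPGMA reproduces hand-derived merges and heights", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.2)

  ids <- c("A", "B", "C")
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3, dimnames = list(ids, ids))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(0.1, 0.3))
  expect_setequal(t3$labels[t3$leaf_sets[[1]]], c("A", "B"))
})

test_that("UPGMA heights match average-linkage hclust", {
  skip_if_not_installed("phangorn")
  set.seed(707)
  n <- 12
  x <- matrix(rnorm(n * 4), n)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:n], letters[1:n])
  ours <- upgma(d)
  theirs <- hclust(as.dist(d), method = "average")
  expect_equal(sort(ours$height * 2), sort(theirs$height), tolerance = 1e-12)
})

test_that("UPGMA topology is invariant to input permutation", {
  set.seed(808)
  n <- 9
  x <- matrix(rnorm(n * 3), n)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  t1 <- upgma(d)
  p <- sample(n)
  t2 <- upgma(d[p, p])
  sets1 <- lapply(t1$leaf_sets, function(s) sort(t1$labels[s]))
  sets2 <- lapply(t2$leaf_sets, function(s) sort(t2$labels[s]))
  expect_setequal(vapply(sets1, paste, character(1), collapse = ","),
                  vapply(sets2, paste, character(1), collapse = ","))
  expect_equal(sort(t1$height), sort(t2$height))
})

test_that("clade assignment recovers planted families without cross errors", {
  fx <- small_families()
  calls <- assign_clades_by_clustering(fx$candidates, fx$references,
                                       fx$ref_clades)
  assigned <- calls$clade != "unclassified"
  expect_gte(mean(assigned), 0.9)
  expect_true(all(calls$clade[assigned] == fx$truth[assigned]))
})

test_that("mixed-reference clusters leave candidates unclassified", {
  # two references of different clades made identical: any candidate whose
  # smallest reference cluster holds both must stay unclassified
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 15)
  mod <- make_clade_model("1", 300, 50, seed = 21)
  cand <- sample_family(mod, 2, penetrance = 1, seed = 22)
  refs <- protein_records(c("r1", "r3", "r2", "r4"),
                          c(cand$sequence[1], cand$sequence[1],
                            s, paste0(substr(s, 1, 280), "WWWWWWWWWWWWWWWWWWWW")))
  calls <- assign_clades_by_clustering(
    cand[1, , drop = FALSE], refs,
    c(r1 = "1", r3 = "3", r2 = "2", r4 = "4"))
  expect_equal(calls$clade, "unclassified")
})

test_that("assignment never invents a clade absent from the references", {
  fx <- small_families()
  calls <- assign_clades_by_clustering(fx$candidates[1:6, ], fx$references,
                                       fx$ref_clades)
  expect_true(all(calls$clade %in% c("1", "2", "3", "4", "unclassified")))
  expect_error(assign_clades_by_clustering(
    fx$candidates[1:2, ], fx$references[1:4, ],
    fx$ref_clades[1:4]), "no reference for clade")
})
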