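# Independent oracles used by the unit and acceptance tests. These are
# deliberately separate implementations (plain R, different algorithms where
# feasible) of the quantities the package computes in compiled code.

AA20 <- stcminer::aa_alphabet()

# --- affine-gap local alignment oracle (plain-R Gotoh, scores only) --------
# gap of length g costs open + g * extend
oracle_sw_score <- function(q, s, sub, open = 11, extend = 1) {
  qi <- strsplit(q, "")[[1]]
  si <- strsplit(s, "")[[1]]
  m <- length(qi); n <- length(si)
  NEG <- -Inf
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 1 + seq_len(m)) {
    for (j in 1 + seq_len(n)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + sub[qi[i - 1], si[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# exhaustive local-alignment enumeration for very short sequences: anchors
# the Gotoh oracle itself. Enumerates all substring pairs and all gapped
# global alignments of each pair by recursion.
oracle_sw_exhaustive <- function(q, s, sub, open = 11, extend = 1) {
  qi <- strsplit(q, "")[[1]]
  si <- strsplit(s, "")[[1]]
  glob <- function(a, b) {
    # best global alignment score of chars a vs b; recursion over last op,
    # with explicit gap-run accounting via state (last op: 0 none/diag,
    # 1 gap-in-b, 2 gap-in-a)
    rec <- function(i, j, last) {
      if (i == 0 && j == 0) return(0)
      out <- -Inf
      if (i > 0 && j > 0) {
        out <- max(out, rec(i - 1, j - 1, 0) + sub[a[i], b[j]])
      }
      if (i > 0) {
        cost <- if (last == 1) extend else open + extend
        out <- max(out, rec(i - 1, j, 1) - cost)
      }
      if (j > 0) {
        cost <- if (last == 2) extend else open + extend
        out <- max(out, rec(i, j - 1, 2) - cost)
      }
      out
    }
    # note: gap costs accrue right-to-left; a trailing gap run charged open
    # at its rightmost element, which is equivalent for totals
    rec(length(a), length(b), 0)
  }
  best <- 0
  for (i1 in seq_along(qi)) for (i2 in i1:length(qi)) {
    for (j1 in seq_along(si)) for (j2 in j1:length(si)) {
      best <- max(best, glob(qi[i1:i2], si[j1:j2]))
    }
  }
  best
}

# --- global alignment oracle (plain-R Gotoh, terminal gaps penalized) ------
oracle_nw_score <- function(q, s, sub, open, extend) {
  qi <- strsplit(q, "")[[1]]
  si <- strsplit(s, "")[[1]]
  m <- length(qi); n <- length(si)
  NEG <- -Inf
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  H[1, 1] <- 0
  for (j in 1 + seq_len(n)) { E[1, j] <- -open - extend * (j - 1); H[1, j] <- E[1, j] }
  for (i in 1 + seq_len(m)) { F[i, 1] <- -open - extend * (i - 1); H[i, 1] <- F[i, 1] }
  for (i in 1 + seq_len(m)) {
    for (j in 1 + seq_len(n)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(H[i - 1, j - 1] + sub[qi[i - 1], si[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  H[m + 1, n + 1]
}

# msa -> pairwise score under the package's profile scoring conventions
# (column score = mean pair score with gaps contributing 0)
msa_pair_score <- function(m, sub, open, extend) {
  rows <- lapply(m$rows, function(r) strsplit(r, "")[[1]])
  a <- rows[[1]]; b <- rows[[2]]
  sc <- 0
  run_a <- FALSE; run_b <- FALSE
  for (t in seq_along(a)) {
    if (a[t] != "-" && b[t] != "-") {
      sc <- sc + sub[a[t], b[t]]
      run_a <- FALSE; run_b <- FALSE
    } else if (a[t] == "-") {
      sc <- sc - (if (run_a) extend else open + extend)
      run_a <- TRUE; run_b <- FALSE
    } else {
      sc <- sc - (if (run_b) extend else open + extend)
      run_b <- TRUE; run_a <- FALSE
    }
  }
  sc
}

# --- profile-HMM brute-force path enumeration ------------------------------
# Enumerates every glocal state path: a start flank length s, an end flank
# length, and every core path through nodes 1..L emitting the middle
# residues. Returns both max (viterbi) and log-sum (forward), in bits.
oracle_hmm_scores <- function(hmm, seq) {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, AA20)  # NA = X
  n <- length(codes)
  L <- hmm$L
  tr <- hmm$transitions
  bg <- hmm$background
  em_bits <- function(mat_row, code) {
    if (is.na(code)) 0 else log2(mat_row[code] / bg[code])
  }
  path_logs <- numeric(0)
  # recursive core enumeration: at (state, node) having consumed residues
  # codes[(pos+1)..], accumulate log2 probability `acc`
  recurse <- function(state, node, pos, acc, endpos) {
    if (acc == -Inf) return(invisible())
    row <- node + 1
    if (state == "M" && node > L) {
      # reached E having consumed codes up to pos; remaining = free C flank
      if (pos == endpos) path_logs[length(path_logs) + 1] <<- acc
      return(invisible())
    }
    # transitions out of current state at `node`
    if (state %in% c("M", "I")) {
      # to insert at same node
      if (pos < endpos) {
        tII <- if (state == "M") tr[row, "MI"] else tr[row, "II"]
        if (tII > 0) {
          recurse("I", node, pos + 1,
                  acc + log2(tII) + em_bits(hmm$insert_emissions[row, ],
                                            codes[pos + 1]), endpos)
        }
      }
    }
    tM <- switch(state, M = tr[row, "MM"], I = tr[row, "IM"], D = tr[row, "DM"])
    if (tM > 0) {
      if (node + 1 > L) {
        recurse("M", node + 1, pos, acc + log2(tM), endpos)  # exit to E
      } else if (pos < endpos) {
        recurse("M", node + 1, pos + 1,
                acc + log2(tM) + em_bits(hmm$match_emissions[node + 1, ],
                                         codes[pos + 1]), endpos)
      }
    }
    if (state %in% c("M", "D") && node + 1 <= L) {
      tD <- if (state == "M") tr[row, "MD"] else tr[row, "DD"]
      if (tD > 0) recurse("D", node + 1, pos, acc + log2(tD), endpos)
    }
    invisible()
  }
  for (s in 0:n) {
    for (e in s:n) {
      recurse("M", 0, s, 0, e)
    }
  }
  if (length(path_logs) == 0) return(c(viterbi = -Inf, forward = -Inf))
  mx <- max(path_logs)
  c(viterbi = mx,
    forward = mx + log2(sum(2^(path_logs - mx))))
}

# random small profile HMM with every bundle strictly positive
random_small_hmm <- function(L, seed) {
  set.seed(seed)
  rdir <- function(n) { g <- rgamma(n, 1); g / sum(g) }
  me <- t(replicate(L, rdir(20)))
  ie <- t(replicate(L + 1, rdir(20)))
  tr <- matrix(0, L + 1, 7)
  for (k in seq_len(L + 1)) {
    m3 <- rdir(3); i2 <- rdir(2); d2 <- rdir(2)
    if (k == L + 1) { m3 <- c(m3[1] + m3[3], m3[2], 0); d2 <- c(1, 0) }
    tr[k, ] <- c(m3, i2, d2)
  }
  tr[1, 6:7] <- 0
  # delete bundles only exist for nodes 1..L
  stcminer::profile_hmm(me, ie, tr, rep(0.05, 20),
                        name = paste0("rand", seed))
}

# --- motif discovery brute force -------------------------------------------
oracle_discover <- function(pos, neg, kmin, kmax, min_freq) {
  kmers_of <- function(s) {
    L <- nchar(s)
    out <- character(0)
    for (k in kmin:kmax) {
      if (k > L) break
      out <- c(out, substring(s, 1:(L - k + 1), k:L))
    }
    unique(out)
  }
  pos_k <- lapply(pos, kmers_of)
  neg_k <- unique(unlist(lapply(neg, kmers_of)))
  all_k <- unique(unlist(pos_k))
  all_k <- all_k[!grepl("X", all_k, fixed = TRUE)]
  if (length(all_k) == 0L) return(character(0))
  support <- lapply(all_k, function(m) {
    which(vapply(pos_k, function(s) m %in% s, logical(1)))
  })
  names(support) <- all_k
  ok <- vapply(all_k, function(m) {
    length(support[[m]]) >= ceiling(min_freq * length(pos)) &&
      !(m %in% neg_k)
  }, logical(1))
  cand <- all_k[ok]
  if (length(cand) == 0L) return(character(0))
  maximal <- vapply(cand, function(m) {
    if (nchar(m) >= kmax) return(TRUE)
    for (e in c(paste0(AA20, m), paste0(m, AA20))) {
      if (e %in% cand && identical(support[[e]], support[[m]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(cand[maximal])
}

# random protein-ish string over a restricted alphabet
rand_string <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
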