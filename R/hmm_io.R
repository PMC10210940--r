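# Plain-text profile-HMM serialization. Probabilities are stored with 17
# significant digits, which round-trips IEEE doubles exactly, so
# read(write(x)) reproduces every probability bit-for-bit.

fmt_prob <- function(p) {
  vapply(p, function(x) sprintf("%.17g", x), character(1))
}

#' Write a profile HMM to a text file
#'
#' Format: a \code{SHMM1} magic line; \code{NAME}, \code{CLADE}, \code{LENG}
#' headers; a \code{BG} line; then per node a \code{MATCH} line (nodes
#' 1..L), an \code{INSERT} line (nodes 0..L) and a \code{TRANS} line (nodes
#' 0..L, columns MM MI MD IM II DM DD); probabilities are printed with 17
#' significant digits so the round trip is exact.
#'
#' @param hmm A \code{\link{profile_hmm}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., collapse = " "), con)
  w("SHMM1")
  w(c("NAME", hmm$name))
  w(c("CLADE", hmm$clade))
  w(c("LENG", hmm$L))
  w(c("BG", fmt_prob(hmm$background)))
  for (k in 0:hmm$L) {
    if (k >= 1L) w(c("MATCH", k, fmt_prob(hmm$match_emissions[k, ])))
    w(c("INSERT", k, fmt_prob(hmm$insert_emissions[k + 1L, ])))
    w(c("TRANS", k, fmt_prob(hmm$transitions[k + 1L, ])))
  }
  w("END")
  invisible(path)
}

#' Read a profile HMM from a text file
#'
#' Inverse of \code{\link{write_hmm}}; validates all emission and transition
#' bundles on load and reports the offending line on malformed input.
#'
#' @param path Path to a file written by \code{\link{write_hmm}}.
#' @return A \code{\link{profile_hmm}}.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  bail <- function(i, msg) {
    stop("malformed HMM file at line ", i, ": ", msg, call. = FALSE)
  }
  if (length(lines) < 6L || lines[[1]] != "SHMM1") bail(1L, "missing SHMM1 magic")
  fields <- strsplit(lines, " ", fixed = TRUE)
  get_scalar <- function(i, key) {
    f <- fields[[i]]
    if (length(f) != 2L || f[[1]] != key) bail(i, paste("expected", key))
    f[[2]]
  }
  name <- get_scalar(2L, "NAME")
  clade <- get_scalar(3L, "CLADE")
  L <- as.integer(get_scalar(4L, "LENG"))
  if (is.na(L) || L < 1L) bail(4L, "invalid LENG")
  parse_probs <- function(i, key, extra, n) {
    f <- fields[[i]]
    if (length(f) != 1L + extra + n || f[[1]] != key) {
      bail(i, paste("expected", key, "with", n, "values"))
    }
    v <- suppressWarnings(as.numeric(f[(2L + extra):(1L + extra + n)]))
    if (anyNA(v)) bail(i, "non-numeric probability")
    v
  }
  bg <- parse_probs(5L, "BG", 0L, 20L)
  match_em <- matrix(0, L, 20L)
  insert_em <- matrix(0, L + 1L, 20L)
  trans <- matrix(0, L + 1L, 7L)
  i <- 6L
  for (k in 0:L) {
    if (k >= 1L) { match_em[k, ] <- parse_probs(i, "MATCH", 1L, 20L); i <- i + 1L }
    insert_em[k + 1L, ] <- parse_probs(i, "INSERT", 1L, 20L); i <- i + 1L
    trans[k + 1L, ] <- parse_probs(i, "TRANS", 1L, 7L); i <- i + 1L
  }
  if (i > length(lines) || lines[[i]] != "END") bail(i, "missing END")
  tryCatch(profile_hmm(match_em, insert_em, trans, bg, name, clade),
           error = function(e) {
             stop("invalid HMM in ", path, ": ", conditionMessage(e),
                  call. = FALSE)
           })
}

#' Sample a sequence from a profile HMM
#'
#' Walks the model from begin to end following the transition
#' probabilities, emitting from match and insert states. Uses the current
#' RNG state.
#'
#' @param hmm A \code{\link{profile_hmm}}.
#' @param with_path If TRUE, also return the state path.
#' @return A sequence string, or a list with \code{sequence} and
#'   \code{path}.
#' @export
sample_hmm <- function(hmm, with_path = FALSE) {
  tr <- hmm$transitions
  L <- hmm$L
  pick <- function(probs) sample.int(length(probs), 1L, prob = probs)
  out <- character()
  path <- character()
  state <- "M"; node <- 0L
  repeat {
    row <- node + 1L
    nxt <- switch(state,
                  M = c("M", "I", "D")[pick(tr[row, c("MM", "MI", "MD")])],
                  I = c("M", "I")[pick(tr[row, c("IM", "II")])],
                  D = c("M", "D")[pick(tr[row, c("DM", "DD")])])
    if (nxt == "I") {
      out <- c(out, AA[pick(hmm$insert_emissions[row, ])])
      path <- c(path, paste0("I", node))
      state <- "I"
    } else {
      node <- node + 1L
      if (nxt == "M" && node > L) break  # reached E
      if (nxt == "M") {
        out <- c(out, AA[pick(hmm$match_emissions[node, ])])
        path <- c(path, paste0("M", node))
      } else {
        path <- c(path, paste0("D", node))
      }
      state <- nxt
    }
  }
  seqstr <- paste(out, collapse = "")
  if (with_path) list(sequence = seqstr, path = path) else seqstr
}
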