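# Pipeline configuration: one place for every threshold the method uses.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the mining pipeline. Defaults encode
#' the published protocol: similarity filter at >30 percent identity and
#' >60 percent query coverage (strict bounds), exclusive length window
#' 250 < L < 500 aa, MAFFT-style gap open 2.3 / gap extend 0.63 for the
#' progressive aligner, column trimming at gap fraction 0.5, discriminative
#' motif discovery over 3-6-mers at minimum positive frequency 0.75, HMM
#' gathering threshold 25 bits, refinement with the top 100 scoring
#' sequences per division, and a tandem window of four gene positions.
#'
#' @param min_identity_pct Minimum percent identity (strict) for filter 1.
#' @param min_coverage_pct Minimum percent query coverage (strict) for
#'   filter 1.
#' @param min_len_aa,max_len_aa Exclusive length bounds for filter 3.
#' @param gap_open,gap_extend Affine gap penalties of the progressive
#'   aligner, in bit-scaled BLOSUM62 units.
#' @param sw_gap_open,sw_gap_extend Affine gap penalties of the local
#'   (Smith-Waterman) screen, in half-bit BLOSUM62 units (BLAST defaults).
#' @param trim_gap_threshold Maximum gap fraction of a retained alignment
#'   column.
#' @param motif_min_freq Minimum fraction of positive sequences containing a
#'   discriminative motif.
#' @param motif_kmin,motif_kmax Motif length bounds.
#' @param hmm_bit_threshold Gathering threshold (bits) for HMM hits.
#' @param refine_top_k Sequences per division used to train
#'   second-generation models.
#' @param tandem_window Maximum ordinal distance defining a tandem pair.
#' @param rng_seed Seed for any randomized step.
#' @return A validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(min_identity_pct = 30,
                            min_coverage_pct = 60,
                            min_len_aa = 250L,
                            max_len_aa = 500L,
                            gap_open = 2.3,
                            gap_extend = 0.63,
                            sw_gap_open = 11,
                            sw_gap_extend = 1,
                            trim_gap_threshold = 0.5,
                            motif_min_freq = 0.75,
                            motif_kmin = 3L,
                            motif_kmax = 6L,
                            hmm_bit_threshold = 25,
                            refine_top_k = 100L,
                            tandem_window = 4L,
                            rng_seed = 1L) {
  cfg <- list(min_identity_pct = as.numeric(min_identity_pct),
              min_coverage_pct = as.numeric(min_coverage_pct),
              min_len_aa = as.integer(min_len_aa),
              max_len_aa = as.integer(max_len_aa),
              gap_open = as.numeric(gap_open),
              gap_extend = as.numeric(gap_extend),
              sw_gap_open = as.numeric(sw_gap_open),
              sw_gap_extend = as.numeric(sw_gap_extend),
              trim_gap_threshold = as.numeric(trim_gap_threshold),
              motif_min_freq = as.numeric(motif_min_freq),
              motif_kmin = as.integer(motif_kmin),
              motif_kmax = as.integer(motif_kmax),
              hmm_bit_threshold = as.numeric(hmm_bit_threshold),
              refine_top_k = as.integer(refine_top_k),
              tandem_window = as.integer(tandem_window),
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
              min_coverage_pct >= 0, min_coverage_pct <= 100,
              min_len_aa < max_len_aa,
              motif_min_freq > 0, motif_min_freq <= 1,
              motif_kmin >= 2L, motif_kmin <= motif_kmax,
              trim_gap_threshold >= 0, trim_gap_threshold <= 1,
              tandem_window >= 1L, refine_top_k >= 1L)
  })
  structure(cfg, class = "pipeline_config")
}

#' Read a key=value configuration file
#'
#' Plain-text configuration: one \code{key = value} pair per line, \code{#}
#' comments allowed. Keys are the argument names of
#' \code{\link{pipeline_config}}; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A \code{pipeline_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed config line: ", lines[[i]], call. = FALSE)
    }
    key <- trimws(parts[[1]])
    if (!key %in% names(formals(pipeline_config))) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    args[[key]] <- as.numeric(trimws(parts[[2]]))
  }
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("STC mining pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
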