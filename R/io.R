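# Readers and writers for the plain-text formats the pipeline consumes:
# protein FASTA, clade-label TSV, gene-order TSV, hit/call tables.

#' Construct a set of protein records
#'
#' A protein set is a plain \code{data.frame} with columns \code{id},
#' \code{sequence}, \code{genome_id} and \code{division}. Sequences must
#' already be normalized (upper case, alphabet of the 20 residues plus X).
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of residue strings.
#' @param genome_id Genome of origin (recycled if length 1).
#' @param division One of \code{"basidiomycete"}, \code{"ascomycete"},
#'   \code{"other"} (recycled if length 1).
#' @return A validated \code{data.frame} of protein records.
#' @export
protein_records <- function(id, sequence, genome_id = "genome1",
                            division = "other") {
  df <- data.frame(id = as.character(id),
                   sequence = as.character(sequence),
                   genome_id = rep_len(as.character(genome_id), length(id)),
                   division = rep_len(as.character(division), length(id)),
                   stringsAsFactors = FALSE)
  validate_protein_records(df)
}

validate_protein_records <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("id", "sequence", "genome_id", "division") %in% names(df)))
  if (any(df$id == "")) stop("protein ids must be non-empty", call. = FALSE)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop("duplicate id ", dup[[1L]], call. = FALSE)
  }
  if (any(nchar(df$sequence) == 0L)) {
    stop("empty sequence for id ", df$id[nchar(df$sequence) == 0L][[1L]],
         call. = FALSE)
  }
  bad <- grepl(paste0("[^", paste(AA_X, collapse = ""), "]"), df$sequence)
  if (any(bad)) {
    stop("sequence for id ", df$id[bad][[1L]],
         " contains characters outside the residue alphabet", call. = FALSE)
  }
  ok_div <- df$division %in% c("basidiomycete", "ascomycete", "other")
  if (!all(ok_div)) {
    stop("division must be basidiomycete, ascomycete or other", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Normalize a raw protein sequence
#'
#' Upper-cases, strips \code{*} (stop) characters and maps the ambiguity
#' codes B, Z, J, U, O to X.
#'
#' @param x Character vector of raw sequences.
#' @return Normalized sequences.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- gsub("*", "", x, fixed = TRUE)
  x <- chartr(paste(AA_AMBIG, collapse = ""),
              strrep("X", length(AA_AMBIG)), x)
  x
}

#' Read a protein FASTA file
#'
#' Sequences are normalized with \code{\link{normalize_sequence}}; record
#' order is preserved. Only the first whitespace-delimited token of each
#' header is kept as the id.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome id attached to every record.
#' @param division Division attached to every record.
#' @return A protein record \code{data.frame} (see
#'   \code{\link{protein_records}}).
#' @export
read_fasta <- function(path, genome_id = "genome1", division = "other") {
  if (file.size(path) == 0L || !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(data.frame(id = character(), sequence = character(),
                      genome_id = character(), division = character(),
                      stringsAsFactors = FALSE))
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  protein_records(ids, normalize_sequence(as.character(aa)),
                  genome_id = genome_id, division = division)
}

#' Write protein records to FASTA
#'
#' @param records Protein record \code{data.frame}.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- validate_protein_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a clade-label table
#'
#' Two-column tab-separated file: protein id, clade in 1..4.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping protein id to clade label.
#' @export
read_clade_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty clade table: ", path, call. = FALSE)
    return(setNames(character(), character()))
  }
  out <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[[1]])) {
      stop("malformed clade table line ", i, ": ", lines[[i]], call. = FALSE)
    }
    if (!parts[[2]] %in% CLADES) {
      stop("line ", i, ": clade must be one of 1-4, got ", parts[[2]],
           call. = FALSE)
    }
    ids[i] <- parts[[1]]
    out[i] <- parts[[2]]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate id in clade table: ", ids[duplicated(ids)][[1]],
         call. = FALSE)
  }
  setNames(out, ids)
}

#' Read a gene-order table
#'
#' Tab-separated with columns \code{genome_id}, \code{scaffold},
#' \code{ordinal}, \code{strand}, \code{protein_id}; \code{ordinal} is the
#' rank of the gene along its scaffold, counting all annotated genes.
#'
#' @param path Path to the TSV file (no header).
#' @return A \code{data.frame} of gene loci sorted by genome, scaffold and
#'   ordinal.
#' @export
read_gene_order <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("genome_id", "scaffold", "ordinal",
                                 "strand", "protein_id"))
  gene_loci(df)
}

#' Construct/validate a gene-locus table
#'
#' @param df \code{data.frame} with columns \code{genome_id},
#'   \code{scaffold}, \code{ordinal}, \code{strand}, \code{protein_id}.
#' @return The validated table, sorted by genome, scaffold, ordinal.
#' @export
gene_loci <- function(df) {
  stopifnot(all(c("genome_id", "scaffold", "ordinal", "strand",
                  "protein_id") %in% names(df)))
  df$ordinal <- as.integer(df$ordinal)
  if (any(is.na(df$ordinal)) || any(df$ordinal < 1L)) {
    stop("ordinals must be integers >= 1", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  key <- paste(df$genome_id, df$scaffold, df$ordinal, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop("duplicate gene position: genome ", d$genome_id[[1]], " scaffold ",
         d$scaffold[[1]], " ordinal ", d$ordinal[[1]], call. = FALSE)
  }
  df <- df[order(df$genome_id, df$scaffold, df$ordinal), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# fixed-format TSV writer used for hits/calls/report tables: floats with six
# decimals, no quoting, no row names
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
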