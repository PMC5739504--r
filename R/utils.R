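BASES <- c("A", "C", "G", "T")
DEL <- "del"

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; accepts upper-case A/C/G/T strings.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Read a reference sequence
#'
#' Accepts either a literal DNA string or a path to a FASTA file (read with
#' Biostrings). Multi-record FASTA files are rejected: the scorer works
#' against a single circular-genome reference.
#'
#' @param reference A DNA string or a FASTA file path.
#' @return A single upper-case DNA string.
#' @export
read_reference <- function(reference) {
  stopifnot(is.character(reference), length(reference) == 1)
  if (file.exists(reference) && !grepl("^[ACGTNacgtn]+$", reference)) {
    set <- Biostrings::readDNAStringSet(reference)
    if (length(set) != 1) {
      abort("reference FASTA must contain exactly one sequence",
            class = "trnascore_validation")
    }
    return(toupper(as.character(set[[1]])))
  }
  toupper(reference)
}

#' Write a reference sequence to FASTA
#'
#' @param reference DNA string.
#' @param path Output file path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path, name = "reference") {
  set <- Biostrings::DNAStringSet(setNames(reference, name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

require_file <- function(path, what = "input file") {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(paste0(what, " not found: ", if (is.character(path)) path else "<missing>"),
          class = "trnascore_missing_input")
  }
  path
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Area under the ROC curve
#'
#' Rank-statistic AUC (equivalent to the Mann-Whitney U estimate; ties
#' share mean ranks): the probability that a random positive outranks a
#' random negative.
#'
#' @param score Numeric score vector.
#' @param is_positive Logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, is_positive) {
  r <- rank(score)
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  stopifnot(n_pos > 0, n_neg > 0)
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
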