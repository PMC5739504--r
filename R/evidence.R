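#' Read the variant-evidence table
#'
#' One row per observed variant: GenBank-style population observation
#' counts plus pathogenicity-report counts stratified by heteroplasmy and
#' experimental confirmation (single-fiber or cybrid). Variants absent from
#' the table are treated downstream as novel (zero counts, no reports).
#'
#' @param evidence A data frame or TSV path with columns `position`, `ref`,
#'   `alt` (`A`/`C`/`G`/`T` or `"del"`), `genbank_count`, `total_sequences`,
#'   `n_reports_het_confirmed`, `n_reports_het_unconfirmed`,
#'   `n_reports_hom_confirmed`, `n_reports_hom_unconfirmed`.
#' @param loci Optional `trna_loci` table; when given, each row's `ref` is
#'   checked against the tRNA-sense base at the position.
#' @return A validated evidence tibble.
#' @export
read_evidence <- function(evidence, loci = NULL) {
  if (is.character(evidence)) {
    require_file(evidence, "evidence table")
    evidence <- readr::read_tsv(evidence, show_col_types = FALSE,
                                progress = FALSE)
  }
  evidence <- tibble::as_tibble(evidence)
  needed <- c("position", "ref", "alt", "genbank_count", "total_sequences",
              "n_reports_het_confirmed", "n_reports_het_unconfirmed",
              "n_reports_hom_confirmed", "n_reports_hom_unconfirmed")
  if (!all(needed %in% names(evidence))) {
    abort(paste0("evidence table must have columns: ",
                 paste(needed, collapse = ", ")),
          class = "trnascore_validation")
  }
  if (!all(evidence$ref %in% BASES)) {
    abort("evidence ref alleles must be A/C/G/T", class = "trnascore_validation")
  }
  if (!all(evidence$alt %in% c(BASES, DEL))) {
    abort("evidence alt alleles must be A/C/G/T or 'del'",
          class = "trnascore_validation")
  }
  if (any(evidence$ref == evidence$alt)) {
    abort("alt allele equals ref", class = "trnascore_validation")
  }
  key <- paste(evidence$position, evidence$ref, evidence$alt)
  if (anyDuplicated(key)) {
    abort("duplicate variant rows in evidence table",
          class = "trnascore_validation")
  }
  counts <- evidence[, needed[-(1:3)]]
  if (any(as.matrix(counts) < 0)) {
    abort("negative counts in evidence table", class = "trnascore_validation")
  }
  if (any(evidence$genbank_count > evidence$total_sequences)) {
    abort("genbank_count exceeds total_sequences",
          class = "trnascore_validation")
  }
  if (!is.null(loci)) {
    m <- match(evidence$position, loci$mtdna_pos)
    bad <- !is.na(m) & loci$ref_base[m] != evidence$ref
    if (any(bad)) {
      abort(paste0("ref allele mismatch vs reference at position(s): ",
                   paste(evidence$position[bad], collapse = ", ")),
            class = "trnascore_validation")
    }
  }
  evidence
}

#' Write an evidence table
#' @param evidence Evidence tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  readr::write_tsv(evidence, path, progress = FALSE)
  invisible(path)
}

#' Read the cross-species conservation table
#'
#' Per tRNA position, the number of species in the panel carrying each base
#' (gaps allowed, so counts may sum to less than the panel size). Positions
#' annotated in `loci` but missing from the table are filled with an all-gap
#' column and flagged (`filled = TRUE`), never an error.
#'
#' @param conservation A data frame or TSV path with columns `gene`,
#'   `trna_index`, `count_A`, `count_C`, `count_G`, `count_T`, `n_species`.
#' @param loci Optional `trna_loci` table used to complete coverage.
#' @return A conservation tibble with a logical `filled` column.
#' @export
read_conservation <- function(conservation, loci = NULL) {
  if (is.character(conservation)) {
    require_file(conservation, "conservation table")
    conservation <- readr::read_tsv(conservation, show_col_types = FALSE,
                                    progress = FALSE)
  }
  conservation <- tibble::as_tibble(conservation)
  needed <- c("gene", "trna_index", "count_A", "count_C", "count_G",
              "count_T", "n_species")
  if (!all(needed %in% names(conservation))) {
    abort(paste0("conservation table must have columns: ",
                 paste(needed, collapse = ", ")),
          class = "trnascore_validation")
  }
  cts <- as.matrix(conservation[, c("count_A", "count_C", "count_G", "count_T")])
  if (any(cts < 0) || any(conservation$n_species <= 0)) {
    abort("conservation counts must be non-negative and n_species positive",
          class = "trnascore_validation")
  }
  if (any(rowSums(cts) > conservation$n_species)) {
    abort("conservation column total exceeds n_species",
          class = "trnascore_validation")
  }
  if (anyDuplicated(paste(conservation$gene, conservation$trna_index))) {
    abort("duplicate conservation rows", class = "trnascore_validation")
  }
  if (!"filled" %in% names(conservation)) conservation$filled <- FALSE
  if (!is.null(loci)) {
    if (nrow(conservation) == 0) {
      abort("conservation table is empty", class = "trnascore_validation")
    }
    n_sp <- max(conservation$n_species)
    full <- loci |>
      dplyr::select(gene = "gene", trna_index = "index_5p") |>
      dplyr::left_join(conservation, by = c("gene", "trna_index"))
    miss <- is.na(full$n_species)
    if (any(miss)) {
      full$count_A[miss] <- 0L
      full$count_C[miss] <- 0L
      full$count_G[miss] <- 0L
      full$count_T[miss] <- 0L
      full$n_species[miss] <- n_sp
      full$filled[miss] <- TRUE
    }
    conservation <- full
  }
  conservation
}

#' Write a conservation table
#' @param conservation Conservation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(conservation, path) {
  readr::write_tsv(conservation, path, progress = FALSE)
  invisible(path)
}

#' Read the optional haplogroup-association table
#'
#' @param haplogroups A data frame or TSV path with columns `position`,
#'   `ref`, `alt`, `haplogroup`, `fraction` (fraction of sequences in that
#'   haplogroup carrying the variant, in `[0, 1]`).
#' @return A haplogroup tibble, or `NULL` when `haplogroups` is `NULL`.
#' @export
read_haplogroups <- function(haplogroups) {
  if (is.null(haplogroups)) return(NULL)
  if (is.character(haplogroups)) {
    require_file(haplogroups, "haplogroup table")
    haplogroups <- readr::read_tsv(haplogroups, show_col_types = FALSE,
                                   progress = FALSE)
  }
  haplogroups <- tibble::as_tibble(haplogroups)
  needed <- c("position", "ref", "alt", "haplogroup", "fraction")
  if (!all(needed %in% names(haplogroups))) {
    abort("haplogroup table must have columns position, ref, alt, haplogroup, fraction",
          class = "trnascore_validation")
  }
  if (any(haplogroups$fraction < 0 | haplogroups$fraction > 1)) {
    abort("haplogroup fractions must lie in [0, 1]",
          class = "trnascore_validation")
  }
  haplogroups
}

# Canonical "novel" evidence used for variants absent from the table.
novel_evidence <- function(position, ref, alt, total_sequences) {
  tibble::tibble(
    position = position, ref = ref, alt = alt,
    genbank_count = 0L, total_sequences = total_sequences,
    n_reports_het_confirmed = 0L, n_reports_het_unconfirmed = 0L,
    n_reports_hom_confirmed = 0L, n_reports_hom_unconfirmed = 0L
  )
}

#' Benign population-frequency distribution
#'
#' The sorted GenBank observation counts of report-free variants seen at
#' least once; the percentile reference for the population sub-score.
#'
#' @param evidence Evidence tibble.
#' @return Sorted integer vector of counts.
#' @export
benign_distribution <- function(evidence) {
  n_rep <- evidence$n_reports_het_confirmed + evidence$n_reports_het_unconfirmed +
    evidence$n_reports_hom_confirmed + evidence$n_reports_hom_unconfirmed
  sort(evidence$genbank_count[n_rep == 0 & evidence$genbank_count >= 1])
}
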