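# All hand-chosen scoring constants live here so they can be retuned in one
# place. The orderings they must respect: stem ends > stem centre;
# unobserved alleles > observed; confirmed/heteroplasmic reports >
# unconfirmed/homoplasmic; substitutions that improve pairing score < 0.

# Pathogenicity-report stratum weights (max over a variant's reports).
PATH_STRATUM <- c(het_confirmed = 1.0, hom_confirmed = 0.8,
                  het_unconfirmed = 0.6, hom_unconfirmed = 0.4)

# Steric classes of a base pair, from innocuous to most disruptive.
# Watson-Crick 0 < G.U wobble 1 < pyrimidine-pyrimidine 2 < other
# (A.C-type) mismatch 3 < purine-purine 4; a single-base deletion inside a
# stem also takes the maximal class 4.
STERIC_WC <- 0
STERIC_WOBBLE <- 1
STERIC_PYR_PYR <- 2
STERIC_OTHER <- 3
STERIC_PUR_PUR <- 4
STERIC_DELETION <- 4

# Quadratic end-of-stem weight floor (weight at the stem centre).
STEM_WEIGHT_FLOOR <- 0.25

#' Scaling factors for the pathogenicity score
#'
#' The six tunable weights: `var_hx_scal` (variant history: population and
#' report sub-scores), `cons_scal` (interspecies conservation),
#' `var_hx_cons_scal` (the combined history-and-conservation score),
#' `SS_scal` (secondary structure), `Pos_scal` (generic-position score) and
#' `base_scal` (base score applied to novel variants with no history).
#'
#' @param var_hx_scal,cons_scal,var_hx_cons_scal,SS_scal,Pos_scal,base_scal
#'   Real weights; `var_hx_cons_scal`, `SS_scal` and `Pos_scal` must be
#'   strictly positive.
#' @return A named list of class `scaling_factors`.
#' @export
scaling_factors <- function(var_hx_scal = 1, cons_scal = 1,
                            var_hx_cons_scal = 1, SS_scal = 1,
                            Pos_scal = 1, base_scal = 1) {
  f <- list(var_hx_scal = var_hx_scal, cons_scal = cons_scal,
            var_hx_cons_scal = var_hx_cons_scal, SS_scal = SS_scal,
            Pos_scal = Pos_scal, base_scal = base_scal)
  if (!all(vapply(f, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    abort("scaling factors must be single finite numbers",
          class = "trnascore_bad_config")
  }
  if (f$var_hx_cons_scal <= 0 || f$SS_scal <= 0 || f$Pos_scal <= 0) {
    abort("var_hx_cons_scal, SS_scal and Pos_scal must be positive",
          class = "trnascore_bad_config")
  }
  structure(f, class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("<scaling_factors>\n")
  print(unlist(x))
  invisible(x)
}

factor_names <- function() {
  c("var_hx_scal", "cons_scal", "var_hx_cons_scal", "SS_scal", "Pos_scal",
    "base_scal")
}

#' Coerce a numeric vector to scaling factors
#' @param x Named or positionally ordered numeric vector of length 6
#'   (order: var_hx_scal, cons_scal, var_hx_cons_scal, SS_scal, Pos_scal,
#'   base_scal).
#' @return A `scaling_factors` object.
#' @export
as_scaling_factors <- function(x) {
  if (inherits(x, "scaling_factors")) return(x)
  x <- unlist(x)
  if (!is.null(names(x)) && all(factor_names() %in% names(x))) {
    x <- x[factor_names()]
  }
  if (length(x) != 6) {
    abort("expected 6 scaling factors", class = "trnascore_bad_config")
  }
  do.call(scaling_factors, as.list(setNames(as.numeric(x), factor_names())))
}

#' Population sub-score
#'
#' Percentile rank of a variant's GenBank observation count within the
#' benign count distribution, flipped so that common variants score low:
#' `1 - percentile/100`. The rank convention is strictly-below with tied
#' entries sharing the mean rank; counts at or above the distribution
#' maximum take percentile 100 (score 0), and counts below every entry take
#' percentile 0 (score 1).
#'
#' @param count Integer vector of observation counts (each >= 1).
#' @param distribution Sorted benign count distribution
#'   (see [benign_distribution()]).
#' @return Numeric vector in `[0, 1]`, non-increasing in `count`.
#' @export
pop_score <- function(count, distribution) {
  if (length(distribution) == 0) {
    abort("empty benign count distribution", class = "trnascore_bad_config")
  }
  stopifnot(all(count >= 1))
  d <- sort(distribution)
  n <- length(d)
  top <- max(d)
  vapply(count, function(cc) {
    if (cc >= top) return(0)
    b <- sum(d < cc)
    e <- sum(d == cc)
    1 - (b + max(e - 1, 0) / 2) / n
  }, numeric(1))
}

#' Pathogenicity-report sub-score
#'
#' The maximum stratum weight over a variant's reports: confirmed &
#' heteroplasmic 1.0, confirmed & homoplasmic 0.8, unconfirmed &
#' heteroplasmic 0.6, unconfirmed & homoplasmic 0.4; 0 with no reports.
#'
#' @param het_confirmed,het_unconfirmed,hom_confirmed,hom_unconfirmed
#'   Integer vectors of report counts per stratum.
#' @return Numeric vector in `[0, 1]`.
#' @export
path_score <- function(het_confirmed, het_unconfirmed,
                       hom_confirmed, hom_unconfirmed) {
  dplyr::case_when(
    het_confirmed > 0 ~ PATH_STRATUM[["het_confirmed"]],
    hom_confirmed > 0 ~ PATH_STRATUM[["hom_confirmed"]],
    het_unconfirmed > 0 ~ PATH_STRATUM[["het_unconfirmed"]],
    hom_unconfirmed > 0 ~ PATH_STRATUM[["hom_unconfirmed"]],
    TRUE ~ 0
  )
}

#' Conservation sub-score
#'
#' Logarithmic deviation from complete conservation:
#' `1 - log(1 + k) / log(1 + N)` where `k` species in the panel of size `N`
#' carry the alternate base (`k = 0` for deletions and unseen bases). 1 when
#' the alternate base is absent from the panel, 0 when all species carry it,
#' strictly decreasing in `k`.
#'
#' @param k Species counts carrying the alternate base.
#' @param n_species Panel size(s), positive.
#' @return Numeric vector in `[0, 1]`.
#' @export
cons_score <- function(k, n_species) {
  if (any(n_species <= 0)) {
    abort("conservation panel size must be positive",
          class = "trnascore_bad_config")
  }
  stopifnot(all(k >= 0), all(k <= n_species))
  1 - log1p(k) / log1p(n_species)
}

#' Quadratic end-of-stem weight
#'
#' `w(i) = 0.25 + 0.75 * ((i - (L-1)/2)^2) / (((L-1)/2)^2)` for within-stem
#' index `i` in a stem of `L` base pairs: 1 at both stem ends, 0.25 at the
#' centre, symmetric.
#'
#' @param i Within-stem pair index, 0-based.
#' @param stem_len Stem length in base pairs (>= 2).
#' @return Numeric weights in `[0.25, 1]`.
#' @export
stem_position_weight <- function(i, stem_len) {
  if (any(stem_len < 2)) {
    abort("degenerate stem of length < 2", class = "trnascore_validation")
  }
  mid <- (stem_len - 1) / 2
  STEM_WEIGHT_FLOOR + (1 - STEM_WEIGHT_FLOOR) * ((i - mid)^2) / (mid^2)
}

#' Steric class of a base pair
#'
#' @param b1,b2 Base characters (`A`/`C`/`G`/`T`); symmetric in its
#'   arguments.
#' @return Integer-valued class: Watson-Crick 0, G.U wobble 1,
#'   pyrimidine-pyrimidine 2, other mismatch 3, purine-purine 4.
#' @export
pair_class <- function(b1, b2) {
  pair <- paste0(pmin(b1, b2), pmax(b1, b2))
  dplyr::case_when(
    pair %in% c("AT", "CG") ~ STERIC_WC,
    pair == "GT" ~ STERIC_WOBBLE,
    b1 %in% c("C", "T") & b2 %in% c("C", "T") ~ STERIC_PYR_PYR,
    b1 %in% c("A", "G") & b2 %in% c("A", "G") ~ STERIC_PUR_PUR,
    TRUE ~ STERIC_OTHER
  )
}

#' Secondary-structure sub-score
#'
#' 0 for unpaired positions. For a stem position, the end-of-stem quadratic
#' weight times the steric change `class(new pair) - class(old pair)`;
#' deletions in stems take the maximal steric class. Substitutions that
#' improve pairing (e.g. wobble to Watson-Crick) score negative.
#'
#' @param paired Logical: is the position in a stem?
#' @param pair_index Within-stem pair index (0-based).
#' @param stem_len Stem length in base pairs.
#' @param base Reference base at the position (tRNA sense).
#' @param partner_base Base at the pairing partner.
#' @param alt Alternate allele (`A`/`C`/`G`/`T` or `"del"`).
#' @return Numeric vector of steric scores.
#' @export
secondary_structure_score <- function(paired, pair_index, stem_len,
                                      base, partner_base, alt) {
  out <- numeric(length(paired))
  p <- which(paired)
  if (length(p) > 0) {
    old_class <- pair_class(base[p], partner_base[p])
    is_del <- alt[p] == DEL
    new_class <- numeric(length(p))
    new_class[is_del] <- STERIC_DELETION
    if (any(!is_del)) {
      new_class[!is_del] <- pair_class(alt[p][!is_del], partner_base[p][!is_del])
    }
    out[p] <- stem_position_weight(pair_index[p], stem_len[p]) *
      (new_class - old_class)
  }
  out
}

#' Variant-history-and-conservation decision tree
#'
#' Combines the population, report and conservation sub-scores. Branch 1
#' (any pathogenicity report): `var_hx_scal * path + cons_scal * cons`.
#' Branch 2 (observed, no reports): `var_hx_scal * (pop - 1) + cons_scal *
#' cons`, so common benign variants are rewarded with a negative history
#' term. Branch 3 (novel): `base_scal + cons_scal * cons`.
#'
#' Returned alongside the score are the factor-independent components used
#' by the take-one-out machinery: `hist_component` (`path`, `pop - 1`, or
#' 0) and `novel_component` (1 on branch 3).
#'
#' @param branch Integer vector in `{1, 2, 3}`.
#' @param path,pop,cons Sub-score vectors (pop may be `NA` off branch 2).
#' @param factors A [scaling_factors()] object.
#' @return A tibble with `hist_component`, `novel_component`,
#'   `var_hx_cons_score`.
#' @keywords internal
vhc_combine <- function(branch, path, pop, cons, factors) {
  hist_component <- dplyr::case_when(
    branch == 1L ~ path,
    branch == 2L ~ pop - 1,
    TRUE ~ 0
  )
  novel_component <- as.numeric(branch == 3L)
  tibble::tibble(
    hist_component = hist_component,
    novel_component = novel_component,
    var_hx_cons_score = factors$var_hx_scal * hist_component +
      factors$cons_scal * cons +
      factors$base_scal * novel_component
  )
}

#' Score every possible variant in the annotated tRNAs
#'
#' Enumerates all 4 alleles (3 substitutions + single-base deletion) at
#' every annotated tRNA position and computes the full score breakdown:
#' population, report and conservation sub-scores, the
#' variant-history-and-conservation decision tree, the generic-position
#' score (slot average of per-position history summaries), the
#' secondary-structure steric score, and the weighted total
#' `var_hx_cons_scal * vhc + Pos_scal * position + SS_scal * ss`.
#'
#' @param loci A `trna_loci` table.
#' @param evidence Evidence tibble (validated by [read_evidence()]).
#' @param conservation Conservation tibble covering every locus
#'   (see [read_conservation()]).
#' @param factors A [scaling_factors()] object.
#' @param distribution Benign count distribution for the population
#'   percentile; defaults to [benign_distribution()] of `evidence`. Passed
#'   explicitly when re-scoring after evidence deletion (take-one-out),
#'   where the population reference stays at its full-data value.
#' @return A tibble of class `trna_scores`, 4 rows per tRNA position,
#'   ordered by mtDNA position then alt allele, with the benign count
#'   distribution and factors attached as attributes.
#' @export
score_all <- function(loci, evidence, conservation,
                      factors = scaling_factors(), distribution = NULL) {
  factors <- as_scaling_factors(factors)

  rows <- tidyr::crossing(
    loci |>
      dplyr::select("gene", "strand", "mtdna_pos", "index_5p", "base",
                    "ref_base", "element", "element_index", "paired",
                    "stem_len", "pair_index", "partner_base", "is_anticodon",
                    "slot_id", "anchor_class"),
    alt = c(BASES, DEL)
  ) |>
    dplyr::filter(.data$alt != .data$ref_base) |>
    dplyr::rename(ref = "ref_base") |>
    dplyr::mutate(
      # alt allele in tRNA-sense orientation, for pairing and conservation
      sense_alt = dplyr::if_else(.data$alt == DEL, DEL,
                                 dplyr::if_else(.data$strand == "-",
                                                chartr("ACGT", "TGCA", .data$alt),
                                                .data$alt))
    ) |>
    dplyr::arrange(.data$mtdna_pos, match(.data$alt, c(BASES, DEL)))

  rows <- rows |>
    dplyr::left_join(
      evidence |>
        dplyr::select("position", "ref", "alt", "genbank_count",
                      "n_reports_het_confirmed", "n_reports_het_unconfirmed",
                      "n_reports_hom_confirmed", "n_reports_hom_unconfirmed"),
      by = c(mtdna_pos = "position", "ref", "alt")
    ) |>
    dplyr::mutate(dplyr::across(
      c("genbank_count", dplyr::starts_with("n_reports_")),
      ~ tidyr::replace_na(.x, 0L)
    ))

  cons_tbl <- conservation |>
    dplyr::select("gene", "trna_index", "count_A", "count_C", "count_G",
                  "count_T", "n_species")
  rows <- rows |>
    dplyr::left_join(cons_tbl, by = c("gene", index_5p = "trna_index"))
  if (any(is.na(rows$n_species))) {
    abort("conservation table does not cover every tRNA position; pass it through read_conservation(loci = ...)",
          class = "trnascore_validation")
  }
  alt_k <- dplyr::case_when(
    rows$sense_alt == "A" ~ rows$count_A,
    rows$sense_alt == "C" ~ rows$count_C,
    rows$sense_alt == "G" ~ rows$count_G,
    rows$sense_alt == "T" ~ rows$count_T,
    TRUE ~ 0L
  )

  dist <- distribution %||% benign_distribution(evidence)
  n_reports <- rows$n_reports_het_confirmed + rows$n_reports_het_unconfirmed +
    rows$n_reports_hom_confirmed + rows$n_reports_hom_unconfirmed
  branch <- dplyr::case_when(
    n_reports > 0 ~ 1L,
    rows$genbank_count >= 1 ~ 2L,
    TRUE ~ 3L
  )
  pop <- rep(NA_real_, nrow(rows))
  if (any(branch == 2L)) {
    pop[branch == 2L] <- pop_score(rows$genbank_count[branch == 2L], dist)
  }
  pathv <- path_score(rows$n_reports_het_confirmed,
                      rows$n_reports_het_unconfirmed,
                      rows$n_reports_hom_confirmed,
                      rows$n_reports_hom_unconfirmed)
  consv <- cons_score(alt_k, rows$n_species)
  vhc <- vhc_combine(branch, pathv, pop, consv, factors)

  ss <- secondary_structure_score(rows$paired, rows$pair_index, rows$stem_len,
                                  rows$base, rows$partner_base, rows$sense_alt)

  scored <- rows |>
    dplyr::mutate(
      branch = branch,
      pop_score = pop, path_score = pathv, cons_score = consv,
      hist_component = vhc$hist_component,
      novel_component = vhc$novel_component,
      var_hx_cons_score = vhc$var_hx_cons_score,
      secondary_structure_score = ss
    )

  # Generic-position score: slot average of per-position history summaries,
  # each position summarised as the mean over its 4 possible alleles. The
  # factor-independent slot component means are kept so take-one-out
  # re-scoring and factor retuning need no re-traversal.
  pos_summ <- scored |>
    dplyr::group_by(.data$gene, .data$index_5p, .data$slot_id) |>
    dplyr::summarise(
      p_hist = mean(.data$hist_component),
      p_novel = mean(.data$novel_component),
      p_cons = mean(.data$cons_score),
      .groups = "drop"
    )
  slot_stats <- pos_summ |>
    dplyr::group_by(.data$slot_id) |>
    dplyr::summarise(
      slot_hist_mean = mean(.data$p_hist),
      slot_novel_mean = mean(.data$p_novel),
      slot_cons_mean = mean(.data$p_cons),
      slot_n_positions = dplyr::n(),
      .groups = "drop"
    )
  scored <- scored |>
    dplyr::left_join(slot_stats, by = "slot_id") |>
    dplyr::mutate(
      position_score = factors$var_hx_scal * .data$slot_hist_mean +
        factors$cons_scal * .data$slot_cons_mean +
        factors$base_scal * .data$slot_novel_mean,
      total_score = factors$var_hx_cons_scal * .data$var_hx_cons_score +
        factors$Pos_scal * .data$position_score +
        factors$SS_scal * .data$secondary_structure_score
    ) |>
    dplyr::rename(position = "mtdna_pos") |>
    dplyr::select("position", "ref", "alt", "gene", "index_5p", "element",
                  "element_index", "slot_id", "anchor_class", "branch",
                  "pop_score", "path_score", "cons_score",
                  "hist_component", "novel_component", "var_hx_cons_score",
                  "position_score", "secondary_structure_score",
                  "total_score",
                  dplyr::starts_with("slot_"), "genbank_count",
                  dplyr::starts_with("n_reports_"))

  structure(scored, class = c("trna_scores", class(scored)),
            factors = factors, benign_distribution = dist,
            total_sequences = if (nrow(evidence) > 0)
              max(evidence$total_sequences) else NA_integer_)
}

#' Write a score table
#'
#' @param scores A `trna_scores` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  scores |>
    dplyr::select("position", "ref", "alt", "gene", "element", "slot_id",
                  "pop_score", "path_score", "cons_score", "branch",
                  "var_hx_cons_score", "position_score",
                  "secondary_structure_score", "total_score") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
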