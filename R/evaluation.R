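#' Take-one-out re-scoring of labelled variants
#'
#' Re-scores each labelled variant as if it had never been observed: its own
#' population counts and pathogenicity reports are deleted (the variant
#' becomes novel, decision-tree branch 3) and the generic-position score is
#' recomputed without the variant's own contribution to its alignment slot.
#' The benign count distribution, a property of the population database as
#' a whole, is held at its full-data value.
#'
#' Because every score is linear in the deleted entry's history components,
#' the deletion is applied as an exact algebraic adjustment of the slot
#' means cached in the score table; the result is identical to deleting the
#' evidence row and re-running [score_all()].
#'
#' @param scores A `trna_scores` table from [score_all()] (any factors; the
#'   cached components are factor-independent).
#' @param variants A data frame with columns `position`, `ref`, `alt`
#'   identifying the variants to re-score (e.g. a labels table).
#' @param factors Scaling factors to score under; defaults to the factors
#'   the table was built with.
#' @return A tibble with one row per requested variant: the novel-branch
#'   breakdown (`cons_score`, `var_hx_cons_score`, `position_score`,
#'   `secondary_structure_score`, `total_score`, `branch = 3`) plus any
#'   extra columns of `variants` (such as `label`).
#' @export
loo_rescore <- function(scores, variants, factors = NULL) {
  factors <- as_scaling_factors(factors %||% attr(scores, "factors"))
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("position", "ref", "alt") %in% names(variants)))

  hit <- variants |>
    dplyr::left_join(
      scores |>
        dplyr::select("position", "ref", "alt", "gene", "index_5p",
                      "element", "slot_id", "cons_score", "hist_component",
                      "novel_component", "secondary_structure_score",
                      dplyr::starts_with("slot_")),
      by = c("position", "ref", "alt")
    )
  if (any(is.na(hit$slot_id))) {
    miss <- hit |> dplyr::filter(is.na(.data$slot_id))
    abort(paste0("variant(s) not in the score table: ",
                 paste(paste0(miss$position, miss$ref, ">", miss$alt),
                       collapse = ", ")),
          class = "trnascore_evaluation")
  }

  # Deleting the entry sets its history component to 0 and novel indicator
  # to 1; each position summary averages 4 alleles and each slot averages
  # slot_n_positions position summaries.
  m4 <- 4 * hit$slot_n_positions
  slot_hist <- hit$slot_hist_mean - hit$hist_component / m4
  slot_novel <- hit$slot_novel_mean + (1 - hit$novel_component) / m4
  vhc <- factors$cons_scal * hit$cons_score + factors$base_scal
  pos <- factors$var_hx_scal * slot_hist +
    factors$cons_scal * hit$slot_cons_mean +
    factors$base_scal * slot_novel
  hit |>
    dplyr::mutate(
      branch = 3L,
      pop_score = NA_real_, path_score = 0,
      var_hx_cons_score = vhc,
      position_score = pos,
      total_score = factors$var_hx_cons_scal * vhc +
        factors$Pos_scal * pos +
        factors$SS_scal * .data$secondary_structure_score
    ) |>
    dplyr::select(-dplyr::starts_with("slot_"), -"hist_component",
                  -"novel_component", "slot_id")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sensitivity/specificity sweep over score thresholds
#'
#' A variant is called pathogenic when its score is greater than or equal
#' to the threshold. Thresholds are the sorted unique scores, the midpoints
#' between consecutive unique scores, and one value above the maximum, so
#' the curve runs from (sensitivity 1, specificity 0) to (0, 1). The
#' crossover is the threshold minimising `|sensitivity - specificity|`,
#' ties resolved toward the lower threshold (favouring sensitivity).
#'
#' @param data A data frame with a score column and a label column.
#' @param score,label Column names (tidy-select) for the numeric score and
#'   the label (`"pathogenic"` / `"benign"`).
#' @return A tibble of class `trna_sweep` (`threshold`, `sensitivity`,
#'   `specificity`) with crossover attributes; see [glance.trna_sweep()].
#' @export
sweep_thresholds <- function(data, score = "total_score", label = "label") {
  s <- data[[score]]
  l <- data[[label]]
  stopifnot(!is.null(s), !is.null(l))
  is_path <- l == "pathogenic"
  if (!any(is_path) || all(is_path)) {
    abort("sweep needs both pathogenic and benign labels",
          class = "trnascore_degenerate_labels")
  }
  u <- sort(unique(s))
  degenerate <- length(u) == 1
  step <- if (degenerate) 1 else stats::median(diff(u))
  thresholds <- sort(unique(c(u, if (!degenerate) (u[-1] + u[-length(u)]) / 2,
                              max(u) + step)))
  path_scores <- s[is_path]
  benign_scores <- s[!is_path]
  sens <- vapply(thresholds, function(t) mean(path_scores >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(benign_scores < t), numeric(1))
  i <- which.min(abs(sens - spec))
  out <- tibble::tibble(threshold = thresholds, sensitivity = sens,
                        specificity = spec)
  structure(out, class = c("trna_sweep", class(out)),
            crossover_threshold = thresholds[i],
            crossover_value = (sens[i] + spec[i]) / 2,
            sensitivity_at_crossover = sens[i],
            specificity_at_crossover = spec[i],
            degenerate = degenerate,
            n_pathogenic = sum(is_path), n_benign = sum(!is_path))
}

#' @rdname sweep_thresholds
#' @param x A `trna_sweep` object.
#' @param ... Unused.
#' @export
glance.trna_sweep <- function(x, ...) {
  tibble::tibble(
    crossover_threshold = attr(x, "crossover_threshold"),
    crossover_value = attr(x, "crossover_value"),
    sensitivity = attr(x, "sensitivity_at_crossover"),
    specificity = attr(x, "specificity_at_crossover"),
    degenerate = attr(x, "degenerate"),
    n_pathogenic = attr(x, "n_pathogenic"),
    n_benign = attr(x, "n_benign")
  )
}

#' @rdname sweep_thresholds
#' @export
tidy.trna_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Percentile and four-category interpretation of a score
#'
#' The percentile ranks the query against the scores of all possible
#' variants, clamped to 1-99. The category follows the quartile:
#' percentile <= 25 likely benign, <= 50 possibly benign, <= 75 possibly
#' pathogenic, otherwise likely pathogenic.
#'
#' @param scores A `trna_scores` table (or a numeric vector of all-variant
#'   totals).
#' @param query Numeric vector of query scores.
#' @return A tibble with `score`, `percentile` (integer 1-99), `category`.
#' @export
percentile_interpret <- function(scores, query) {
  all_scores <- if (is.numeric(scores)) scores else scores$total_score
  if (length(all_scores) == 0) {
    abort("empty score table", class = "trnascore_evaluation")
  }
  pct <- vapply(query, function(q) {
    as.integer(clamp(floor(100 * mean(all_scores <= q)), 1L, 99L))
  }, integer(1))
  tibble::tibble(
    score = query,
    percentile = pct,
    category = score_category(pct)
  )
}

score_category <- function(percentile) {
  dplyr::case_when(
    percentile <= 25 ~ "likely benign",
    percentile <= 50 ~ "possibly benign",
    percentile <= 75 ~ "possibly pathogenic",
    TRUE ~ "likely pathogenic"
  )
}

#' Display status of a variant
#'
#' Scored display is suppressed for variants already confirmed pathogenic
#' (`known_pathogenic`) and for frequent polymorphisms: more than 1% of all
#' GenBank sequences, or more than 10% of any single major haplogroup
#' division (both strict inequalities). Precedence: known pathogenic, then
#' frequent polymorphism, then scored. Suppressed variants still carry a
#' score breakdown internally.
#'
#' @param variants A data frame with `position`, `ref`, `alt`.
#' @param evidence Evidence tibble (for counts and panel size).
#' @param known_pathogenic Optional data frame of known-pathogenic variants
#'   (`position`, `ref`, `alt`).
#' @param haplogroups Optional haplogroup table (see [read_haplogroups()]).
#' @return `variants` with a `display_status` column in
#'   `{"known_pathogenic", "frequent_polymorphism", "scored"}`.
#' @export
display_status <- function(variants, evidence, known_pathogenic = NULL,
                           haplogroups = NULL) {
  variants <- tibble::as_tibble(variants)
  key <- function(d) paste(d$position, d$ref, d$alt)
  vkey <- key(variants)
  known <- if (is.null(known_pathogenic) || nrow(known_pathogenic) == 0) {
    rep(FALSE, nrow(variants))
  } else {
    vkey %in% key(known_pathogenic)
  }
  m <- match(vkey, key(evidence))
  genbank_frac <- ifelse(is.na(m), 0,
                         evidence$genbank_count[m] / evidence$total_sequences[m])
  hap_max <- rep(0, nrow(variants))
  if (!is.null(haplogroups) && nrow(haplogroups) > 0) {
    hmax <- haplogroups |>
      dplyr::group_by(.data$position, .data$ref, .data$alt) |>
      dplyr::summarise(fraction = max(.data$fraction), .groups = "drop")
    hm <- match(vkey, key(hmax))
    hap_max <- ifelse(is.na(hm), 0, hmax$fraction[hm])
  }
  variants$display_status <- dplyr::case_when(
    known ~ "known_pathogenic",
    genbank_frac > 0.01 | hap_max > 0.10 ~ "frequent_polymorphism",
    TRUE ~ "scored"
  )
  variants
}

#' Query a single mtDNA position
#'
#' Returns the four per-allele breakdowns at a tRNA position, annotated
#' with percentile, category and display status.
#'
#' @param scores A `trna_scores` table.
#' @param loci A `trna_loci` table (for the not-a-tRNA-position check).
#' @param position 1-based mtDNA coordinate.
#' @param evidence Evidence tibble.
#' @param known_pathogenic,haplogroups Passed to [display_status()].
#' @return A 4-row tibble of breakdowns with interpretation columns.
#' @export
query_position <- function(scores, loci, position, evidence,
                           known_pathogenic = NULL, haplogroups = NULL) {
  locate_position(loci, position)
  rows <- scores |> dplyr::filter(.data$position == !!position)
  interp <- percentile_interpret(scores, rows$total_score)
  rows$percentile <- interp$percentile
  rows$category <- interp$category
  status <- display_status(
    rows |> dplyr::select("position", "ref", "alt"),
    evidence, known_pathogenic, haplogroups
  )
  rows$display_status <- status$display_status
  rows
}
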