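#' Specification for a synthetic tRNA benchmark
#'
#' The generator emulates the data the scorer consumes: a compact genome of
#' cloverleaf tRNA genes on both strands, a cross-species conservation
#' panel in which stems and the anticodon are strongly conserved, a
#' population/report evidence table, and a labelled pathogenic/benign
#' variant set with a planted structural signal.
#'
#' `effect_strength` controls the planted signal symmetrically: with
#' probability `effect_strength` a pathogenic variant is placed at a
#' conserved stem-end or anticodon position and a benign variant at a
#' weakly conserved loop position; otherwise positions are uniform. At
#' `effect_strength = 0` both classes are positionally uniform (a null
#' benchmark); at 1 the placement is deterministic by class.
#'
#' @param n_genes Number of tRNA genes.
#' @param stem_lengths Named integer vector of stem lengths in base pairs
#'   (`acceptor`, `d`, `anticodon`, `t`).
#' @param loop_length_range `(min, max)` for the D and T loop lengths
#'   (anticodon loop is fixed at 7, variable loop at 4-5).
#' @param n_species Conservation panel size.
#' @param total_sequences Population panel size (GenBank-like).
#' @param n_benign,n_pathogenic Labelled variant counts.
#' @param effect_strength Planted-signal strength in `[0, 1]`.
#' @param wobble_rate Expected number of seeded G.U wobble pairs per gene.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 22,
                         stem_lengths = c(acceptor = 7, d = 4,
                                          anticodon = 5, t = 5),
                         loop_length_range = c(7, 9),
                         n_species = 30,
                         total_sequences = 40000,
                         n_benign = 651, n_pathogenic = 38,
                         effect_strength = 0.9,
                         wobble_rate = 1,
                         seed = 1) {
  spec <- list(n_genes = as.integer(n_genes), stem_lengths = stem_lengths,
               loop_length_range = as.integer(loop_length_range),
               n_species = as.integer(n_species),
               total_sequences = as.integer(total_sequences),
               n_benign = as.integer(n_benign),
               n_pathogenic = as.integer(n_pathogenic),
               effect_strength = effect_strength,
               wobble_rate = wobble_rate, seed = as.integer(seed))
  if (spec$n_genes < 1 || spec$n_benign < 1 || spec$n_pathogenic < 1 ||
        spec$n_species < 1) {
    abort("fixture counts must be positive", class = "trnascore_bad_config")
  }
  if (effect_strength < 0 || effect_strength > 1) {
    abort("effect_strength must lie in [0, 1]", class = "trnascore_bad_config")
  }
  if (!all(c("acceptor", "d", "anticodon", "t") %in% names(stem_lengths))) {
    abort("stem_lengths needs acceptor, d, anticodon, t entries",
          class = "trnascore_bad_config")
  }
  if (any(stem_lengths < 2)) {
    abort("stems must be at least 2 bp", class = "trnascore_bad_config")
  }
  if (length(spec$loop_length_range) != 2 ||
        spec$loop_length_range[1] > spec$loop_length_range[2] ||
        spec$loop_length_range[1] < 3) {
    abort("loop_length_range must be (min, max) with min >= 3",
          class = "trnascore_bad_config")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic tRNA genome
#'
#' Produces a reference sequence (a compact concatenation of tRNA genes and
#' random spacers, not a full mitogenome) and its cloverleaf annotation.
#' Genes alternate between the heavy and light strand; stems are
#' Watson-Crick paired in the generated sequence except for seeded G.U
#' wobbles.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `reference` (DNA string), `annotation` (tibble in the
#'   [trna_genes()] input format), `genes` (the parsed `trna_genes` table).
#' @export
simulate_genome <- function(spec) {
  set.seed(spec$seed)
  sl <- spec$stem_lengths
  rng <- spec$loop_length_range

  spacer <- function() {
    paste(sample(BASES, sample(5:20, 1), replace = TRUE), collapse = "")
  }

  ref_parts <- character(0)
  ann <- list()
  cursor <- 0L

  for (g in seq_len(spec$n_genes)) {
    d_loop <- sample(rng[1]:rng[2], 1)
    t_loop <- sample(rng[1]:rng[2], 1)
    var_loop <- sample(4:5, 1)
    lens <- c(
      acceptor_stem_5p = sl[["acceptor"]], d_stem_5p = sl[["d"]],
      d_loop = d_loop, d_stem_3p = sl[["d"]],
      anticodon_stem_5p = sl[["anticodon"]], anticodon_loop = 7L,
      anticodon_stem_3p = sl[["anticodon"]], variable_loop = var_loop,
      t_stem_5p = sl[["t"]], t_loop = t_loop, t_stem_3p = sl[["t"]],
      acceptor_stem_3p = sl[["acceptor"]], discriminator = 1L
    )
    n <- sum(lens)
    bases <- sample(BASES, n, replace = TRUE)
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    # Pair the stems: 3' half is the reverse complement of the 5' half.
    for (fam in c("acceptor_stem", "d_stem", "anticodon_stem", "t_stem")) {
      i5 <- seq(starts[[paste0(fam, "_5p")]], ends[[paste0(fam, "_5p")]])
      i3 <- seq(starts[[paste0(fam, "_3p")]], ends[[paste0(fam, "_3p")]])
      bases[i3] <- rev(chartr("ACGT", "TGCA", bases[i5]))
    }
    # Seed G.U wobbles at random stem pairs.
    n_wob <- rbinom(1, 3, min(1, spec$wobble_rate / 3))
    if (n_wob > 0) {
      fams <- sample(c("acceptor_stem", "d_stem", "anticodon_stem", "t_stem"),
                     n_wob, replace = TRUE)
      for (fam in fams) {
        L <- lens[[paste0(fam, "_5p")]]
        k <- sample.int(L, 1)
        i5 <- starts[[paste0(fam, "_5p")]] + k - 1
        i3 <- ends[[paste0(fam, "_3p")]] - k + 1
        if (sample(c(TRUE, FALSE), 1)) {
          bases[i5] <- "G"; bases[i3] <- "T"
        } else {
          bases[i5] <- "T"; bases[i3] <- "G"
        }
      }
    }
    sense <- paste(bases, collapse = "")
    strand <- if (g %% 2 == 1) "+" else "-"

    sp <- spacer()
    ref_parts <- c(ref_parts, sp)
    cursor <- cursor + nchar(sp)
    g_start <- cursor + 1L
    g_end <- cursor + n
    ref_parts <- c(ref_parts, if (strand == "-") revcomp(sense) else sense)
    cursor <- cursor + n

    # Element rows in 5'->3' tRNA order; mtDNA coordinates ascend for the
    # heavy strand and descend for the light strand.
    off5 <- starts - 1L
    off3 <- ends - 1L
    if (strand == "+") {
      e_start <- g_start + off5
      e_end <- g_start + off3
    } else {
      e_start <- g_end - off3
      e_end <- g_end - off5
    }
    ann[[g]] <- tibble::tibble(
      gene = sprintf("MT-T%02d", g), strand = strand,
      start = as.integer(e_start), end = as.integer(e_end),
      element = names(lens)
    )
  }
  ref_parts <- c(ref_parts, spacer())
  reference <- paste(ref_parts, collapse = "")
  annotation <- dplyr::bind_rows(ann)
  genes <- trna_genes(annotation, reference)
  list(reference = reference, annotation = annotation, genes = genes)
}

#' Generate a synthetic cross-species conservation panel
#'
#' Stems and the anticodon draw the reference base for about 95% of the
#' panel, loops about 60%; the remainder is spread over the other bases and
#' gaps, so column totals never exceed the panel size.
#'
#' @param spec A [fixture_spec()].
#' @param genes A `trna_genes` table from [simulate_genome()].
#' @return A conservation tibble in the [read_conservation()] format.
#' @export
simulate_conservation <- function(spec, genes) {
  set.seed(spec$seed + 1L)
  loci <- trna_loci(genes)
  n_sp <- spec$n_species
  p_ref <- ifelse(loci$paired | loci$is_anticodon, 0.95, 0.6)
  ref_count <- rbinom(nrow(loci), n_sp, p_ref)
  counts <- matrix(0L, nrow(loci), 4, dimnames = list(NULL, BASES))
  for (i in seq_len(nrow(loci))) {
    rest <- n_sp - ref_count[i]
    # remainder split over the three other bases and a gap share
    others <- setdiff(BASES, loci$base[i])
    split <- as.integer(rmultinom(1, rest, rep(0.25, 4)))
    counts[i, others] <- split[1:3]
    counts[i, loci$base[i]] <- ref_count[i]
  }
  tibble::tibble(
    gene = loci$gene, trna_index = loci$index_5p,
    count_A = counts[, "A"], count_C = counts[, "C"],
    count_G = counts[, "G"], count_T = counts[, "T"],
    n_species = n_sp
  )
}

#' Generate labelled variant evidence with a planted signal
#'
#' Pathogenic variants carry 1-3 pathogenicity reports (heteroplasmic with
#' probability 0.7, confirmed with probability 0.5) and few or no GenBank
#' observations; benign variants carry no reports and long-tailed geometric
#' observation counts. Placement follows `effect_strength` (see
#' [fixture_spec()]); alt alleles are drawn uniformly from the three
#' substitutions and the deletion for both classes.
#'
#' @param spec A [fixture_spec()].
#' @param genes A `trna_genes` table.
#' @return A list: `evidence` (evidence tibble), `labels` (tibble with
#'   `position`, `ref`, `alt`, `label`).
#' @export
simulate_evidence <- function(spec, genes) {
  set.seed(spec$seed + 2L)
  loci <- trna_loci(genes)

  hot <- loci$is_anticodon |
    (loci$paired & (loci$pair_index == 0 | loci$pair_index == loci$stem_len - 1))
  weak <- !loci$paired & !loci$is_anticodon

  variants <- tidyr::crossing(
    loci |> dplyr::select("mtdna_pos", "ref_base", "strand"),
    alt = c(BASES, DEL)
  ) |>
    dplyr::filter(.data$alt != .data$ref_base) |>
    dplyr::rename(position = "mtdna_pos", ref = "ref_base")
  variants$hot <- hot[match(variants$position, loci$mtdna_pos)]
  variants$weak <- weak[match(variants$position, loci$mtdna_pos)]

  n_all <- nrow(variants)
  e <- spec$effect_strength
  w_path <- e * variants$hot / max(sum(variants$hot), 1) + (1 - e) / n_all
  if (spec$n_pathogenic > sum(w_path > 0)) {
    abort("not enough candidate positions for the requested pathogenic count",
          class = "trnascore_bad_config")
  }
  idx_path <- sample.int(n_all, spec$n_pathogenic, prob = w_path)
  remaining <- setdiff(seq_len(n_all), idx_path)
  w_ben <- e * variants$weak / max(sum(variants$weak), 1) + (1 - e) / n_all
  w_ben <- w_ben[remaining]
  if (spec$n_benign > sum(w_ben > 0)) {
    abort("not enough candidate positions for the requested benign count",
          class = "trnascore_bad_config")
  }
  idx_ben <- remaining[sample.int(length(remaining), spec$n_benign,
                                  prob = w_ben)]

  path_v <- variants[idx_path, c("position", "ref", "alt")]
  ben_v <- variants[idx_ben, c("position", "ref", "alt")]

  n_p <- nrow(path_v)
  n_rep <- sample(1:3, n_p, replace = TRUE)
  rep_counts <- t(vapply(n_rep, function(k) {
    het <- runif(k) < 0.7
    conf <- runif(k) < 0.5
    c(sum(het & conf), sum(het & !conf), sum(!het & conf), sum(!het & !conf))
  }, numeric(4)))
  path_ev <- tibble::tibble(
    position = path_v$position, ref = path_v$ref, alt = path_v$alt,
    genbank_count = sample(0:2, n_p, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    total_sequences = spec$total_sequences,
    n_reports_het_confirmed = as.integer(rep_counts[, 1]),
    n_reports_het_unconfirmed = as.integer(rep_counts[, 2]),
    n_reports_hom_confirmed = as.integer(rep_counts[, 3]),
    n_reports_hom_unconfirmed = as.integer(rep_counts[, 4])
  )
  ben_ev <- tibble::tibble(
    position = ben_v$position, ref = ben_v$ref, alt = ben_v$alt,
    genbank_count = rgeom(nrow(ben_v), 0.3) + 1L,
    total_sequences = spec$total_sequences,
    n_reports_het_confirmed = 0L, n_reports_het_unconfirmed = 0L,
    n_reports_hom_confirmed = 0L, n_reports_hom_unconfirmed = 0L
  )
  evidence <- dplyr::bind_rows(path_ev, ben_ev) |>
    dplyr::arrange(.data$position, .data$alt)
  labels <- dplyr::bind_rows(
    path_v |> dplyr::mutate(label = "pathogenic"),
    ben_v |> dplyr::mutate(label = "benign")
  ) |>
    dplyr::arrange(.data$position, .data$alt)
  list(evidence = evidence, labels = labels)
}

#' Generate a complete synthetic benchmark
#'
#' Runs the genome, conservation and evidence generators and, optionally,
#' writes the five files every other module consumes: `reference.fasta`,
#' `annotation.tsv`, `conservation.tsv`, `evidence.tsv`, `labels.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory (created if missing).
#' @return A list with `reference`, `annotation`, `genes`, `loci`,
#'   `conservation`, `evidence`, `labels`, `spec`, and `paths` when `dir`
#'   is given.
#' @export
simulate_dataset <- function(spec = fixture_spec(), dir = NULL) {
  genome <- simulate_genome(spec)
  conservation <- simulate_conservation(spec, genome$genes)
  ev <- simulate_evidence(spec, genome$genes)
  out <- list(reference = genome$reference, annotation = genome$annotation,
              genes = genome$genes, loci = trna_loci(genome$genes),
              conservation = conservation,
              evidence = ev$evidence, labels = ev$labels, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      reference = file.path(dir, "reference.fasta"),
      annotation = file.path(dir, "annotation.tsv"),
      conservation = file.path(dir, "conservation.tsv"),
      evidence = file.path(dir, "evidence.tsv"),
      labels = file.path(dir, "labels.tsv")
    )
    write_reference(genome$reference, paths$reference)
    readr::write_tsv(genome$annotation, paths$annotation, progress = FALSE)
    write_conservation(conservation, paths$conservation)
    write_evidence(ev$evidence, paths$evidence)
    readr::write_tsv(ev$labels, paths$labels, progress = FALSE)
    out$paths <- paths
  }
  out
}
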