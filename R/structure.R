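# Cloverleaf vocabulary. Elements are listed in canonical 5'->3' order on the
# tRNA sense strand; a gene's annotation must be an ordered subset of this
# list (the D arm may be absent, as in tRNA-Ser(AGY)).
ELEMENT_KINDS <- c(
  "acceptor_stem_5p", "d_stem_5p", "d_loop", "d_stem_3p",
  "anticodon_stem_5p", "anticodon_loop", "anticodon_stem_3p",
  "variable_loop", "t_stem_5p", "t_loop", "t_stem_3p",
  "acceptor_stem_3p", "discriminator"
)

STEM_PARTNERS <- c(
  acceptor_stem_5p = "acceptor_stem_3p", acceptor_stem_3p = "acceptor_stem_5p",
  d_stem_5p = "d_stem_3p", d_stem_3p = "d_stem_5p",
  anticodon_stem_5p = "anticodon_stem_3p", anticodon_stem_3p = "anticodon_stem_5p",
  t_stem_5p = "t_stem_3p", t_stem_3p = "t_stem_5p"
)

is_stem_kind <- function(kind) kind %in% names(STEM_PARTNERS)
stem_family <- function(kind) sub("_(5p|3p)$", "", kind)
stem_half <- function(kind) sub("^.*_(5p|3p)$", "\\1", kind)

#' Build a tRNA gene table from an annotation and a reference
#'
#' Reads a cloverleaf annotation (one row per secondary-structure element)
#' together with the mitochondrial reference sequence, validates it, and
#' returns one row per gene with the tRNA-sense sequence attached.
#'
#' Genes on the light strand are annotated with mtDNA coordinates on the
#' reference (heavy) strand; their sense sequence is the reverse complement
#' of the reference slice, and tRNA-internal indices count from the gene's
#' 3' reference end.
#'
#' @param annotation A data frame with columns `gene`, `strand` (`"+"` heavy
#'   or `"-"` light), `start`, `end` (1-based inclusive mtDNA coordinates)
#'   and `element` (a cloverleaf element kind), with rows in 5'->3' tRNA
#'   order within each gene; or the path to such a TSV.
#' @param reference A DNA string or FASTA path (see [read_reference()]).
#' @return A tibble of class `trna_genes`: columns `gene`, `strand`, `start`,
#'   `end`, `length`, `sequence`, and a list-column `elements` (tibbles with
#'   `element`, `length`).
#' @export
trna_genes <- function(annotation, reference) {
  if (is.character(annotation)) {
    require_file(annotation, "annotation table")
    annotation <- readr::read_tsv(annotation, show_col_types = FALSE,
                                  progress = FALSE)
  }
  annotation <- tibble::as_tibble(annotation)
  needed <- c("gene", "strand", "start", "end", "element")
  if (!all(needed %in% names(annotation))) {
    abort("annotation needs columns gene, strand, start, end, element",
          class = "trnascore_validation")
  }
  ref <- read_reference(reference)
  ref_len <- nchar(ref)

  bad_kind <- setdiff(unique(annotation$element), ELEMENT_KINDS)
  if (length(bad_kind) > 0) {
    abort(paste0("unknown element kind(s): ", paste(bad_kind, collapse = ", ")),
          class = "trnascore_validation")
  }
  if (any(annotation$start < 1 | annotation$end > ref_len |
            annotation$start > annotation$end)) {
    abort("element coordinates fall outside the reference",
          class = "trnascore_validation")
  }

  genes <- annotation |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(function(rows, key) {
      validate_gene_annotation(rows, key$gene)
      strand <- rows$strand[1]
      g_start <- min(rows$start)
      g_end <- max(rows$end)
      g_len <- g_end - g_start + 1
      slice <- substr(ref, g_start, g_end)
      sense <- if (strand == "-") revcomp(slice) else slice
      tibble::tibble(
        gene = key$gene, strand = strand, start = g_start, end = g_end,
        length = g_len, sequence = sense,
        elements = list(tibble::tibble(
          element = rows$element,
          length = rows$end - rows$start + 1
        ))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$start)

  # Genes must not overlap: every mtDNA position belongs to at most one tRNA.
  if (nrow(genes) > 1 && any(genes$start[-1] <= genes$end[-nrow(genes)])) {
    abort("tRNA genes overlap on the reference", class = "trnascore_validation")
  }

  structure(genes, class = c("trna_genes", class(genes)),
            reference_length = ref_len)
}

validate_gene_annotation <- function(rows, gene) {
  fail <- function(msg) {
    abort(paste0("gene ", gene, ": ", msg), class = "trnascore_validation")
  }
  strand <- unique(rows$strand)
  if (length(strand) != 1 || !strand %in% c("+", "-")) {
    fail("strand must be a single '+' or '-'")
  }
  if (anyDuplicated(rows$element)) fail("duplicated element kind")
  ord <- match(rows$element, ELEMENT_KINDS)
  if (is.unsorted(ord, strictly = TRUE)) {
    fail("elements are not in 5'->3' cloverleaf order")
  }
  # Tiling: rows are in tRNA 5'->3' order, which is ascending mtDNA for the
  # heavy strand and descending for the light strand.
  lens <- rows$end - rows$start + 1
  span <- max(rows$end) - min(rows$start) + 1
  if (sum(lens) != span) fail("element lengths do not tile the gene span")
  if (strand == "+") {
    if (any(rows$start[-1] != rows$end[-nrow(rows)] + 1)) {
      fail("elements do not tile contiguously")
    }
  } else {
    if (any(rows$end[-1] != rows$start[-nrow(rows)] - 1)) {
      fail("elements do not tile contiguously")
    }
  }
  # Stem halves: both present, equal length.
  for (kind in intersect(rows$element, names(STEM_PARTNERS))) {
    partner <- STEM_PARTNERS[[kind]]
    if (!partner %in% rows$element) fail(paste0(kind, " lacks its partner half"))
    if (lens[rows$element == kind] != lens[rows$element == partner]) {
      fail(paste0("stem halves of ", stem_family(kind), " differ in length"))
    }
    if (lens[rows$element == kind] < 2) {
      fail(paste0("degenerate stem (length < 2) in ", stem_family(kind)))
    }
  }
  if (!"anticodon_loop" %in% rows$element) fail("anticodon loop missing")
  if (lens[rows$element == "anticodon_loop"] < 3) {
    fail("anticodon loop shorter than the anticodon triplet")
  }
  invisible(TRUE)
}

#' Expand tRNA genes into a per-nucleotide locus table
#'
#' The locus table is the structural backbone of the scorer: one row per
#' encoded tRNA nucleotide, carrying the mtDNA coordinate, tRNA-internal
#' index, cloverleaf element, base-pairing partner, anticodon membership,
#' and the generic cross-tRNA alignment slot.
#'
#' The generic alignment anchors on the four stems and the anticodon
#' triplet: stem positions share a slot by (stem half, within-stem pair
#' index), anticodon bases align position-by-position, and loop positions
#' align end-anchored (counting in from each loop end toward the middle,
#' ties to the 5' side), so loops of different length share end-proximal
#' slots while longer loops own extra central slots.
#'
#' @param genes A `trna_genes` table.
#' @return A tibble of class `trna_loci`, one row per tRNA position.
#' @export
trna_loci <- function(genes) {
  loci <- purrr::pmap(
    list(genes$gene, genes$strand, genes$start, genes$end,
         genes$sequence, genes$elements),
    gene_loci
  ) |>
    dplyr::bind_rows()
  structure(loci, class = c("trna_loci", class(loci)))
}

gene_loci <- function(gene, strand, g_start, g_end, sequence, elements) {
  bases <- seq_chars(sequence)
  n <- length(bases)
  ends <- cumsum(elements$length)
  starts <- ends - elements$length + 1
  element <- rep(elements$element, elements$length)
  element_len <- rep(elements$length, elements$length)
  element_index <- unlist(lapply(elements$length, function(l) seq_len(l) - 1L))
  index_5p <- seq_len(n) - 1L
  mtdna_pos <- if (strand == "-") g_end - index_5p else g_start + index_5p

  is_stem <- is_stem_kind(element)
  half <- ifelse(is_stem, stem_half(element), NA_character_)
  family <- ifelse(is_stem, stem_family(element), NA_character_)
  pair_index <- ifelse(is_stem,
                       ifelse(half == "5p", element_index,
                              element_len - 1L - element_index),
                       NA_integer_)

  # Partner lookup: same family and pair index, other half.
  partner_index_5p <- rep(NA_integer_, n)
  for (fam in unique(stats::na.omit(family))) {
    i5 <- which(family == fam & half == "5p")
    i3 <- which(family == fam & half == "3p")
    m <- match(pair_index[i5], pair_index[i3])
    partner_index_5p[i5] <- index_5p[i3][m]
    partner_index_5p[i3[m]] <- index_5p[i5]
  }
  partner_base <- ifelse(is.na(partner_index_5p), NA_character_,
                         bases[partner_index_5p + 1L])

  # Anticodon: central 3 bases of the anticodon loop.
  ac_len <- elements$length[elements$element == "anticodon_loop"]
  ac_start <- (ac_len - 3L) %/% 2L
  is_anticodon <- element == "anticodon_loop" &
    element_index >= ac_start & element_index <= ac_start + 2L
  anticodon_index <- ifelse(is_anticodon, element_index - ac_start, NA_integer_)

  slot_id <- character(n)
  anchor_class <- character(n)
  for (i in seq_len(n)) {
    if (is_stem[i]) {
      slot_id[i] <- paste0(element[i], "|", pair_index[i])
      anchor_class[i] <- "stem"
    } else if (is_anticodon[i]) {
      slot_id[i] <- paste0("anticodon|", anticodon_index[i])
      anchor_class[i] <- "anticodon"
    } else if (element[i] == "anticodon_loop") {
      # Loop flanks anchored by the anticodon triplet itself.
      if (element_index[i] < ac_start) {
        slot_id[i] <- paste0("anticodon_loop|5p|", element_index[i])
      } else {
        slot_id[i] <- paste0("anticodon_loop|3p|",
                             element_len[i] - 1L - element_index[i])
      }
      anchor_class[i] <- "loop"
    } else {
      h5 <- ceiling(element_len[i] / 2)
      if (element_index[i] < h5) {
        slot_id[i] <- paste0(element[i], "|5p|", element_index[i])
      } else {
        slot_id[i] <- paste0(element[i], "|3p|",
                             element_len[i] - 1L - element_index[i])
      }
      anchor_class[i] <- "loop"
    }
  }

  # base as written on the reference (heavy) strand; variants are stated in
  # this orientation, structure and conservation in tRNA sense.
  ref_base <- if (strand == "-") chartr("ACGT", "TGCA", bases) else bases

  tibble::tibble(
    gene = gene, strand = strand, mtdna_pos = as.integer(mtdna_pos),
    index_5p = index_5p, base = bases, ref_base = ref_base,
    element = element, element_index = element_index,
    element_len = as.integer(element_len),
    paired = is_stem, stem_len = ifelse(is_stem, element_len, NA_integer_),
    pair_index = as.integer(pair_index),
    partner_index_5p = as.integer(partner_index_5p),
    partner_base = partner_base,
    is_anticodon = is_anticodon,
    slot_id = slot_id, anchor_class = anchor_class
  )
}

#' Locate an mtDNA position inside the annotated tRNAs
#'
#' @param loci A `trna_loci` table.
#' @param position 1-based mtDNA coordinate.
#' @return The single locus row for that position.
#' @export
locate_position <- function(loci, position) {
  hit <- dplyr::filter(loci, .data$mtdna_pos == position)
  if (nrow(hit) == 0) {
    abort(paste0("position ", position, " is not inside an annotated tRNA"),
          class = "trnascore_not_trna_position")
  }
  if (nrow(hit) > 1) {
    abort(paste0("position ", position, " maps to multiple tRNAs"),
          class = "trnascore_validation")
  }
  hit
}

#' Export the generic-slot map
#'
#' @param loci A `trna_loci` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_slot_map <- function(loci, path) {
  loci |>
    dplyr::select("gene", "mtdna_pos", "index_5p", "element",
                  "element_index", "slot_id") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
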