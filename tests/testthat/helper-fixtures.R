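# Shared fixture builders. Everything is generated in code; nothing is read
# from disk unless a test is exercising the file round trip.

small_spec <- function(seed = 7, ...) {
  fixture_spec(n_genes = 4, n_benign = 40, n_pathogenic = 10,
               seed = seed, ...)
}

tiny_spec <- function(seed = 1, ...) {
  fixture_spec(n_genes = 2, n_benign = 12, n_pathogenic = 4,
               seed = seed, ...)
}

# A hand-built two-gene annotation (one heavy, one light strand) with known
# coordinates, used by the structure tests. Gene lengths: 69 nt each
# (acceptor 7 bp, D stem 4 bp, D loop of chosen length, anticodon stem 5 bp,
# anticodon loop 7, variable loop, T stem 5 bp, T loop 7, discriminator 1).
hand_annotation <- function(d_loop_1 = 7, d_loop_2 = 9) {
  lens <- function(d_loop) c(
    acceptor_stem_5p = 7, d_stem_5p = 4, d_loop = d_loop, d_stem_3p = 4,
    anticodon_stem_5p = 5, anticodon_loop = 7, anticodon_stem_3p = 5,
    variable_loop = 12 - d_loop, t_stem_5p = 5, t_loop = 7,
    t_stem_3p = 5, acceptor_stem_3p = 7, discriminator = 1
  )
  # variable loop absorbs the D-loop difference so both genes are 69 nt
  build <- function(gene, strand, g_start, l) {
    ends <- cumsum(l)
    starts <- ends - l + 1
    if (strand == "+") {
      tibble::tibble(gene = gene, strand = strand,
                     start = g_start + starts - 1,
                     end = g_start + ends - 1, element = names(l))
    } else {
      g_end <- g_start + sum(l) - 1
      tibble::tibble(gene = gene, strand = strand,
                     start = g_end - ends + 1,
                     end = g_end - starts + 1, element = names(l))
    }
  }
  dplyr::bind_rows(
    build("tH", "+", 11, lens(d_loop_1)),
    build("tL", "-", 101, lens(d_loop_2))
  )
}

# Paired-stem sequence for one hand gene, deterministic.
hand_gene_sequence <- function(annotation_gene) {
  lens <- annotation_gene$end - annotation_gene$start + 1
  names(lens) <- annotation_gene$element
  set.seed(99)
  bases <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  for (fam in c("acceptor_stem", "d_stem", "anticodon_stem", "t_stem")) {
    i5 <- seq(starts[[paste0(fam, "_5p")]], ends[[paste0(fam, "_5p")]])
    i3 <- seq(starts[[paste0(fam, "_3p")]], ends[[paste0(fam, "_3p")]])
    bases[i3] <- rev(chartr("ACGT", "TGCA", bases[i5]))
  }
  paste(bases, collapse = "")
}

# Reference carrying the two hand genes at their annotated coordinates.
hand_reference <- function(annotation) {
  ref <- rep("A", 200)
  for (g in unique(annotation$gene)) {
    rows <- annotation[annotation$gene == g, ]
    sense <- hand_gene_sequence(rows)
    g_start <- min(rows$start)
    g_end <- max(rows$end)
    written <- if (rows$strand[1] == "-") revcomp(sense) else sense
    ref[g_start:g_end] <- strsplit(written, "")[[1]]
  }
  paste(ref, collapse = "")
}
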