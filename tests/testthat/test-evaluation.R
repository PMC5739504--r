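test_that("take-one-out equals the delete-and-rescore oracle exactly", {
  for (seed in c(3, 17)) {
    ds <- simulate_dataset(tiny_spec(seed = seed))
    f <- scaling_factors(var_hx_scal = 1.2, cons_scal = 0.7,
                         var_hx_cons_scal = 1.8, SS_scal = 1.1,
                         Pos_scal = 2.5, base_scal = 0.4)
    scores <- score_all(ds$loci, ds$evidence, ds$conservation, f)
    dist <- benign_distribution(ds$evidence)
    loo <- loo_rescore(scores, ds$labels)
    for (i in seq_len(nrow(ds$labels))) {
      v <- ds$labels[i, ]
      ev2 <- dplyr::anti_join(ds$evidence, v,
                              by = c("position", "ref", "alt"))
      s2 <- score_all(ds$loci, ev2, ds$conservation, f, distribution = dist)
      row <- s2[s2$position == v$position & s2$ref == v$ref &
                  s2$alt == v$alt, ]
      expect_equal(loo$total_score[i], row$total_score, tolerance = 1e-12)
      expect_equal(loo$var_hx_cons_score[i], row$var_hx_cons_score,
                   tolerance = 1e-12)
      expect_equal(loo$position_score[i], row$position_score,
                   tolerance = 1e-12)
      expect_equal(row$branch, 3L)
    }
  }
})

test_that("take-one-out is a no-op for variants with no evidence", {
  ds <- simulate_dataset(tiny_spec(seed = 5))
  scores <- score_all(ds$loci, ds$evidence, ds$conservation)
  known <- paste(ds$evidence$position, ds$evidence$ref, ds$evidence$alt)
  novel <- scores[!paste(scores$position, scores$ref, scores$alt) %in% known, ]
  target <- novel[3, c("position", "ref", "alt")]
  loo <- loo_rescore(scores, target)
  expect_equal(loo$total_score, novel$total_score[3])

  # a reported variant flips from the report branch to the novel branch
  rep_v <- ds$labels[ds$labels$label == "pathogenic", ][1, ]
  full_row <- scores[scores$position == rep_v$position &
                       scores$ref == rep_v$ref & scores$alt == rep_v$alt, ]
  expect_equal(full_row$branch, 1L)
  expect_equal(loo_rescore(scores, rep_v)$branch, 3L)

  # unknown variant -> evaluation error
  expect_error(loo_rescore(scores, tibble::tibble(position = 1L, ref = "A",
                                                  alt = "C")),
               class = "trnascore_evaluation")
})

test_that("threshold sweep is monotone and finds the crossover", {
  # perfectly separated scores: a threshold with sens = spec = 1
  sep <- tibble::tibble(
    total_score = c(1, 2, 3, 11, 12, 13),
    label = rep(c("benign", "pathogenic"), each = 3)
  )
  sw <- sweep_thresholds(sep)
  g <- glance(sw)
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 1)
  expect_false(g$degenerate)

  # monotonicity along the whole curve
  expect_true(all(diff(sw$sensitivity) <= 0))
  expect_true(all(diff(sw$specificity) >= 0))
  # endpoints: everything called at the lowest threshold, nothing above the top
  expect_equal(sw$sensitivity[1], 1)
  expect_equal(sw$specificity[1], 0)
  expect_equal(sw$sensitivity[nrow(sw)], 0)
  expect_equal(sw$specificity[nrow(sw)], 1)

  # labels permuted at random against scores: crossover value near 0.5
  set.seed(91)
  n <- 2000
  perm <- tibble::tibble(
    total_score = rnorm(n),
    label = sample(rep(c("pathogenic", "benign"), n / 2))
  )
  gp <- glance(sweep_thresholds(perm))
  expect_lt(abs(gp$crossover_value - 0.5), 0.05)

  # identical scores for every variant: degenerate, flagged
  same <- tibble::tibble(total_score = rep(2, 10),
                         label = rep(c("pathogenic", "benign"), 5))
  gs <- glance(sweep_thresholds(same))
  expect_true(gs$degenerate)
  expect_true((gs$sensitivity == 1 && gs$specificity == 0) ||
                (gs$sensitivity == 0 && gs$specificity == 1))

  # single-label input -> degenerate-labels error
  expect_error(sweep_thresholds(sep[1:3, ]),
               class = "trnascore_degenerate_labels")
})

test_that("percentiles are clamped to 1-99 with quartile categories", {
  scores <- seq(-5, 20, length.out = 200)
  top <- percentile_interpret(scores, max(scores))
  expect_equal(top$percentile, 99L)
  expect_equal(top$category, "likely pathogenic")

  bottom <- percentile_interpret(scores, min(scores))
  expect_equal(bottom$percentile, 1L)
  expect_equal(bottom$category, "likely benign")

  med <- percentile_interpret(scores, median(scores))
  expect_equal(med$percentile, 50L)
  expect_equal(med$category, "possibly benign")

  # bounds property: any query lands in {1, ..., 99}
  set.seed(8)
  q <- runif(100, -10, 25)
  pct <- percentile_interpret(scores, q)$percentile
  expect_true(all(pct >= 1 & pct <= 99))
  # category is a step function of percentile
  expect_equal(percentile_interpret(scores, quantile(scores, 0.6))$category,
               "possibly pathogenic")
  expect_error(percentile_interpret(numeric(0), 1),
               class = "trnascore_evaluation")
})

test_that("display status applies suppression precedence and strict rules", {
  ev <- tibble::tibble(
    position = c(10L, 20L, 30L, 40L), ref = "A",
    alt = c("G", "G", "G", "G"),
    genbank_count = c(50L, 11L, 10L, 0L), total_sequences = 1000L,
    n_reports_het_confirmed = 0L, n_reports_het_unconfirmed = 0L,
    n_reports_hom_confirmed = 0L, n_reports_hom_unconfirmed = 0L
  )
  vars <- ev[, c("position", "ref", "alt")]
  known <- vars[1, ]
  hap <- tibble::tibble(position = c(30L, 40L), ref = "A", alt = "G",
                        haplogroup = c("L0", "M"), fraction = c(0.10, 0.11))

  st <- display_status(vars, ev, known, hap)$display_status
  # known pathogenic wins regardless of its 5% frequency
  expect_equal(st[1], "known_pathogenic")
  # 11/1000 = 1.1% > 1% -> frequent polymorphism
  expect_equal(st[2], "frequent_polymorphism")
  # 10/1000 = 1% exactly and haplogroup fraction 0.10 exactly: strict rules
  expect_equal(st[3], "scored")
  # haplogroup fraction 0.11 > 10% -> frequent polymorphism
  expect_equal(st[4], "frequent_polymorphism")
})

test_that("query_position reports four interpreted allele breakdowns", {
  ds <- simulate_dataset(tiny_spec(seed = 9))
  scores <- score_all(ds$loci, ds$evidence, ds$conservation)
  pos <- ds$loci$mtdna_pos[10]
  q <- query_position(scores, ds$loci, pos, ds$evidence)
  expect_equal(nrow(q), 4)
  expect_true(all(q$percentile >= 1 & q$percentile <= 99))
  expect_true(all(q$category %in% c("likely benign", "possibly benign",
                                    "possibly pathogenic",
                                    "likely pathogenic")))
  intergenic <- min(ds$loci$mtdna_pos) - 1L
  expect_error(query_position(scores, ds$loci, intergenic, ds$evidence),
               class = "trnascore_not_trna_position")
})
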