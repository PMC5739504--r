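test_that("population sub-score follows the percentile-rank convention", {
  d <- c(1, 2, 3, 4)
  # strictly-below rank: count 2 sits above one quarter of the distribution
  expect_equal(pop_score(2, d), 0.75)
  # count below every entry -> percentile 0 -> score 1
  expect_equal(pop_score(1, c(2, 3, 4, 5)), 1)
  # count at the distribution maximum -> percentile 100 -> score 0
  expect_equal(pop_score(4, d), 0)
  expect_equal(pop_score(10, d), 0)
  expect_error(pop_score(1, numeric(0)), class = "trnascore_bad_config")

  # monotone non-increasing in the observation count, for random
  # distributions with ties
  set.seed(31)
  for (rep in 1:20) {
    dist <- sample(1:30, 25, replace = TRUE)
    s <- pop_score(1:31, dist)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("report sub-score is the maximum stratum weight", {
  expect_equal(path_score(0L, 0L, 0L, 0L), 0)
  expect_equal(path_score(1L, 0L, 0L, 0L), 1.0)
  expect_equal(path_score(0L, 0L, 1L, 0L), 0.8)
  # {unconfirmed hom, unconfirmed het} -> the heteroplasmic stratum wins
  expect_equal(path_score(0L, 1L, 0L, 1L), 0.6)
  expect_equal(path_score(0L, 0L, 0L, 2L), 0.4)

  # monotone under report-set inclusion: adding any report never lowers it
  strata <- expand.grid(hc = 0:1, hu = 0:1, mc = 0:1, mu = 0:1)
  s0 <- with(strata, path_score(hc, hu, mc, mu))
  for (j in 1:4) {
    bumped <- strata
    bumped[, j] <- bumped[, j] + 1L
    s1 <- with(bumped, path_score(hc, hu, mc, mu))
    expect_true(all(s1 >= s0))
  }
})

test_that("conservation sub-score is the log deviation from full conservation", {
  expect_equal(cons_score(0, 30), 1)
  expect_equal(cons_score(30, 30), 0)
  expect_equal(cons_score(5, 30), 1 - log(6) / log(31), tolerance = 1e-12)
  # strictly decreasing in the species count carrying the alternate base
  s <- cons_score(0:30, 30)
  expect_true(all(diff(s) < 0))
  expect_error(cons_score(1, 0), class = "trnascore_bad_config")
})

test_that("quadratic stem weight is symmetric with strict end maximality", {
  for (L in 2:10) {
    w <- stem_position_weight(0:(L - 1), L)
    expect_equal(w, rev(w))
    expect_equal(max(w), w[1])
    expect_equal(w[1], 1)
    if (L >= 3) expect_true(all(w[1] > w[2:(L - 1)]))
    expect_true(all(w >= 0.25))
  }
  # a 7-bp stem: end weight is exactly 4x the centre weight
  expect_equal(stem_position_weight(0, 7) / stem_position_weight(3, 7), 4)
  expect_error(stem_position_weight(0, 1), class = "trnascore_validation")
})

test_that("steric scoring penalises mispairing and rewards repaired stems", {
  # steric antisymmetry: class(p) - class(q) = -(class(q) - class(p))
  combos <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  cls <- pair_class(combos$a, combos$b)
  expect_equal(cls, pair_class(combos$b, combos$a))
  expect_equal(pair_class("A", "T"), 0)
  expect_equal(pair_class("G", "T"), 1)
  expect_equal(pair_class("C", "T"), 2)
  expect_equal(pair_class("A", "C"), 3)
  expect_equal(pair_class("G", "A"), 4)

  # unpaired locus -> 0 for any substitution
  expect_equal(secondary_structure_score(FALSE, NA, NA, "A", NA, "G"), 0)

  # wobble converted to Watson-Crick pairing scores negative
  gu_fix <- secondary_structure_score(TRUE, 0L, 7L, "T", "G", "C")
  expect_lt(gu_fix, 0)

  # identical mismatch at stem end vs stem centre of a 7-bp stem: 4x
  end <- secondary_structure_score(TRUE, 0L, 7L, "A", "T", "C")
  centre <- secondary_structure_score(TRUE, 3L, 7L, "A", "T", "C")
  expect_equal(end / centre, 4)

  # deletion in a stem takes the maximal steric class
  del <- secondary_structure_score(TRUE, 0L, 7L, "A", "T", "del")
  expect_equal(del, 4)
})

test_that("decision tree routes report, population and novel branches", {
  ann <- hand_annotation()
  ref <- hand_reference(ann)
  loci <- trna_loci(trna_genes(ann, ref))
  # all-gap panel: every alternate base unseen, cons score 1 everywhere
  cons <- tibble::tibble(gene = loci$gene, trna_index = loci$index_5p,
                         count_A = 0L, count_C = 0L, count_G = 0L,
                         count_T = 0L, n_species = 30L)
  pos <- loci$mtdna_pos[1:3]
  refb <- loci$ref_base[1:3]
  altb <- vapply(refb, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  ev <- tibble::tibble(
    position = pos, ref = refb, alt = altb,
    genbank_count = c(1L, 9L, 0L), total_sequences = 1000L,
    n_reports_het_confirmed = c(1L, 0L, 0L),
    n_reports_het_unconfirmed = 0L,
    n_reports_hom_confirmed = 0L, n_reports_hom_unconfirmed = 0L
  )
  f <- scaling_factors(var_hx_scal = 2, cons_scal = 3, base_scal = 5)
  dist <- c(1L, 4L, 9L, 9L)
  scores <- score_all(loci, ev, cons, f, distribution = dist)
  key <- paste(scores$position, scores$ref, scores$alt)

  # branch 1: reported variant, path score 1; cons = 1 on the gap panel
  r1 <- scores[key == paste(pos[1], refb[1], altb[1]), ]
  expect_equal(r1$branch, 1L)
  expect_equal(r1$var_hx_cons_score, 2 * 1 + 3 * 1)

  # branch 2 at the distribution maximum: full benign reward, pop = 0
  r2 <- scores[key == paste(pos[2], refb[2], altb[2]), ]
  expect_equal(r2$branch, 2L)
  expect_equal(r2$pop_score, 0)
  expect_equal(r2$var_hx_cons_score, 2 * (0 - 1) + 3 * 1)

  # branch 3 (novel, fully conserved column): base + cons
  r3 <- scores[key == paste(pos[3], refb[3], altb[3]), ]
  expect_equal(r3$branch, 3L)
  expect_equal(r3$var_hx_cons_score, 5 + 3 * 1)
})

test_that("score_all enumerates 4 alleles per position deterministically", {
  ds <- simulate_dataset(tiny_spec())
  scores <- score_all(ds$loci, ds$evidence, ds$conservation)
  expect_equal(nrow(scores), 4 * nrow(ds$loci))
  counts <- table(scores$position)
  expect_true(all(counts == 4))
  # deletion allele present exactly once per position
  expect_equal(sum(scores$alt == "del"), nrow(ds$loci))

  # rerun on identical inputs -> identical table
  again <- score_all(ds$loci, ds$evidence, ds$conservation)
  expect_identical(as.data.frame(scores), as.data.frame(again))

  # the summation identity holds exactly on every row
  f <- attr(scores, "factors")
  lhs <- scores$total_score
  rhs <- f$var_hx_cons_scal * scores$var_hx_cons_score +
    f$Pos_scal * scores$position_score +
    f$SS_scal * scores$secondary_structure_score
  expect_identical(lhs, rhs)
})

test_that("position score equals brute-force slot averaging", {
  ds <- simulate_dataset(small_spec(seed = 19))
  f <- scaling_factors(var_hx_scal = 1.7, cons_scal = 0.6,
                       var_hx_cons_scal = 2.2, SS_scal = 0.9,
                       Pos_scal = 1.4, base_scal = 0.3)
  scores <- score_all(ds$loci, ds$evidence, ds$conservation, f)

  # oracle: mean over positions in the slot of the per-position mean of the
  # 4 allele history-and-conservation scores, via plain aggregate()
  per_pos <- aggregate(var_hx_cons_score ~ gene + index_5p + slot_id,
                       data = as.data.frame(scores), FUN = mean)
  per_slot <- aggregate(var_hx_cons_score ~ slot_id, data = per_pos,
                        FUN = mean)
  oracle <- per_slot$var_hx_cons_score[match(scores$slot_id,
                                             per_slot$slot_id)]
  expect_equal(scores$position_score, oracle, tolerance = 1e-12)
})
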