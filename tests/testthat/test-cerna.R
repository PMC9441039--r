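test_that("hypergeometric overlap matches enumeration on worked cases", {
  expect_equal(hypergeom_overlap_p(0, 4, 5, 10), 1)
  expect_equal(hypergeom_overlap_p(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hyper_enum_p(4, 4, 5, 10), 6 / 252)
  expect_equal(hyper_enum_p(3, 4, 5, 10), 66 / 252)
  expect_error(hypergeom_overlap_p(5, 4, 5, 10), "invalid")
  expect_error(hypergeom_overlap_p(1, 4, 11, 10), "invalid")
  expect_error(hypergeom_overlap_p(-1, 4, 5, 10), "invalid")
})

test_that("hypergeometric overlap is monotone in k and symmetric in (K, n)", {
  for (N in c(8, 15, 40)) {
    K <- floor(N / 3); n <- floor(N / 2)
    p <- hypergeom_overlap_p(0:min(K, n), K, n, N)
    expect_true(all(diff(p) <= 1e-15))
    expect_equal(hypergeom_overlap_p(0:min(K, n), n, K, N), p,
                 tolerance = 1e-12)
  }
})

test_that("correlation helpers match their definitions", {
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 100, 1000)), 1)
  # ties via average ranks, checked against explicit rank-then-Pearson
  x <- c(1, 2, 2, 4); y <- c(2, 3, 3, 1)
  expect_equal(spearman_rho(x, y),
               stats::cor(rank(x), rank(y), method = "pearson"))
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  # direct product-moment arithmetic
  x2 <- c(0, 1, 2, 3); y2 <- c(1, 1, 2, 4)
  num <- sum((x2 - mean(x2)) * (y2 - mean(y2)))
  den <- sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  expect_equal(pearson_r(x2, y2), num / den)
  # degenerate input is flagged, never silently zero
  expect_warning(r1 <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r1))
  expect_warning(r2 <- pearson_r(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_true(is.na(r2))
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("cerna_params defines nested lenient/strict regimes", {
  len <- cerna_params("lenient")
  str <- cerna_params("strict")
  expect_equal(len$spearman_max, -0.7)
  expect_equal(len$pearson_min, 0.9)
  expect_equal(len$pair_p_max, 0.05)
  expect_null(len$pair_fdr_max)
  expect_equal(str$spearman_max, -0.95)
  expect_equal(str$pearson_min, 0.95)
  expect_equal(str$pair_p_max, 0.01)
  expect_equal(str$pair_fdr_max, 0.01)
  # strict thresholds sit inside the lenient ones
  expect_lte(str$spearman_max, len$spearman_max)
  expect_gte(str$pearson_min, len$pearson_min)
  expect_lte(str$pair_p_max, len$pair_p_max)
  expect_error(cerna_params("lenient", spearman_max = 0.2), "out of range")
})

make_score_fixture <- function() {
  # two lncRNAs, two mRNAs, ten miRNAs in the universe; lnc1/m1 is a real
  # sponge pair sharing mi1 and mi2, the other eight miRNAs only touch lnc2
  g <- toy_groups(3)
  sponge <- c(1, 2, 3, 10, 11, 12)          # up in B
  anti <- rev(sponge)                       # down in B, anti-ranked
  flat <- c(5, 6, 5.5, 5.2, 6.1, 5.8)
  lnc <- toy_expr(rbind(lnc1 = sponge, lnc2 = flat), class_label = "lncRNA",
                  lengths = c(1000, 1000), groups = g)
  mrna <- toy_expr(rbind(m1 = sponge * 2, m2 = flat), lengths = c(1000, 1000),
                  groups = g)
  others <- paste0("mi", 3:10)
  mirv <- rbind(mi1 = anti, mi2 = anti * 3)
  for (o in others) mirv <- rbind(mirv, flat + which(others == o) / 10)
  rownames(mirv) <- c("mi1", "mi2", others)
  mir <- toy_expr(mirv, class_label = "miRNA", groups = g)
  inter <- tibble::tibble(
    mirna_id = c("mi1", "mi1", "mi2", "mi2", others),
    transcript_id = c("lnc1", "m1", "lnc1", "m1", rep("lnc2", 8)))
  list(lnc = lnc, mrna = mrna, mir = mir, inter = inter)
}

test_that("score_cerna_pairs scores shared-miRNA pairs and gates them", {
  fx <- make_score_fixture()
  p <- score_cerna_pairs(fx$inter, fx$lnc, fx$mrna, fx$mir, cerna_params())
  # only lnc1-m1 shares miRNAs; lnc2 shares none with any mRNA
  expect_equal(nrow(p), 1)
  expect_equal(p$lncrna_id, "lnc1")
  expect_equal(p$mrna_id, "m1")
  expect_equal(p$k, 2)
  expect_equal(p$N, 10)
  expect_equal(p$shared_mirnas, "mi1;mi2")
  expect_equal(p$n_screening_mirnas, 2)
  expect_true(p$passed)
  expect_equal(p$hypergeom_p,
               hyper_enum_p(2, 2, 2, 10), tolerance = 1e-12)
  # both-arms screen semantics: breaking one arm removes the evidence
  mir2 <- fx$mir
  one_arm <- score_cerna_pairs(
    fx$inter[fx$inter$mirna_id != "mi2", ], fx$lnc, fx$mrna, fx$mir,
    cerna_params())
  expect_equal(one_arm$k, 1)
  # missing expression id is named
  expect_error(
    score_cerna_pairs(dplyr::add_row(fx$inter, mirna_id = "mi1",
                                     transcript_id = "ghost"),
                      fx$lnc, fx$mrna, fx$mir, cerna_params()),
    "ghost")
  # empty interaction table warns and returns an empty scored table
  expect_warning(e <- score_cerna_pairs(fx$inter[0, ], fx$lnc, fx$mrna,
                                        fx$mir, cerna_params()),
                 "empty")
  expect_equal(nrow(e), 0)
})

test_that("strict-regime pairs are a subset of lenient-regime pairs", {
  for (seed in c(13, 14, 15)) {
    run <- run_cerna_pipeline(
      cerna_config(simulate = list(n_mrna = 200, n_lncrna = 60, n_mirna = 40,
                                   n_planted_triples = 10, seed = seed)))
    len_keys <- with(run$pairs$lenient[run$pairs$lenient$passed, ],
                     paste(lncrna_id, mrna_id))
    str_keys <- with(run$pairs$strict[run$pairs$strict$passed, ],
                     paste(lncrna_id, mrna_id))
    expect_true(all(str_keys %in% len_keys))
  }
})

test_that("overrepresentation_test gives exact hypergeometric enrichment", {
  universe <- paste0("g", 1:20)
  term_map <- list(T1 = paste0("g", 1:10),   # half the universe
                   T2 = paste0("g", 15:20),  # disjoint from the query
                   T3 = paste0("g", 1:3))
  gene_set <- paste0("g", 1:10)
  res <- overrepresentation_test(gene_set, term_map, universe)
  r1 <- res[res$term == "T1", ]
  expect_equal(r1$p_value, hyper_enum_p(10, 10, 10, 20), tolerance = 1e-12)
  expect_equal(r1$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "T2"], 1)
  expect_equal(res$fdr, bh_bruteforce(res$p_value), tolerance = 1e-12)
  # universe == gene_set: every term's overlap is forced, p = 1
  res2 <- overrepresentation_test(universe, term_map, universe)
  expect_true(all(res2$p_value == 1))
  expect_error(overrepresentation_test(gene_set, term_map, character(0)),
               "empty universe")
  expect_error(overrepresentation_test(c("zz"), term_map, universe),
               "subset")
})
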