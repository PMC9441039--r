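test_that("read_counts parses a toy TSV and validates it", {
  dir <- withr::local_tempdir()
  counts <- file.path(dir, "counts.tsv")
  lens <- file.path(dir, "lengths.tsv")
  groups <- toy_groups(3)
  writeLines(c(paste(c("id", names(groups)), collapse = "\t"),
               "g1\t1\t2\t3\t4\t5\t6",
               "g2\t0\t0\t1\t1\t2\t2",
               "g3\t9\t8\t7\t6\t5\t4"), counts)
  writeLines(c("g1\t1000", "g2\t1500", "g3\t500"), lens)
  m <- read_counts(counts, "mRNA", groups, lens)
  expect_s3_class(m, "expr_mat")
  expect_equal(nrow(m), 3)
  expect_equal(length(expr_samples(m)), 6)
  expect_equal(m$length, c(1000, 1500, 500))
  expect_equal(expr_kind(m), "counts")

  # duplicated id named in the error
  writeLines(c(paste(c("id", names(groups)), collapse = "\t"),
               "g1\t1\t2\t3\t4\t5\t6",
               "g1\t0\t0\t1\t1\t2\t2"), counts)
  expect_error(read_counts(counts, "mRNA", groups, lens), "g1")

  # empty file is an error, not an empty matrix
  writeLines(paste(c("id", names(groups)), collapse = "\t"), counts)
  expect_error(read_counts(counts, "mRNA", groups, lens), "empty")

  # missing length
  writeLines(c(paste(c("id", names(groups)), collapse = "\t"),
               "g9\t1\t2\t3\t4\t5\t6"), counts)
  expect_error(read_counts(counts, "mRNA", groups, lens), "g9")
})

test_that("expr_mat rejects invalid input", {
  g <- toy_groups(1)
  tb <- tibble::tibble(id = "a", length = 100, CC_1 = -1, GC_1 = 2)
  expect_error(expr_mat(tb, "mRNA", g), "negative")
  tb2 <- tibble::tibble(id = "a", CC_1 = 1, GC_1 = 2)
  expect_error(expr_mat(tb2, "mRNA", g), "length")
  expect_silent(expr_mat(tb2, "miRNA", g))
  expect_error(expr_mat(tb2, "miRNA", c(CC_1 = "CC")), "groups")
})

test_that("FPKM follows its defining arithmetic", {
  # one transcript of 1000 bp with 100 of the sample's 1e6 counts -> 100
  g <- toy_groups(1)
  m <- toy_expr(cbind(c(100, 1e6 - 100), c(100, 1e6 - 100)),
                lengths = c(1000, 1000), groups = g)
  f <- fpkm_normalize(m)
  expect_equal(unname(expr_values(f)[1, 1]), 100)
  expect_equal(expr_kind(f), "FPKM")

  # uniform scaling of a column leaves FPKM unchanged
  v <- matrix(c(5, 10, 20, 7, 3, 11), nrow = 3)
  m1 <- toy_expr(v, lengths = c(500, 1000, 2000), groups = g)
  m2 <- toy_expr(v * rep(c(3, 1), each = 3), lengths = c(500, 1000, 2000),
                 groups = g)
  expect_equal(expr_values(fpkm_normalize(m1)),
               expr_values(fpkm_normalize(m2)))

  # zero counts stay zero; zero column total errors
  expect_equal(unname(expr_values(fpkm_normalize(
    toy_expr(cbind(c(0, 5), c(1, 1)), lengths = c(1000, 1000), groups = g)
  ))[1, 1]), 0)
  expect_error(fpkm_normalize(
    toy_expr(cbind(c(0, 0), c(1, 1)), lengths = c(1000, 1000), groups = g)),
    "zero column total")
})

test_that("TPM columns always sum to one million", {
  g <- toy_groups(1)
  mi <- tpm_normalize(toy_expr(cbind(c(10, 30, 60), c(1, 2, 3)),
                               class_label = "miRNA", groups = g))
  expect_equal(unname(expr_values(mi)[, 1]), c(1e5, 3e5, 6e5))
  expect_equal(unname(colSums(expr_values(mi))), c(1e6, 1e6),
               tolerance = 1e-6)

  # length-normalized variant for mRNA also sums to 1e6
  set.seed(42)
  v <- matrix(rpois(30, 100), nrow = 5)
  m <- tpm_normalize(toy_expr(v, lengths = c(300, 600, 900, 1200, 1500)))
  expect_equal(unname(colSums(expr_values(m))), rep(1e6, 6),
               tolerance = 1e-6)

  # single transcript gets the whole million
  one <- tpm_normalize(toy_expr(cbind(5, 9), class_label = "miRNA",
                                groups = g))
  expect_equal(unname(expr_values(one)[1, ]), c(1e6, 1e6))
})

test_that("normalization preserves within-sample ordering at equal length", {
  set.seed(7)
  v <- matrix(rpois(24, 50), nrow = 4)
  m <- toy_expr(v, lengths = rep(800, 4))
  for (f in list(fpkm_normalize, tpm_normalize)) {
    nv <- expr_values(f(m))
    for (s in seq_len(ncol(v))) {
      expect_equal(order(nv[, s]), order(v[, s]))
    }
  }
})

test_that("Welch de_test matches its definition", {
  g <- toy_groups(3)
  # group means 8 vs 2, pseudocount 0 -> log2fc = -2 (B relative to A)
  m <- toy_expr(matrix(c(8, 8, 8, 2, 2, 2), nrow = 1), groups = g)
  de <- de_test(m, pseudocount = 0)
  expect_equal(de$log2fc, -2)

  # identical groups: log2fc 0, p 1 under the zero-variance convention
  m2 <- toy_expr(matrix(c(5, 5, 5, 5, 5, 5), nrow = 1), groups = g)
  de2 <- de_test(m2)
  expect_equal(de2$log2fc, 0)
  expect_equal(de2$p_value, 1)

  # equal-variance zero with different means: deterministic difference
  m3 <- toy_expr(matrix(c(2, 2, 2, 8, 8, 8), nrow = 1), groups = g)
  expect_equal(de_test(m3)$p_value, 0)

  # toy 3v3 against the reference Welch implementation on logged values
  a <- c(10, 11, 9); b <- c(100, 110, 90)
  m4 <- toy_expr(matrix(c(a, b), nrow = 1), groups = g)
  de4 <- de_test(m4, pseudocount = 1)
  ref <- stats::t.test(log2(b + 1), log2(a + 1), var.equal = FALSE)
  expect_equal(de4$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(de4$log2fc, log2((mean(b) + 1) / (mean(a) + 1)))
})

test_that("moderated de_test shares fold changes with Welch and gains power
          at small n", {
  set.seed(31)
  n <- 300
  v <- matrix(rnbinom(n * 6, mu = 200, size = 50), nrow = n)
  shifted <- 1:20
  v[shifted, 4:6] <- rnbinom(20 * 3, mu = 800, size = 50)
  m <- toy_expr(v, lengths = rep(1000, n))
  w <- de_test(m, method = "welch")
  mod <- de_test(m, method = "moderated")
  expect_equal(mod$log2fc, w$log2fc)
  # moderation should produce smaller typical p on the truly shifted rows
  expect_lt(median(mod$p_value[shifted]), median(w$p_value[shifted]))
  expect_true(all(mod$p_value >= 0 & mod$p_value <= 1))
})

test_that("bh_fdr implements the step-up adjustment", {
  expect_equal(bh_fdr(c(0.005, 0.03, 0.5)), c(0.015, 0.045, 0.5))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.9, 0.01, 0.04, 0.5)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("bh_fdr agrees with the brute-force step-up oracle and is
          permutation-equivariant", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(1:100, 1)
    p <- runif(n)^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-12)
  }
})

test_that("filter_de applies the class-appropriate gates", {
  rec <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    log2fc = c(1.5, 1.5, -1.2, 0.5),
    p_value = c(0.0001, 0.03, 0.03, 0.001))
  # mRNA/lncRNA gate on FDR
  out <- filter_de(rec, "mRNA")
  expect_equal(out$call[1], "up")
  expect_true(all(out$fdr >= out$p_value))
  # FDR too high -> not_de even with large fold change
  rec2 <- tibble::tibble(id = letters[1:10], log2fc = rep(1.5, 10),
                         p_value = c(0.04, rep(0.9, 9)))
  out2 <- filter_de(rec2, "mRNA")
  expect_equal(out2$call[1], "not_de")  # fdr = 0.4
  # miRNA uses raw p, not FDR
  out3 <- filter_de(rec2, "miRNA")
  expect_equal(out3$call[1], "up")
  rec3 <- tibble::tibble(id = letters[1:10], log2fc = c(-1.2, rep(0, 9)),
                         p_value = c(0.03, rep(0.5, 9)))
  expect_equal(filter_de(rec3, "miRNA")$call[1], "down")
  # sub-threshold fold change never passes
  rec4 <- tibble::tibble(id = "a", log2fc = 0.9, p_value = 1e-8)
  expect_equal(filter_de(rec4, "mRNA")$call, "not_de")
  expect_error(filter_de(rec4, "tRNA"))
})

test_that("DE gates recover planted transcripts on synthetic data", {
  cfg <- small_sim(seed = 23, decoy_de_fraction = 0.1)
  ds <- simulate_cerna_dataset(cfg)
  calls <- list()
  for (cl in c("mrna", "lncrna", "mirna")) {
    x <- ds$counts[[cl]]
    norm <- if (cl == "mirna") tpm_normalize(x) else fpkm_normalize(x)
    calls[[cl]] <- filter_de(de_test(norm, method = "moderated"),
                             expr_class(x))
  }
  de_tab <- dplyr::bind_rows(calls)
  truth <- ds$truth_de
  called <- de_tab$id[de_tab$call != "not_de"]
  recall <- mean(truth$id %in% called)
  fdr <- mean(!called %in% truth$id)
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.1)
  # directions agree for recovered transcripts
  hit <- de_tab[de_tab$id %in% truth$id & de_tab$call != "not_de", ]
  dir <- truth$direction[match(hit$id, truth$id)]
  expect_true(all(hit$call == dir))
})
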