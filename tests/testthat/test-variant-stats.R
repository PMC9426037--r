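test_that("TMB is qualifying variants over panel megabases, with strict filters", {
  panel <- panel_spec()
  v <- make_variants("S1", "TP53", rep(0.2, 12))
  expect_equal(compute_tmb(v, panel)$tmb, 12 / 1.94)

  # the VAF threshold is strict: 0.05 itself does not qualify
  v2 <- make_variants("S1", "TP53", c(0.05, 0.04, 0.01))
  expect_equal(compute_tmb(v2, panel)$tmb, 0)

  # 5 somatic missense VAF 0.2 + 3 synonymous VAF 0.3 + 2 missense VAF 0.03
  v3 <- rbind(make_variants("S1", "TP53", rep(0.2, 5)),
              make_variants("S1", "TP53", rep(0.3, 3),
                            classification = "synonymous"),
              make_variants("S1", "TP53", rep(0.03, 2)))
  r3 <- compute_tmb(v3, panel)
  expect_equal(r3$n_qualifying_variants, 5L)
  expect_equal(r3$tmb, 5 / 1.94)
})

test_that("TMB retains zero-variant samples and rejects unknown classifications", {
  panel <- panel_spec()
  v <- make_variants("S1", "TP53", 0.2)
  out <- compute_tmb(v, panel, sample_ids = c("S1", "S2", "S3"))
  expect_equal(out$sample_id, c("S1", "S2", "S3"))
  expect_equal(out$tmb, c(1 / 1.94, 0, 0))

  bad <- make_variants("S1", "TP53", 0.2)
  bad$variant_classification <- "weird"
  expect_error(compute_tmb(bad, panel), "unknown variant_classification")
})

test_that("TMB is invariant to adding synonymous or sub-threshold variants", {
  panel <- panel_spec()
  set.seed(41)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    base <- make_variants(sample(c("A", "B"), n, replace = TRUE), "GENE",
                          runif(n, 0.06, 0.9),
                          classification = sample(c("missense", "nonsense",
                                                    "frameshift"), n,
                                                  replace = TRUE))
    extra <- rbind(
      make_variants("A", "GENE", runif(5, 0.1, 0.9),
                    classification = "synonymous"),
      make_variants("B", "GENE", runif(5, 0.001, 0.05)),
      make_variants("A", "GENE", runif(3, 0.3, 0.6), origin = "germline"))
    ids <- c("A", "B")
    expect_equal(compute_tmb(base, panel, sample_ids = ids)$tmb,
                 compute_tmb(rbind(base, extra), panel,
                             sample_ids = ids)$tmb)
  }
})

test_that("MSI fraction and flag follow the unstable-locus ratio", {
  mk <- function(unstable, total = 120, id = "S1") {
    data.frame(sample_id = id,
               locus = sprintf("L%03d", seq_len(total)),
               call = c(rep("unstable", unstable),
                        rep("stable", total - unstable)),
               stringsAsFactors = FALSE)
  }
  expect_equal(msi_score(mk(48))$msi_fraction, 0.40)
  expect_true(msi_score(mk(48))$msi_flag)

  zero <- msi_score(mk(0))
  expect_equal(zero$msi_fraction, 0)
  expect_false(zero$msi_flag)

  # the MSI-high threshold is inclusive at 0.20
  edge <- msi_score(mk(24))
  expect_equal(edge$msi_fraction, 0.20)
  expect_true(edge$msi_flag)

  expect_error(msi_score(mk(0)[0, ]), "empty")
  badcall <- mk(1); badcall$call[5] <- "maybe"
  expect_error(msi_score(badcall), "invalid locus call")
})

test_that("mutation frequency collapses multiple variants per sample and gene", {
  samples <- data.frame(sample_id = sprintf("S%02d", 1:10),
                        her2_class = "HLBC-1", stringsAsFactors = FALSE)
  v <- make_variants(c("S01", "S01"), "PIK3CA", c(0.2, 0.4))
  tab <- mutation_frequency_table(v, samples, group_by = NULL)$table
  expect_equal(tab$frac_total[tab$gene == "PIK3CA"], 1 / 10)
  expect_equal(tab$n_total[tab$gene == "PIK3CA"], 1L)

  # empty variant table keeps the full gene index at zero
  empty <- mutation_frequency_table(v[0, ], samples, group_by = NULL,
                                    genes = c("PIK3CA", "TP53"))$table
  expect_equal(nrow(empty), 2L)
  expect_true(all(empty$n_total == 0))

  orphan <- make_variants("S99", "TP53", 0.3)
  expect_error(mutation_frequency_table(orphan, samples), "S99")
})

test_that("per-gene mutated-sample counts agree with a direct tally", {
  set.seed(7)
  samples <- data.frame(sample_id = sprintf("S%02d", 1:20),
                        her2_class = sample(c("a", "b"), 20, replace = TRUE),
                        stringsAsFactors = FALSE)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    v <- make_variants(sample(samples$sample_id, n, replace = TRUE),
                       sample(c("G1", "G2", "G3"), n, replace = TRUE),
                       runif(n, 0.06, 0.9))
    tab <- mutation_frequency_table(v, samples)$table
    for (g in unique(v$gene)) {
      direct <- length(unique(v$sample_id[v$gene == g]))
      expect_equal(tab$n_total[tab$gene == g], direct)
    }
  }
})

test_that("gene ranking uses overall frequency with lexicographic tie-break", {
  samples <- data.frame(sample_id = c("S1", "S2"), her2_class = "x",
                        stringsAsFactors = FALSE)
  v <- make_variants(c("S1", "S1", "S2"), c("ZZZ", "AAA", "MMM"),
                     rep(0.2, 3))
  tab <- mutation_frequency_table(v, samples)$table
  expect_equal(tab$gene, c("AAA", "MMM", "ZZZ"))  # all tied at 1 sample
})

test_that("group mean comparison matches Welch's t-test", {
  res <- group_mean_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$pairs$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$pairs$t, unname(oracle$statistic), tolerance = 1e-12)
  # textbook closed form: t = -3 / sqrt(2/3), df = 4
  expect_equal(res$pairs$t, -3 / sqrt(2 / 3))
  expect_equal(res$pairs$p, 2 * pt(-abs(-3 / sqrt(2 / 3)), 4))

  same <- group_mean_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$pairs$t, 0)
  expect_equal(same$pairs$p, 1)

  # zero-variance group: CI collapses onto the mean
  zv <- group_mean_test(c(5, 5, 5, 1, 2, 3), rep(c("a", "b"), each = 3))
  a_row <- zv$groups[zv$groups$group == "a", ]
  expect_equal(a_row$ci_lo, 5)
  expect_equal(a_row$ci_hi, 5)

  expect_error(group_mean_test(c(1, 2, 3), c("a", "a", "b")), "b")
})

test_that("group mean comparison agrees with stats::t.test on random inputs", {
  set.seed(13)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, sd = runif(1, 0.5, 2))
    res <- group_mean_test(c(x, y), rep(c("a", "b"), c(n1, n2)))
    oracle <- t.test(x, y)
    expect_equal(res$pairs$p, oracle$p.value, tolerance = 1e-10)
    expect_equal(res$pairs$df, unname(oracle$parameter), tolerance = 1e-10)
  }
})

test_that("96-context catalogs bin qualifying SNVs only", {
  v <- make_variants(c("S1", "S1"), "TP53", c(0.3, 0.5),
                     context = "A[C>T]G")
  cat96 <- build_96_catalog(v)
  expect_equal(sum(cat96), 2)
  expect_equal(unname(cat96["A[C>T]G"]), 2L)

  # the catalog VAF filter is strict at 0.1
  low <- make_variants("S1", "TP53", 0.08, context = "A[C>T]G")
  expect_equal(sum(build_96_catalog(low)), 0)
  at <- make_variants("S1", "TP53", 0.1, context = "A[C>T]G")
  expect_equal(sum(build_96_catalog(at)), 0)

  # non-SNVs are ignored even at high VAF
  indel <- make_variants("S1", "TP53", 0.4, classification = "frameshift")
  expect_equal(sum(build_96_catalog(indel)), 0)

  expect_equal(sum(build_96_catalog(v[0, ])), 0)
  expect_length(build_96_catalog(v[0, ]), 96)

  bad <- make_variants("S1", "TP53", 0.4, context = "A[C-T]G")
  expect_error(build_96_catalog(bad), "malformed context96")
})

test_that("signature refitting recovers exact mixtures with zero residual", {
  ref <- synthetic_signatures(8)
  catalog <- 1000 * (0.7 * ref[, 1] + 0.3 * ref[, 5])
  fit <- fit_signatures(catalog, ref)
  expect_lt(max(abs(fit$weights - c(S1 = 0.7, 0, 0, 0, S5 = 0.3, 0, 0, 0))),
            1e-8)
  expect_lt(fit$residual, 1e-10)

  pure <- fit_signatures(500 * ref[, 3], ref)
  expect_equal(unname(pure$weights["S3"]), 1, tolerance = 1e-8)

  expect_error(fit_signatures(rep(0, 96), ref), "empty catalog")
})

test_that("signature refitting approximates mixture weights from finite catalogs", {
  ref <- synthetic_signatures(8)
  set.seed(21)
  probs <- 0.5 * ref[, 1] + 0.5 * ref[, 5]
  ok <- 0
  for (i in 1:5) {
    catalog <- as.numeric(rmultinom(1, 500, probs))
    fit <- fit_signatures(catalog, ref)
    oracle <- nnls_pg(ref, catalog / sum(catalog))
    oracle <- oracle / sum(oracle)
    expect_lt(max(abs(fit$weights - oracle)), 1e-3)
    if (max(abs(fit$weights - c(0.5, 0, 0, 0, 0.5, 0, 0, 0))) < 0.1)
      ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("NNLS residual is zero whenever the catalog lies in the reference cone", {
  ref <- synthetic_signatures(6)
  set.seed(33)
  for (i in 1:10) {
    w <- runif(6); w <- w / sum(w)
    fit <- fit_signatures(700 * as.numeric(ref %*% w), ref)
    expect_lt(fit$residual, 1e-10)
    expect_lt(max(abs(fit$weights - w)), 1e-6)
  }
})
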