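block_matrix <- function(n_per_block = 12, genes_per_block = 15, k = 3,
                         noise = 0.02, seed = 1) {
  set.seed(seed)
  n <- n_per_block * k
  V <- matrix(noise * runif(genes_per_block * k * n),
              genes_per_block * k, n)
  for (b in seq_len(k)) {
    rows <- (b - 1) * genes_per_block + seq_len(genes_per_block)
    cols <- (b - 1) * n_per_block + seq_len(n_per_block)
    V[rows, cols] <- V[rows, cols] + runif(length(rows) * length(cols), 2, 4)
  }
  dimnames(V) <- list(sprintf("g%03d", seq_len(nrow(V))),
                      sprintf("s%03d", seq_len(n)))
  list(V = V, truth = rep(seq_len(k), each = n_per_block))
}

test_that("variable-gene selection uses the floor rule with lexicographic ties", {
  set.seed(2)
  m9 <- matrix(rnorm(9 * 10), 9, 10,
               dimnames = list(paste0("g", 1:9), paste0("s", 1:10)))
  expect_length(select_variable_genes(m9, 0.33), 2)  # floor(2.97) = 2

  m776 <- matrix(rnorm(776 * 5), 776, 5,
                 dimnames = list(sprintf("g%04d", 1:776), paste0("s", 1:5)))
  expect_length(select_variable_genes(m776, 0.33), 256)  # floor(256.08)

  const <- matrix(1, 6, 4, dimnames = list(c("d", "b", "f", "a", "c", "e"),
                                           paste0("s", 1:4)))
  expect_equal(select_variable_genes(const, 0.5), c("a", "b", "c"))

  expect_error(select_variable_genes(m9, 0), "fraction")
  expect_error(select_variable_genes(m9, 1.2), "fraction")
})

test_that("KL-NMF recovers exact low-rank factorizations and stays nonnegative", {
  set.seed(14)
  W0 <- matrix(runif(40, 0.5, 2), 20, 2)
  H0 <- matrix(runif(24, 0.2, 1.5), 2, 12)
  V <- W0 %*% H0
  fit <- nmf_factorize(V, 2, seed = 5, max_iter = 5000)
  expect_lt(fit$kl, 1e-6)
  expect_true(min(fit$W) >= 0 && min(fit$H) >= 0)
  expect_equal(dim(fit$W), c(20L, 2L))
  expect_equal(dim(fit$H), c(2L, 12L))

  refit <- nmf_factorize(V, 2, seed = 5, max_iter = 5000)
  expect_identical(fit$W, refit$W)
  expect_identical(fit$H, refit$H)

  V0 <- V; V0[3, ] <- 0
  expect_error(nmf_factorize(V0, 2), "all-zero")
  expect_error(nmf_factorize(V, 25), "k must satisfy")
  expect_error(nmf_factorize(-V, 2), "nonnegative")
})

test_that("the KL objective is nonincreasing across update sweeps", {
  set.seed(15)
  V <- matrix(runif(300, 0.1, 5), 20, 15)
  fit <- nmf_factorize(V, 3, seed = 2, max_iter = 400, tol = 0,
                       check_every = 1)
  expect_true(all(diff(fit$trace) <= 1e-8))
})

test_that("consensus NMF is perfectly stable on separable planted blocks", {
  bm <- block_matrix(n_per_block = 10, k = 3, seed = 4)
  res <- consensus_nmf(bm$V, k_range = 2:4, n_runs = 8, seed = 6)
  r3 <- res[["3"]]
  expect_true(all(r3$consensus %in% c(0, 1)))
  expect_equal(r3$cophenetic, 1, tolerance = 1e-12)
  expect_equal(mclust::adjustedRandIndex(r3$labels, bm$truth), 1)
  for (r in res) {
    expect_true(isSymmetric(r$consensus))
    expect_true(all(diag(r$consensus) == 1))
    expect_true(all(r$consensus >= 0 & r$consensus <= 1))
  }
})

test_that("rank selection ranks cophenetics after discarding overlapping clusterings", {
  fake <- function(k, coph, labels) {
    structure(list(k = k, consensus = diag(length(labels)), labels = labels,
                   cophenetic = coph, silhouette = 0.5, n_runs = 10),
              class = "consensus_nmf_result")
  }
  ext <- rep(c("LumA", "LumB", "Basal"), each = 10)
  same_as_ext <- as.integer(factor(ext))
  novel <- rep(1:3, 10)
  results <- list("2" = fake(2, 0.99, same_as_ext),
                  "3" = fake(3, 0.95, novel))
  sel <- select_rank(results, ext, overlap_threshold = 0.6)
  expect_equal(sel$chosen_k, 3)
  expect_true(sel$candidates$discarded[sel$candidates$k == 2])

  # random external labels: selection reduces to pure cophenetic ranking
  set.seed(3)
  ext_rand <- sample(c("LumA", "LumB", "Basal"), 30, replace = TRUE)
  sel2 <- select_rank(results, ext_rand, overlap_threshold = 0.6)
  expect_equal(sel2$chosen_k, 2)

  # every K recapitulates the external labels: no novel clustering
  both_ext <- list("2" = fake(2, 0.99, same_as_ext),
                   "3" = fake(3, 0.95, same_as_ext))
  expect_error(select_rank(both_ext, ext), "no novel clustering")

  # optional minimum-K constraint
  sel3 <- select_rank(results, ext_rand, min_k = 3)
  expect_equal(sel3$chosen_k, 3)
  expect_error(select_rank(results, rep("x", 10)), "cover all samples")
})

test_that("cluster characterization reports per-cluster statistics", {
  set.seed(23)
  cohort <- generate_cohort(cohort_config(n_per_group = c(12L, 10L, 14L),
                                          seed = 7L))
  labels <- setNames(rep(1:3, length.out = 36), cohort$samples$sample_id)
  tmb <- compute_tmb(cohort$variants, cohort$panel,
                     sample_ids = cohort$samples$sample_id)
  reports <- characterize_clusters(labels, cohort$samples, cohort$variants,
                                   tmb, cn = cohort$cn)
  expect_length(reports, 3)
  expect_equal(vapply(reports, function(r) r$n, numeric(1)),
               c("1" = 12, "2" = 12, "3" = 12))
  r1 <- reports[["1"]]
  expect_s3_class(r1, "cluster_report")
  expect_true(all(r1$mutation_tests$p_adj >= r1$mutation_tests$p - 1e-12))
  expect_true(is.finite(r1$mean_erbb2_fc))
  expect_equal(sum(r1$pam50_composition), 12)

  # planted enrichment is detected
  pik <- make_variants(cohort$samples$sample_id[labels == 1], "NEWGENE",
                       rep(0.3, 12))
  reports2 <- characterize_clusters(labels, cohort$samples,
                                    rbind(cohort$variants, pik), tmb,
                                    genes = "NEWGENE")
  expect_lt(reports2[["1"]]$mutation_tests$p, 0.01)

  # singleton clusters are skipped with a warning
  labels2 <- labels; labels2[] <- 1; labels2[1] <- 2
  expect_warning(characterize_clusters(labels2, cohort$samples,
                                       cohort$variants, tmb),
                 "singleton")
})
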