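make_expr <- function(n_genes = 30, n_samples = 20, seed = 1,
                      n_hk = 3, hk_level = 100) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_samples, 1, 50), n_genes, n_samples,
              dimnames = list(c(sprintf("HK%d", seq_len(n_hk)),
                                sprintf("G%03d", seq_len(n_genes - n_hk))),
                              sprintf("S%03d", seq_len(n_samples))))
  m[seq_len(n_hk), ] <- hk_level
  m
}

test_that("housekeeping normalization has unit factors for balanced samples", {
  raw <- make_expr()
  norm <- normalize_expression(raw, c("HK1", "HK2", "HK3"))
  expect_equal(unname(norm$scale_factors), rep(1, ncol(raw)))
  expect_equal(norm$values, log2(raw + 1))
})

test_that("normalization is scale-invariant given a fixed reference", {
  raw <- make_expr()
  norm <- normalize_expression(raw, c("HK1", "HK2", "HK3"))
  doubled <- raw
  doubled[, 5] <- 2 * doubled[, 5]
  renorm <- normalize_expression(doubled, c("HK1", "HK2", "HK3"),
                                 ref_mean = norm$ref_mean)
  expect_equal(renorm$values[, 5], norm$values[, 5], tolerance = 1e-12)
})

test_that("normalization errors on missing or zero housekeeping genes", {
  raw <- make_expr()
  expect_error(normalize_expression(raw, c("HK1", "NOT_THERE")),
               "NOT_THERE")
  raw0 <- raw; raw0["HK2", 4] <- 0
  expect_error(normalize_expression(raw0, c("HK1", "HK2")), "S004")
})

test_that("differential expression recovers planted shifts and nulls", {
  set.seed(8)
  n <- 80
  values <- matrix(rnorm(200 * n, 5, 0.2), 200, n,
                   dimnames = list(sprintf("G%03d", 1:200),
                                   sprintf("S%03d", 1:n)))
  group <- factor(rep(c("ref", "tgt"), each = n / 2),
                  levels = c("ref", "tgt"))
  # plant an exact 1-unit (2x) shift on the log2 scale
  values["G001", group == "tgt"] <- values["G001", group == "tgt"] + 1
  res <- dge(values, group)
  expect_equal(res$log2fc[res$gene == "G001"], 1, tolerance = 0.05)
  expect_lt(res$p_adj[res$gene == "G001"], 1e-6)
  expect_true(all(sign(res$t) == sign(res$log2fc) | res$t == 0))
  expect_true(all(res$p_adj >= res$p - 1e-12))

  # identical groups: everything null
  null_values <- values[, c(which(group == "ref"), which(group == "ref"))]
  res0 <- dge(null_values, rep(c("a", "b"), each = n / 2))
  expect_true(all(abs(res0$t) < 1e-8))
  expect_true(all(res0$p_adj > 0.999))
})

test_that("covariates absorb confounded effects", {
  set.seed(9)
  n <- 60
  er <- rep(c("pos", "neg"), each = n / 2)
  group <- factor(ifelse(er == "pos", "tgt", "ref"), levels = c("ref", "tgt"))
  values <- matrix(rnorm(50 * n, 5, 0.3), 50, n,
                   dimnames = list(sprintf("G%03d", 1:50), NULL))
  # the shift follows ER exactly, so the group term is aliased with ER
  values["G001", er == "pos"] <- values["G001", er == "pos"] + 2
  expect_error(dge(values, group, covariates = data.frame(er = er)),
               "rank-deficient")
  # with a partially confounded design the covariate absorbs the ER effect
  group2 <- group
  flip <- c(1:5, (n / 2 + 1):(n / 2 + 5))
  group2[flip] <- ifelse(group2[flip] == "tgt", "ref", "tgt")
  res <- dge(values, group2, covariates = data.frame(er = er))
  expect_lt(abs(res$t[res$gene == "G001"]), 3)
  res_naive <- dge(values, group2)
  expect_gt(abs(res_naive$t[res_naive$gene == "G001"]),
            abs(res$t[res$gene == "G001"]))
})

test_that("pathway scores are oriented PC1 of the centered gene-set submatrix", {
  raw <- make_expr(n_genes = 10, n_samples = 15, seed = 4)
  norm <- normalize_expression(raw, c("HK1", "HK2", "HK3"))

  # single-gene set: score equals the centered gene, up to positive scale
  s1 <- pathway_score(norm, "G001")
  g <- norm$values["G001", ] - mean(norm$values["G001", ])
  expect_equal(abs(cor(s1, g)), 1, tolerance = 1e-12)
  expect_gt(cor(s1, norm$values["G001", ]), 0)

  # two perfectly correlated genes: PC1 explains all variance
  vals <- norm$values
  vals["G002", ] <- 2 * vals["G001", ] + 3
  expect_equal(attr(pathway_score(vals, c("G001", "G002")),
                    "var_explained"), 1, tolerance = 1e-12)

  # anti-correlated pair: orientation is deterministic and matches an
  # explicit eigen-decomposition oracle
  vals["G003", ] <- -vals["G001", ] + 10
  sc <- pathway_score(vals, c("G001", "G003"))
  sub <- vals[c("G001", "G003"), ]
  centered <- sub - rowMeans(sub)
  ev <- eigen(tcrossprod(centered) / (ncol(sub) - 1))
  lvec <- ev$vectors[, 1]
  oracle <- as.numeric(t(centered) %*% lvec)
  orient <- suppressWarnings(cor(oracle, colMeans(sub)))
  if (!is.finite(orient) || abs(orient) < 1e-9) orient <- sum(lvec)
  if (abs(orient) < 1e-9) orient <- oracle[which(abs(oracle) > 1e-9)[1]]
  if (orient < 0) oracle <- -oracle
  expect_equal(as.numeric(sc), oracle, tolerance = 1e-8)

  expect_error(pathway_score(norm, c("NOPE1", "NOPE2")), "empty intersection")
})

test_that("pathway score is invariant to adding a constant to every gene", {
  raw <- make_expr(n_genes = 12, n_samples = 18, seed = 6)
  norm <- normalize_expression(raw, c("HK1", "HK2", "HK3"))
  set <- c("G002", "G004", "G007")
  base <- pathway_score(norm$values, set)
  shifted <- pathway_score(norm$values + 5, set)
  expect_equal(unname(base), unname(shifted), tolerance = 1e-10)
})

test_that("cell-type scores are mean marker expression", {
  vals <- matrix(3, 4, 5, dimnames = list(paste0("M", 1:4),
                                          paste0("S", 1:5)))
  sc <- cell_type_score(vals, list(ct = c("M1", "M2")))
  expect_equal(unname(sc[, "ct"]), rep(3, 5))

  vals2 <- matrix(rnorm(20), 4, 5, dimnames = dimnames(vals))
  one <- cell_type_score(vals2, list(ct = "M3"))
  expect_equal(unname(one[, "ct"]), unname(vals2["M3", ]))

  # linear on the log2 scale: adding 1 to each marker adds 1 to the score
  plus <- vals2; plus[c("M1", "M2"), ] <- plus[c("M1", "M2"), ] + 1
  expect_equal(cell_type_score(plus, list(ct = c("M1", "M2")))[, "ct"],
               cell_type_score(vals2, list(ct = c("M1", "M2")))[, "ct"] + 1)

  expect_error(cell_type_score(vals2, list(ct = "ABSENT")), "empty marker")
})

test_that("GSS and directed GSS follow their closed forms", {
  d <- data.frame(gene = c("A", "B", "C", "D", "E"),
                  t = c(2, -2, 3, -3, -3), stringsAsFactors = FALSE)
  res <- gss(d, list(sym = c("A", "B"), single = "C", neg = c("D", "E")))
  expect_equal(res$gss[res$set == "sym"], 2)
  expect_equal(res$dgss[res$set == "sym"], 0)
  expect_equal(res$gss[res$set == "single"], 3)
  expect_equal(res$dgss[res$set == "single"], 3)
  expect_equal(res$gss[res$set == "neg"], 3)
  expect_equal(res$dgss[res$set == "neg"], -3)
  expect_error(gss(d, list(bad = "ZZ")), "empty intersection")
})

test_that("|dGSS| <= GSS with equality only under a single sign, and GSS is permutation-invariant", {
  set.seed(10)
  for (i in 1:300) {
    k <- sample(1:12, 1)
    t <- rnorm(k, sd = 2)
    d <- data.frame(gene = paste0("g", seq_len(k)), t = t,
                    stringsAsFactors = FALSE)
    res <- gss(d, list(s = d$gene))
    expect_lte(abs(res$dgss), res$gss + 1e-12)
    if (all(t > 0) || all(t < 0))
      expect_equal(abs(res$dgss), res$gss, tolerance = 1e-12)
    perm <- gss(d, list(s = sample(d$gene)))
    expect_equal(perm$gss, res$gss, tolerance = 1e-12)
    expect_equal(perm$dgss, res$dgss, tolerance = 1e-12)
  }
})
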