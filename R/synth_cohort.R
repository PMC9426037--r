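#' Targeted-panel specification
#'
#' Describes the targeted DNA panel: the gene list, the sequenced footprint in
#' megabases, the number of microsatellite loci scored for instability, and
#' the subset of genes with copy-number calls.
#'
#' @param n_genes panel size (default 523).
#' @param panel_mb sequenced footprint in Mb (default 1.94).
#' @param msi_loci number of microsatellite loci (default 120).
#' @param n_cn_genes number of copy-number genes (default 59, subset of the
#'   panel).
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(n_genes = 523, panel_mb = 1.94, msi_loci = 120,
                       n_cn_genes = 59) {
  if (panel_mb <= 0) stop_config("panel_mb", "must be > 0")
  if (n_cn_genes > n_genes) stop_config("n_cn_genes", "must be <= n_genes")
  named <- c("PIK3CA", "GATA3", "TP53", "ERBB2", "CBFB", "CDH1", "ESR1",
             "SPEN", "BRCA1", "BRCA2", "PALB2", "BARD1", "MAP3K1", "KMT2C",
             "AKT1", "PTEN", "CCND1", "FGFR1", "FGF3", "FGF4", "FGF19",
             "MET", "KRAS", "MYC", "NRG1", "RB1", "CDK4", "NF1", "ARID1A",
             "RUNX1")
  filler <- sprintf("PANEL_G%03d", seq_len(max(0, n_genes - length(named))))
  gene_list <- c(named, filler)[seq_len(n_genes)]
  cn_named <- c("ERBB2", "CCND1", "FGFR1", "FGF3", "FGF4", "FGF19", "MET",
                "KRAS", "MYC", "PTEN", "NRG1", "CDK4", "RB1", "AKT1")
  cn_genes <- c(cn_named,
                gene_list[!(gene_list %in% cn_named)])[seq_len(n_cn_genes)]
  structure(list(gene_list = gene_list, panel_mb = panel_mb,
                 msi_loci = msi_loci, cn_genes = cn_genes),
            class = "panel_spec")
}

#' Configuration for the synthetic HLBC-like cohort generator
#'
#' Defaults reproduce the structure of a three-subgroup HER2-low cohort:
#' 34 score-1+ (HLBC-1), 15 score-2+ FISH-negative (HLBC-2N) and 50 score-2+
#' FISH-equivocal (HLBC-2E) tumors; PIK3CA/GATA3/TP53 driver prevalences of
#' roughly 31/18/17 percent with ERBB2 mutations confined to HLBC-2E;
#' subgroup mean TMB of 8.46/4.70/5.18 mut/Mb; subgroup mean VAF of
#' 0.175/0.244/0.256 (Beta with concentration 20); an ERBB2 copy-number
#' fold-change gradient rising across the subgroups; and an expression matrix
#' with four planted nonnegative metagenes.
#'
#' @param n_per_group integer counts for HLBC-1 / HLBC-2N / HLBC-2E.
#' @param mutation_prevalence named list: gene -> numeric length-3 per-group
#'   Bernoulli rate.
#' @param vaf_mean per-group Beta mean of variant allele frequency.
#' @param vaf_concentration Beta concentration (shape1 + shape2).
#' @param tmb_mean per-group mean qualifying mutations per megabase.
#' @param erbb2_cn_mean per-group mean ERBB2 copy-number fold change.
#' @param n_metagenes number of planted expression metagenes K*.
#' @param metagene_fractions sample fractions per planted cluster (length
#'   `n_metagenes`, summing to 1).
#' @param bleed between-block leakage of the planted metagenes, in [0, 1);
#'   larger values make cluster recovery harder.
#' @param noise_sd standard deviation of the additive truncated-Gaussian
#'   expression noise, on the metagene signal scale (in-block signal is O(3)).
#' @param msi_high_rate per-sample probability of a hypermutated, MSI-high
#'   profile (TMB about 42.5 mut/Mb, 40 percent unstable loci).
#' @param panel a [panel_spec()].
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(34L, 15L, 50L),
                          mutation_prevalence = NULL,
                          vaf_mean = c(0.175, 0.244, 0.256),
                          vaf_concentration = 20,
                          tmb_mean = c(8.46, 4.70, 5.18),
                          erbb2_cn_mean = c(1.0, 1.7, 2.5),
                          n_metagenes = 4L,
                          metagene_fractions = c(12, 28, 15, 30) / 85,
                          bleed = 0.05,
                          noise_sd = 0.2,
                          msi_high_rate = 0.01,
                          panel = panel_spec(),
                          seed = 1L) {
  if (length(n_per_group) != 3 || any(n_per_group <= 0))
    stop_config("n_per_group", "three positive group sizes required")
  if (is.null(mutation_prevalence))
    mutation_prevalence <- list(
      PIK3CA = c(0.31, 0.31, 0.31),
      GATA3  = c(0.21, 0.07, 0.19),
      TP53   = c(0.21, 0.07, 0.16),
      ERBB2  = c(0.00, 0.00, 0.16),
      CBFB   = c(0.03, 0.20, 0.03),
      CDH1   = c(0.10, 0.10, 0.10),
      MAP3K1 = c(0.08, 0.08, 0.08),
      KMT2C  = c(0.10, 0.10, 0.10),
      ESR1   = c(0.03, 0.03, 0.03),
      BRCA2  = c(0.03, 0.03, 0.03))
  for (g in names(mutation_prevalence))
    check_prob(mutation_prevalence[[g]], paste0("mutation_prevalence$", g))
  check_prob(vaf_mean, "vaf_mean")
  check_prob(msi_high_rate, "msi_high_rate")
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  if (any(tmb_mean < 0)) stop_config("tmb_mean", "must be >= 0")
  if (n_metagenes < 2) stop_config("n_metagenes", "must be >= 2")
  if (length(metagene_fractions) != n_metagenes)
    stop_config("metagene_fractions", "length must equal n_metagenes")
  if (bleed < 0 || bleed >= 1) stop_config("bleed", "must be in [0, 1)")
  structure(list(n_per_group = as.integer(n_per_group),
                 mutation_prevalence = mutation_prevalence,
                 vaf_mean = vaf_mean, vaf_concentration = vaf_concentration,
                 tmb_mean = tmb_mean, erbb2_cn_mean = erbb2_cn_mean,
                 n_metagenes = as.integer(n_metagenes),
                 metagene_fractions = metagene_fractions,
                 bleed = bleed, noise_sd = noise_sd,
                 msi_high_rate = msi_high_rate, panel = panel,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Beta draws with given mean/concentration, truncated to (lo, hi]
rbeta_trunc <- function(n, mean, conc, lo = 0, hi = 1) {
  a <- mean * conc
  b <- (1 - mean) * conc
  u <- runif(n, pbeta(lo, a, b), pbeta(hi, a, b))
  pmin(pmax(qbeta(u, a, b), lo + 1e-9), hi)
}

random_protein_change <- function(n, classification) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  pos <- sample.int(900, n, replace = TRUE)
  ref <- sample(aa, n, replace = TRUE)
  alt <- sample(aa, n, replace = TRUE)
  suffix <- ifelse(classification == "nonsense", "*",
            ifelse(classification == "frameshift", "fs",
            ifelse(classification == "splice", "_splice",
            ifelse(classification == "inframe_indel", "del", alt))))
  ifelse(classification == "synonymous",
         paste0("p.", ref, pos, "="),
         paste0("p.", ref, pos, suffix))
}

# draw variant rows for one subgroup; returns a data frame in variant-call
# layout (sample_id, gene, protein_change, variant_type,
# variant_classification, vaf, origin, pathogenicity, context96)
simulate_group_variants <- function(sample_ids, prevalence, vaf_mean, conc,
                                    tmb_mean, panel, ctx_prob, msi_high) {
  n <- length(sample_ids)
  rows <- list()
  # drivers: one non-synonymous somatic variant per flagged sample and gene
  for (gene in names(prevalence)) {
    hit <- which(rbinom(n, 1, prevalence[[gene]]) == 1)
    if (length(hit) > 0)
      rows[[length(rows) + 1]] <- data.frame(sample_id = sample_ids[hit],
                                             gene = gene,
                                             stringsAsFactors = FALSE)
  }
  # passengers fill the gap to the target qualifying-variant rate; drawn
  # outside the configured driver genes so per-gene prevalence stays exact
  passenger_pool <- setdiff(panel$gene_list, names(prevalence))
  lambda <- max(0, tmb_mean * panel$panel_mb - sum(unlist(prevalence)))
  lam_vec <- rep(lambda, n)
  lam_vec[msi_high] <- max(lambda, 42.52 * panel$panel_mb)
  n_pass <- rpois(n, lam_vec)
  if (sum(n_pass) > 0)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = rep(sample_ids, n_pass),
      gene = sample(passenger_pool, sum(n_pass), replace = TRUE),
      stringsAsFactors = FALSE)
  qual <- do.call(rbind, rows)
  if (is.null(qual))
    qual <- data.frame(sample_id = character(0), gene = character(0),
                       stringsAsFactors = FALSE)
  nq <- nrow(qual)
  qual$variant_classification <- sample(.NONSYN, nq, replace = TRUE,
                                        prob = c(0.70, 0.08, 0.10, 0.06, 0.06))
  qual$vaf <- rbeta_trunc(nq, vaf_mean, conc, lo = 0.05)
  qual$origin <- "somatic"

  # non-qualifying extras: synonymous SNVs and sub-threshold VAF calls
  n_syn <- rpois(n, 1.0)
  n_low <- rpois(n, 0.5)
  syn <- data.frame(sample_id = rep(sample_ids, n_syn),
                    gene = sample(passenger_pool, sum(n_syn), replace = TRUE),
                    variant_classification = rep("synonymous", sum(n_syn)),
                    vaf = rbeta_trunc(sum(n_syn), vaf_mean, conc),
                    origin = rep("somatic", sum(n_syn)),
                    stringsAsFactors = FALSE)
  low <- data.frame(sample_id = rep(sample_ids, n_low),
                    gene = sample(passenger_pool, sum(n_low), replace = TRUE),
                    variant_classification = sample(.NONSYN, sum(n_low),
                                                    replace = TRUE),
                    vaf = rbeta_trunc(sum(n_low), vaf_mean, conc, hi = 0.05),
                    origin = rep("somatic", sum(n_low)),
                    stringsAsFactors = FALSE)
  n_germ <- rpois(n, 0.1)
  germ <- data.frame(sample_id = rep(sample_ids, n_germ),
                     gene = sample(c("BRCA1", "BRCA2", "PALB2", "BARD1"),
                                   sum(n_germ), replace = TRUE),
                     variant_classification = sample(c("missense", "nonsense"),
                                                     sum(n_germ),
                                                     replace = TRUE),
                     vaf = runif(sum(n_germ), 0.35, 0.65),
                     origin = rep("germline", sum(n_germ)),
                     stringsAsFactors = FALSE)
  v <- rbind(qual, syn, low, germ)

  snv_class <- c("missense", "nonsense", "splice", "synonymous")
  is_snv <- v$variant_classification %in% snv_class
  v$variant_type <- ifelse(is_snv, "SNV",
                           sample(c("INS", "DEL"), nrow(v), replace = TRUE))
  v$context96 <- NA_character_
  v$context96[is_snv] <- sample(contexts_96(), sum(is_snv), replace = TRUE,
                                prob = ctx_prob)
  v$protein_change <- random_protein_change(nrow(v),
                                            v$variant_classification)
  v$pathogenicity <- ifelse(
    v$variant_classification == "nonsense", "nonsense",
    ifelse(v$variant_classification %in% c("frameshift", "splice"),
           "damaging",
           ifelse(v$variant_classification == "synonymous", "tolerated",
                  sample(c("damaging", "potentially_damaging", "tolerated"),
                         nrow(v), replace = TRUE, prob = c(0.3, 0.3, 0.4)))))
  v[, c("sample_id", "gene", "protein_change", "variant_type",
        "variant_classification", "vaf", "origin", "pathogenicity",
        "context96")]
}

#' Simulate an expression matrix with planted nonnegative metagenes
#'
#' Builds `V = W %*% H + noise` (noise truncated at zero) where `H` carries a
#' block structure: each sample belongs to one of `k` planted clusters and
#' loads about 1 on its own metagene and `bleed` on the others. A fixed block
#' of `genes_per_block` genes loads on each metagene; remaining genes are flat
#' (near-constant across samples), including `n_housekeeping` high-expressed
#' housekeeping genes named `"HK.."`.
#'
#' @param n_samples number of samples.
#' @param n_genes total genes (default 776).
#' @param k number of planted metagenes.
#' @param fractions per-cluster sample fractions (largest-remainder rounded to
#'   exact counts).
#' @param bleed between-block leakage in [0, 1).
#' @param noise_sd truncated-Gaussian noise standard deviation.
#' @param genes_per_block informative genes per metagene (default 64).
#' @param n_housekeeping number of housekeeping genes (default 10).
#' @param seed integer RNG seed.
#' @return list with `expression` (genes x samples matrix), `truth`
#'   (per-sample planted cluster), `W`, `H`, `housekeeping` (gene names) and
#'   `gene_sets` (the planted blocks, as a named list usable with
#'   [gss()]/[pathway_score()]).
#' @export
simulate_expression <- function(n_samples, n_genes = 776, k = 4,
                                fractions = rep(1 / k, k), bleed = 0.05,
                                noise_sd = 0.2, genes_per_block = 64,
                                n_housekeeping = 10, seed = 1L) {
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  if (k * genes_per_block + n_housekeeping > n_genes)
    stop_config("n_genes", "too small for the requested block structure")
  set.seed(seed)
  hk <- sprintf("HK%02d", seq_len(n_housekeeping))
  other <- sprintf("G%04d", seq_len(n_genes - n_housekeeping))
  genes <- c(hk, other)
  counts <- largest_remainder(n_samples, fractions)
  truth <- rep(seq_len(k), counts)
  truth <- truth[sample.int(n_samples)]

  H <- matrix(bleed * runif(k * n_samples), k, n_samples)
  H[cbind(truth, seq_len(n_samples))] <- runif(n_samples, 0.8, 1.2)

  W <- matrix(0, n_genes, k, dimnames = list(genes, NULL))
  block_genes <- vector("list", k)
  for (b in seq_len(k)) {
    idx <- n_housekeeping + (b - 1) * genes_per_block + seq_len(genes_per_block)
    block_genes[[b]] <- genes[idx]
    W[idx, ] <- bleed * runif(genes_per_block * k)
    W[idx, b] <- runif(genes_per_block, 2, 4)
  }
  flat <- setdiff(seq_len(n_genes),
                  n_housekeeping + seq_len(k * genes_per_block))
  mu <- runif(length(flat), 0.5, 2)
  mu[seq_len(n_housekeeping)] <- runif(n_housekeeping, 8, 12)
  # flat genes load equally on every metagene: near-constant across samples
  W[flat, ] <- matrix(mu, length(flat), k)

  V <- W %*% H
  if (noise_sd > 0)
    V <- pmax(V + matrix(rnorm(length(V), 0, noise_sd), nrow(V)), 0)
  colnames(V) <- sprintf("S%03d", seq_len(n_samples))
  names(block_genes) <- paste0("METAGENE_", seq_len(k))
  list(expression = V, truth = truth, W = W, H = H, housekeeping = hk,
       gene_sets = block_genes)
}

#' Generate a synthetic HLBC-like study cohort
#'
#' Draws a full synthetic cohort under a [cohort_config()]: clinical table,
#' variant-call table, copy-number table, per-locus microsatellite calls,
#' expression matrix with planted metagenes, and a truth record of all
#' planted parameters. Group sizes match the configuration exactly; mutation
#' prevalences, VAF and TMB contrasts hold in expectation.
#'
#' @param config a [cohort_config()].
#' @return list with elements `samples`, `variants`, `cn`, `msi`,
#'   `expression`, `gene_sets`, `housekeeping`, `panel`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config object", call. = FALSE)
  set.seed(config$seed)
  panel <- config$panel
  groups <- c("HLBC-1", "HLBC-2N", "HLBC-2E")
  n <- config$n_per_group
  ids <- sprintf("HLBC%03d", seq_len(sum(n)))
  group_of <- rep(groups, n)

  # clinical covariates
  samples <- data.frame(
    sample_id = ids,
    er_status = ifelse(rbinom(sum(n), 1, 0.89) == 1, "pos", "neg"),
    grade = sample(.GRADES, sum(n), replace = TRUE,
                   prob = c(0.10, 0.355, 0.545)),
    ki67_pct = round(100 * rbeta(sum(n), 1.8, 3.7), 1),
    her2_class = group_of,
    pam50 = sample(.PAM50_LEVELS, sum(n), replace = TRUE,
                   prob = c(0.30, 0.51, 0.045, 0.065, 0.08)),
    cohort_tag = "synthetic-HLBC",
    stringsAsFactors = FALSE)
  samples$pgr_pct <- round(ifelse(samples$er_status == "pos",
                                  100 * rbeta(sum(n), 2, 2),
                                  100 * rbeta(sum(n), 1, 8)), 1)
  samples <- samples[, c("sample_id", "er_status", "pgr_pct", "grade",
                         "ki67_pct", "her2_class", "pam50", "cohort_tag")]

  # hypermutated / MSI-high profiles
  msi_high <- rbinom(sum(n), 1, config$msi_high_rate) == 1

  # substitution-context distributions: one shared trio of signature
  # components plus a private component for the first subgroup
  sig <- synthetic_signatures(8)
  ctx_prob <- list(
    as.numeric(sig %*% c(0.35, 0, 0.30, 0, 0.20, 0, 0.15, 0)),
    as.numeric(sig %*% c(0.50, 0, 0.30, 0, 0.20, 0, 0, 0)),
    as.numeric(sig %*% c(0.50, 0, 0.30, 0, 0.20, 0, 0, 0)))

  variants <- vector("list", 3)
  offset <- c(0, cumsum(n))
  for (g in seq_len(3)) {
    idx <- offset[g] + seq_len(n[g])
    prev <- lapply(config$mutation_prevalence, `[`, g)
    variants[[g]] <- simulate_group_variants(
      ids[idx], prev, config$vaf_mean[g], config$vaf_concentration,
      config$tmb_mean[g], panel, ctx_prob[[g]], msi_high[idx])
  }
  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL

  # copy-number fold changes (log10 scale) for the CN gene panel
  gain_rate <- c(CCND1 = 0.11, FGFR1 = 0.08, FGF3 = 0.08, FGF4 = 0.08,
                 FGF19 = 0.08, MET = 0.02, KRAS = 0.02, MYC = 0.03)
  loss_rate <- c(PTEN = 0.01, NRG1 = 0.05)
  cn_rows <- expand.grid(sample_id = ids, gene = panel$cn_genes,
                         stringsAsFactors = FALSE)
  fc <- pmax(rnorm(nrow(cn_rows), 1, 0.12), 0.2)
  erbb2 <- cn_rows$gene == "ERBB2"
  fc[erbb2] <- pmax(rnorm(sum(erbb2),
                          config$erbb2_cn_mean[match(group_of, groups)], 0.3),
                    0.2)
  for (gn in names(gain_rate)) {
    sel <- which(cn_rows$gene == gn & rbinom(nrow(cn_rows), 1,
                                             gain_rate[[gn]]) == 1)
    fc[sel] <- runif(length(sel), 2.5, 5)
  }
  for (gn in names(loss_rate)) {
    sel <- which(cn_rows$gene == gn & rbinom(nrow(cn_rows), 1,
                                             loss_rate[[gn]]) == 1)
    fc[sel] <- runif(length(sel), 0.05, 0.4)
  }
  cn <- data.frame(cn_rows, log10_fc = log10(fc),
                   call = ifelse(fc >= 2, "gain",
                                 ifelse(fc <= 0.5, "loss", "neutral")),
                   stringsAsFactors = FALSE)

  # per-locus microsatellite calls
  unstable_rate <- ifelse(msi_high, 0.40, 0.02)
  n_loci <- panel$msi_loci
  msi <- data.frame(
    sample_id = rep(ids, each = n_loci),
    locus = rep(sprintf("MSI_L%03d", seq_len(n_loci)), length(ids)),
    call = ifelse(rbinom(length(ids) * n_loci, 1,
                         rep(unstable_rate, each = n_loci)) == 1,
                  "unstable", "stable"),
    stringsAsFactors = FALSE)

  ex <- simulate_expression(sum(n), k = config$n_metagenes,
                            fractions = config$metagene_fractions,
                            bleed = config$bleed,
                            noise_sd = config$noise_sd,
                            seed = derive_seed(config$seed, 101))
  colnames(ex$expression) <- ids

  truth <- list(cluster = ex$truth, group = group_of, msi_high = msi_high,
                config = config[setdiff(names(config), "panel")])
  list(samples = samples, variants = variants, cn = cn, msi = msi,
       expression = ex$expression, gene_sets = ex$gene_sets,
       housekeeping = ex$housekeeping, panel = panel, truth = truth)
}

#' Generate a synthetic control-cohort pool
#'
#' Emulates a large public breast-cancer cohort with clinical strata and
#' per-gene binary mutation flags, as used for matched-cohort assembly.
#'
#' @param n pool size.
#' @param composition list with `er_pos` (ER-positive fraction),
#'   `g3_in_er_pos`, `g3_in_er_neg` (G3 fractions per ER stratum) and
#'   `her2_scores` (named probabilities over IHC score classes).
#' @param per_gene_rates named numeric vector of marginal mutation rates.
#' @param seed integer RNG seed.
#' @return data frame with `sample_id`, `er_status`, `grade`, `her2_score`
#'   and one 0/1 column per gene.
#' @export
generate_control_pool <- function(n,
                                  composition = list(
                                    er_pos = 0.75, g3_in_er_pos = 0.45,
                                    g3_in_er_neg = 0.75,
                                    her2_scores = c("score0" = 0.45,
                                                    "score1+" = 0.30,
                                                    "score2+" = 0.15,
                                                    "score3+" = 0.10)),
                                  per_gene_rates = c(PIK3CA = 0.33,
                                                     TP53 = 0.40,
                                                     GATA3 = 0.12,
                                                     CDH1 = 0.12,
                                                     KMT2C = 0.10,
                                                     MAP3K1 = 0.08,
                                                     ESR1 = 0.04,
                                                     AKT1 = 0.04,
                                                     ERBB2 = 0.03,
                                                     SPEN = 0.01),
                                  seed = 1L) {
  if (n <= 0) stop_config("n", "must be > 0")
  check_prob(c(composition$er_pos, composition$g3_in_er_pos,
               composition$g3_in_er_neg), "composition")
  check_prob(per_gene_rates, "per_gene_rates")
  set.seed(seed)
  er <- ifelse(rbinom(n, 1, composition$er_pos) == 1, "pos", "neg")
  g3_rate <- ifelse(er == "pos", composition$g3_in_er_pos,
                    composition$g3_in_er_neg)
  g3 <- rbinom(n, 1, g3_rate) == 1
  grade <- ifelse(g3, "G3", sample(c("G1", "G2"), n, replace = TRUE,
                                   prob = c(0.3, 0.7)))
  pool <- data.frame(sample_id = sprintf("CTRL%05d", seq_len(n)),
                     er_status = er, grade = grade,
                     her2_score = sample(names(composition$her2_scores), n,
                                         replace = TRUE,
                                         prob = composition$her2_scores),
                     stringsAsFactors = FALSE)
  for (gene in names(per_gene_rates))
    pool[[gene]] <- rbinom(n, 1, per_gene_rates[[gene]])
  pool
}
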