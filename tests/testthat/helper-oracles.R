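# Independent oracles used to cross-check package statistics. These are
# deliberately naive implementations (enumeration, literal step-down,
# projected gradient) kept separate from the code paths they verify.

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins; sums probabilities <= the observed
# table's probability (with the customary 1 + 1e-7 relative slack).
fisher_enum_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; c2 <- b + d; N <- a + b + c + d
  table_prob <- function(k) {
    exp(lchoose(c1, k) + lchoose(c2, r1 - k) - lchoose(N, r1))
  }
  ks <- max(0, r1 - c2):min(r1, c1)
  probs <- vapply(ks, table_prob, numeric(1))
  p_obs <- table_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Literal Benjamini-Hochberg step-down: sort ascending, scale by n/rank,
# enforce monotonicity from the largest p downward, cap at 1.
bh_stepdown <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, scaled[i])
    adj[i] <- running
  }
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Nonnegative least squares by projected gradient with a Lipschitz step.
nnls_pg <- function(A, b, iters = 50000) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  step <- 1 / norm(AtA, "2")
  x <- rep(0, ncol(A))
  for (i in seq_len(iters)) {
    x <- pmax(0, x - step * (AtA %*% x - Atb))
  }
  as.numeric(x)
}

# Minimal variant-table builder for unit fixtures.
make_variants <- function(sample_id, gene, vaf,
                          classification = "missense",
                          origin = "somatic", type = NULL,
                          context = NA_character_) {
  n <- max(length(sample_id), length(gene), length(vaf))
  classification <- rep_len(classification, n)
  if (is.null(type))
    type <- ifelse(classification %in% c("missense", "nonsense", "splice",
                                         "synonymous"), "SNV", "DEL")
  data.frame(sample_id = rep_len(sample_id, n),
             gene = rep_len(gene, n),
             protein_change = sprintf("p.A%dG", seq_len(n)),
             variant_type = rep_len(type, n),
             variant_classification = classification,
             vaf = rep_len(vaf, n),
             origin = rep_len(origin, n),
             pathogenicity = rep_len("tolerated", n),
             context96 = rep_len(context, n),
             stringsAsFactors = FALSE)
}

# Binary mutation-flag cohort with the requested number of mutated samples.
make_flag_cohort <- function(n, mutated, gene = "PIK3CA") {
  df <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                   er_status = "pos", grade = "G3",
                   stringsAsFactors = FALSE)
  df[[gene]] <- as.integer(seq_len(n) <= mutated)
  df
}
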