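#' @useDynLib hlbc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rbeta rpois runif rnorm qbeta pbeta p.adjust
#'   fisher.test chisq.test pt qt var prcomp hclust cutree cophenetic cor
#'   as.dist sd setNames model.matrix lm.fit complete.cases
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

# closed vocabularies shared across modules
.VC_LEVELS <- c("missense", "nonsense", "frameshift", "inframe_indel",
                "splice", "synonymous")
.VT_LEVELS <- c("SNV", "INS", "DEL")
.NONSYN <- c("missense", "nonsense", "frameshift", "inframe_indel", "splice")
.HER2_CLASSES <- c("score0", "HLBC-1", "HLBC-2N", "HLBC-2E", "score3+")
.PAM50_LEVELS <- c("LumA", "LumB", "HER2E", "Basal", "Normal")
.GRADES <- c("G1", "G2", "G3")
.PATHOGENICITY <- c("nonsense", "damaging", "potentially_damaging", "tolerated")
.CN_CALLS <- c("gain", "loss", "neutral")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config(field, "rates must lie in [0, 1]")
  invisible(x)
}

#' Largest-remainder apportionment of integer counts
#'
#' Splits `total` into integer counts proportional to `fractions` so that the
#' counts sum exactly to `total`. Each stratum first receives the floor of its
#' quota; leftover units go to the strata with the largest fractional
#' remainders (earlier strata win ties).
#'
#' @param total integer total to apportion.
#' @param fractions nonnegative weights; normalized internally.
#' @return integer vector of counts, same length as `fractions`.
#' @export
largest_remainder <- function(total, fractions) {
  if (total < 0) stop("total must be nonnegative", call. = FALSE)
  f <- fractions / sum(fractions)
  quota <- total * f
  base <- floor(quota)
  rem <- quota - base
  left <- total - sum(base)
  if (left > 0) {
    take <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# derive a child seed from a base seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}
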