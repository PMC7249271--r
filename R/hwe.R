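#' Exact conditional outcome probabilities for a biallelic locus
#'
#' Under Hardy-Weinberg equilibrium, conditional on the allele counts
#' `n_a + n_b = 2n` of `n` diploid individuals, the number of heterozygotes
#' `h` has the exact distribution
#' `P(h) = n! 2^h n_a! n_b! / (n_aa! h! n_bb! (2n)!)` over the support
#' `h = n_b mod 2, n_b mod 2 + 2, ..., min(n_a, n_b)`.
#'
#' @param n_a,n_b Allele counts of the two alleles (`n_a + n_b = 2n`).
#' @return Tibble `het` (heterozygote count) and `prob`, summing to 1.
#' @export
hwe_outcome_probs <- function(n_a, n_b) {
  stopifnot(n_a >= 0, n_b >= 0, (n_a + n_b) %% 2 == 0)
  n <- (n_a + n_b) / 2
  hs <- seq(min(n_b, n_a) %% 2, min(n_a, n_b), by = 2)
  lp <- vapply(hs, function(h) {
    naa <- (n_a - h) / 2
    nbb <- (n_b - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  tibble(het = as.integer(hs), prob = exp(lp))
}

#' Hardy-Weinberg equilibrium test
#'
#' For biallelic loci: the exact conditional test, enumerating heterozygote
#' counts given the observed allele counts ([hwe_outcome_probs()]); the
#' two-sided p-value sums the probabilities of all outcomes no more probable
#' than the observed one.  For loci with more than two alleles: a Monte-Carlo
#' permutation test that shuffles the `2n` allele copies into random diploid
#' genotypes and compares the conditional probability of each shuffled
#' genotype configuration with the observed one, with the add-one correction
#' `p = (1 + #{perm <= obs}) / (1 + n_reps)` so `p > 0` always.
#' Monomorphic loci return exactly 1.
#'
#' @inheritParams allele_frequencies
#' @param method `"auto"` (exact when biallelic, permutation otherwise),
#'   `"exact"` or `"permutation"`.
#' @param n_reps Monte-Carlo replicates (>= 99).
#' @param seed Optional seed; with a seed the Monte-Carlo p-value is
#'   reproducible and the caller's RNG state is untouched.
#' @return A p-value in `(0, 1]`, or `NA` when no individuals are scored.
#' @export
hwe_test <- function(genotypes, locus, population = NULL,
                     method = c("auto", "exact", "permutation"),
                     n_reps = 999L, seed = NULL) {
  method <- match.arg(method)
  calls <- locus_calls(genotypes, locus, population)
  calls <- calls[!is.na(calls$a1), ]
  n <- nrow(calls)
  if (n == 0L) return(NA_real_)
  copies <- c(calls$a1, calls$a2)
  alleles <- sort(unique(copies))
  if (length(alleles) == 1L) return(1)
  if (method == "auto") {
    method <- if (length(alleles) == 2L) "exact" else "permutation"
  }
  if (method == "exact") {
    if (length(alleles) != 2L) {
      abort("exact test implemented for biallelic loci; use method = 'permutation'")
    }
    n_a <- sum(copies == alleles[1])
    n_b <- sum(copies == alleles[2])
    h_obs <- sum(calls$a1 != calls$a2)
    probs <- hwe_outcome_probs(n_a, n_b)
    p_obs <- probs$prob[probs$het == h_obs]
    return(min(1, sum(probs$prob[probs$prob <= p_obs * (1 + 1e-10)])))
  }
  if (n_reps < 99L) abort("n_reps must be >= 99 for the permutation test")
  stat_obs <- log_config_prob(calls$a1, calls$a2)
  run <- function() {
    count <- 0L
    for (i in seq_len(n_reps)) {
      perm <- sample(copies)
      s <- log_config_prob(perm[seq_len(n)], perm[n + seq_len(n)])
      if (s <= stat_obs + 1e-10) count <- count + 1L
    }
    (1 + count) / (1 + n_reps)
  }
  with_preserved_seed(seed, run())
}

# Log conditional probability of a diploid genotype configuration given its
# allele counts (Levene).
log_config_prob <- function(a1, a2) {
  n <- length(a1)
  h <- sum(a1 != a2)
  geno <- paste(pmin(a1, a2), pmax(a1, a2))
  n_geno <- table(geno)
  n_allele <- table(c(a1, a2))
  lgamma(n + 1) - sum(lgamma(n_geno + 1)) + h * log(2) +
    sum(lgamma(n_allele + 1)) - lgamma(2 * n + 1)
}

# Evaluate `expr` under `set.seed(seed)` (when given) without disturbing the
# caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
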