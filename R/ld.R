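# Pairwise genetic distances at one locus: for individuals i < j,
# d = 2 - (multiset overlap of the two diploid genotypes), in {0, 1, 2}.
pairwise_d <- function(a1, a2) {
  same <- outer(a1, a1, "==") + outer(a2, a2, "==")
  cross <- outer(a1, a2, "==") + outer(a2, a1, "==")
  m <- pmax(same, cross)
  d <- 2 - m
  d[upper.tri(d)]
}

#' Pairwise index of association between two loci
#'
#' For each pair of individuals let `d_a`, `d_b` be the number of allele
#' differences (0, 1 or 2) between their diploid genotypes at the two loci.
#' The index of association is `Ia = V_O / V_E - 1` with
#' `V_O = var(d_a + d_b)` and `V_E = var(d_a) + var(d_b)`, and its
#' standardised form is the correlation
#' `rbar_d = cov(d_a, d_b) / sqrt(var(d_a) var(d_b))`.  Significance is
#' assessed by permuting one locus's genotypes across individuals:
#' `perm_p = (1 + #{perm rbar_d >= observed}) / (1 + n_perm)`.
#'
#' Individuals missing at either locus are excluded (pairwise-complete);
#' at least 3 complete individuals are required.  When either locus is
#' monomorphic in the group the statistics are undefined (`NA`).
#'
#' @inheritParams allele_frequencies
#' @param locus_a,locus_b Locus names.
#' @param n_perm Permutations for the null (default 999).
#' @param seed Optional seed for reproducible permutation p-values.
#' @return One-row tibble: `locus_a`, `locus_b`, `population` (`"All"` when
#'   pooled), `n`, `ia`, `rbar_d`, `perm_p`, `n_perm`.
#' @export
index_of_association <- function(genotypes, locus_a, locus_b,
                                 population = NULL, n_perm = 999L,
                                 seed = NULL) {
  ca <- locus_calls(genotypes, locus_a, population)
  cb <- locus_calls(genotypes, locus_b, population)
  ok <- !is.na(ca$a1) & !is.na(cb$a1)
  ca <- ca[ok, ]
  cb <- cb[ok, ]
  n <- nrow(ca)
  if (n < 3L) abort("index_of_association needs >= 3 pairwise-complete individuals")
  pop_label <- population %||% "All"
  da <- pairwise_d(ca$a1, ca$a2)
  db <- pairwise_d(cb$a1, cb$a2)
  if (var(da) == 0 || var(db) == 0) {
    return(tibble(locus_a = locus_a, locus_b = locus_b,
                  population = pop_label, n = n, ia = NA_real_,
                  rbar_d = NA_real_, perm_p = NA_real_,
                  n_perm = as.integer(n_perm)))
  }
  ia <- var(da + db) / (var(da) + var(db)) - 1
  rbar <- cov(da, db) / sqrt(var(da) * var(db))
  run <- function() {
    count <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      dbp <- pairwise_d(cb$a1[idx], cb$a2[idx])
      vb <- var(dbp)
      r <- if (vb == 0) -Inf else cov(da, dbp) / sqrt(var(da) * vb)
      if (r >= rbar - 1e-12) count <- count + 1L
    }
    (1 + count) / (1 + n_perm)
  }
  perm_p <- with_preserved_seed(seed, run())
  tibble(locus_a = locus_a, locus_b = locus_b, population = pop_label,
         n = n, ia = ia, rbar_d = rbar, perm_p = perm_p,
         n_perm = as.integer(n_perm))
}

#' Pairwise linkage-disequilibrium panel
#'
#' [index_of_association()] for every locus pair, within each population and
#' (optionally) pooled across populations.  Pairs with fewer than 3
#' pairwise-complete individuals in a group are skipped.
#'
#' @inheritParams index_of_association
#' @param within_populations,pooled Which groupings to report.
#' @return Tibble of class `ssr_ld`, one row per locus pair per group.
#' @export
ld_table <- function(genotypes, within_populations = TRUE, pooled = TRUE,
                     n_perm = 999L, seed = NULL) {
  loci <- genotype_loci(genotypes)
  if (length(loci) < 2L) abort("ld_table needs >= 2 loci")
  pairs <- utils::combn(loci, 2L)
  groups <- c(if (within_populations) unique(as_tibble(genotypes)$population),
              if (pooled) list(NULL))
  rows <- purrr::map(groups, function(pop) {
    purrr::map(seq_len(ncol(pairs)), function(j) {
      tryCatch(
        index_of_association(genotypes, pairs[1, j], pairs[2, j],
                             population = if (!is.null(pop)) pop,
                             n_perm = n_perm, seed = seed),
        error = function(e) NULL
      )
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  structure(out, class = c("ssr_ld", class(out)))
}
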