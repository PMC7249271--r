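# Extract the two allele columns of one locus for a set of individuals.
locus_calls <- function(genotypes, locus, population = NULL) {
  df <- as_tibble(genotypes)
  if (!is.null(population)) {
    if (!population %in% df$population) {
      abort(sprintf("population '%s' not present", population))
    }
    df <- df[df$population == population, ]
  }
  c1 <- paste0(locus, ".1")
  c2 <- paste0(locus, ".2")
  if (!all(c(c1, c2) %in% names(df))) {
    abort(sprintf("locus '%s' not present", locus))
  }
  tibble(individual = df$individual, population = df$population,
         a1 = df[[c1]], a2 = df[[c2]])
}

#' Allele frequencies at one locus
#'
#' Frequencies are computed over the `2n` allele copies of the `n`
#' individuals with non-missing calls (per-locus pairwise deletion), and
#' reported in ascending order of allele size.
#'
#' @param genotypes An `ssr_genotypes` tibble (see [read_genotype_table()]).
#' @param locus Locus name.
#' @param population Optional population; `NULL` pools all individuals.
#' @return A list with `freq` (named numeric vector, names = allele sizes,
#'   summing to 1 when `n >= 1`) and `n` (individuals with non-missing
#'   calls).
#' @export
allele_frequencies <- function(genotypes, locus, population = NULL) {
  calls <- locus_calls(genotypes, locus, population)
  calls <- calls[!is.na(calls$a1), ]
  n <- nrow(calls)
  if (n == 0L) return(list(freq = setNames(numeric(0), character(0)), n = 0L))
  copies <- c(calls$a1, calls$a2)
  tab <- table(copies)
  alleles <- as.integer(names(tab))
  ord <- order(alleles)
  list(freq = setNames(as.numeric(tab[ord]) / (2 * n),
                       as.character(alleles[ord])),
       n = n)
}

#' Observed heterozygosity at one locus
#'
#' Fraction of non-missing individuals whose two alleles differ.
#'
#' @inheritParams allele_frequencies
#' @return Ho in `[0, 1]`, or `NA` when no individual has a call.
#' @export
observed_het <- function(genotypes, locus, population = NULL) {
  calls <- locus_calls(genotypes, locus, population)
  calls <- calls[!is.na(calls$a1), ]
  if (nrow(calls) == 0L) return(NA_real_)
  mean(calls$a1 != calls$a2)
}

#' Unbiased expected heterozygosity
#'
#' Small-sample-corrected gene diversity
#' `Hs = (2n / (2n - 1)) * (1 - sum(p_i^2))`, where `p_i` are allele
#' frequencies over the `2n` allele copies of `n` individuals.
#'
#' @param freq Numeric vector of allele frequencies (summing to 1).
#' @param n Number of individuals the frequencies were estimated from.
#' @return Hs in `[0, 1)`; 0 iff a single allele; `NA` when `n = 0`.
#' @examples
#' unbiased_expected_het(c(0.5, 0.5), 23)  # 0.511 at 3 dp
#' @export
unbiased_expected_het <- function(freq, n) {
  if (n == 0L || length(freq) == 0L) return(NA_real_)
  stopifnot(abs(sum(freq) - 1) < 1e-8)
  (2 * n / (2 * n - 1)) * (1 - sum(freq^2))
}

#' Private alleles per population at one locus
#'
#' An allele is private to a population when it occurs there and in no other
#' population.
#'
#' @inheritParams allele_frequencies
#' @return Tibble `population`, `locus`, `Ap`.  With fewer than two
#'   populations `Ap` is `NA` (with a warning), since privacy is undefined.
#' @export
private_alleles <- function(genotypes, locus) {
  pops <- unique(as_tibble(genotypes)$population)
  if (length(pops) < 2L) {
    warn("private alleles undefined with a single population")
    return(tibble(population = pops, locus = locus, Ap = NA_integer_))
  }
  sets <- purrr::map(pops, function(p) {
    af <- allele_frequencies(genotypes, locus, p)
    as.integer(names(af$freq))
  })
  names(sets) <- pops
  ap <- vapply(pops, function(p) {
    others <- unique(unlist(sets[setdiff(pops, p)]))
    sum(!sets[[p]] %in% others)
  }, integer(1))
  tibble(population = pops, locus = locus, Ap = unname(ap))
}

#' Per-population diversity panel
#'
#' Computes, for every population x locus cell: `n` (individuals with
#' non-missing calls), `A` (alleles), `Ap` (private alleles), `Ho`, `Hs`
#' (see [unbiased_expected_het()]), an exact/permutation Hardy-Weinberg
#' p-value and a `monomorphic` flag.  Rows with population `"All"` give the
#' across-population panel: pooled allele counts, with `Ho`/`Hs`/`hwe_p`
#' either computed on the pooled individuals (`all_method = "pooled"`) or as
#' the mean of the per-population values (`all_method = "mean"`).
#' Monomorphic cells have `Ho = Hs = 0` and `hwe_p = 1` by convention.
#'
#' @inheritParams allele_frequencies
#' @param drop_monomorphic Drop loci monomorphic across all populations
#'   pooled.
#' @param hwe_reps Monte-Carlo replicates for multiallelic Hardy-Weinberg
#'   tests (see [hwe_test()]).
#' @param seed Optional seed making Monte-Carlo p-values reproducible.
#' @param all_method How the `"All"` rows are computed (see above).
#' @return A tibble of class `ssr_diversity` with columns `population`,
#'   `locus`, `n`, `A`, `Ap`, `Ho`, `Hs`, `hwe_p`, `monomorphic`.
#' @export
diversity_table <- function(genotypes, drop_monomorphic = TRUE,
                            hwe_reps = 999L, seed = NULL,
                            all_method = c("pooled", "mean")) {
  all_method <- match.arg(all_method)
  df <- as_tibble(genotypes)
  if (nrow(df) == 0L) abort("empty genotype matrix")
  loci <- genotype_loci(genotypes)
  pops <- unique(df$population)
  if (drop_monomorphic) {
    keep <- vapply(loci, function(loc) {
      length(allele_frequencies(genotypes, loc, NULL)$freq) > 1L
    }, logical(1))
    loci <- loci[keep]
    if (length(loci) == 0L) abort("all loci are monomorphic")
  }
  ap <- if (length(pops) >= 2L) {
    bind_rows(purrr::map(loci, ~ private_alleles(genotypes, .x)))
  } else {
    tibble(population = character(), locus = character(), Ap = integer())
  }
  cell <- function(pop, loc) {
    af <- allele_frequencies(genotypes, loc, pop)
    a <- length(af$freq)
    mono <- a <= 1L
    ho <- if (af$n == 0L) NA_real_ else if (mono) 0 else
      observed_het(genotypes, loc, pop)
    hs <- if (af$n == 0L) NA_real_ else if (mono) 0 else
      unbiased_expected_het(af$freq, af$n)
    p <- if (af$n == 0L) NA_real_ else if (mono) 1 else
      hwe_test(genotypes, loc, pop, n_reps = hwe_reps, seed = seed)
    tibble(population = pop %||% "All", locus = loc, n = af$n, A = a,
           Ho = ho, Hs = hs, hwe_p = p, monomorphic = mono)
  }
  per_pop <- bind_rows(purrr::map(loci, function(loc) {
    bind_rows(purrr::map(pops, cell, loc = loc))
  }))
  per_pop <- left_join(per_pop, ap, by = c("population", "locus"))
  all_rows <- bind_rows(purrr::map(loci, function(loc) cell(NULL, loc)))
  if (all_method == "mean") {
    means <- per_pop |>
      group_by(.data$locus) |>
      summarise(Ho = mean(.data$Ho, na.rm = TRUE),
                Hs = mean(.data$Hs, na.rm = TRUE), .groups = "drop")
    all_rows <- all_rows |>
      select(-"Ho", -"Hs") |>
      left_join(means, by = "locus")
  }
  all_rows$Ap <- NA_integer_
  out <- bind_rows(per_pop, all_rows)
  out <- out[c("population", "locus", "n", "A", "Ap", "Ho", "Hs", "hwe_p",
               "monomorphic")]
  out <- arrange(out, .data$locus,
                 factor(.data$population, levels = c(pops, "All")))
  structure(out, class = c("ssr_diversity", class(out)))
}

#' Per-population mean and SD rows of a diversity panel
#'
#' Mean and sample standard deviation (n - 1 denominator) over loci of `A`,
#' `Ho` and `Hs` for every population (including the pooled `"All"` rows).
#'
#' @param diversity An `ssr_diversity` tibble from [diversity_table()].
#' @return Tibble `population`, `statistic` (`"mean"`/`"sd"`), `A`, `Ho`,
#'   `Hs`.
#' @export
diversity_summary <- function(diversity) {
  as_tibble(diversity) |>
    group_by(.data$population) |>
    summarise(
      mean_A = mean(.data$A, na.rm = TRUE),
      sd_A = sd(.data$A, na.rm = TRUE),
      mean_Ho = mean(.data$Ho, na.rm = TRUE),
      sd_Ho = sd(.data$Ho, na.rm = TRUE),
      mean_Hs = mean(.data$Hs, na.rm = TRUE),
      sd_Hs = sd(.data$Hs, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"population",
                        names_to = c("statistic", "parameter"),
                        names_sep = "_") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
}

#' Flag loci with a universal heterozygote fingerprint
#'
#' Duplicated (paralogous) loci whose diverged copies co-amplify produce the
#' same heterozygous genotype in essentially every individual.  A locus is
#' flagged when observed heterozygosity is 1 across all populations and a
#' single identical heterozygous genotype is shared by at least
#' `share_min` of the non-missing individuals.  Flagged loci are annotated,
#' never removed.
#'
#' @inheritParams allele_frequencies
#' @param loci Loci to test (default: all).
#' @param share_min Minimum shared-genotype fraction (default 0.95).
#' @return Tibble `locus`, `flagged`, `note`.
#' @export
paralogy_flag <- function(genotypes, loci = NULL, share_min = 0.95) {
  loci <- loci %||% genotype_loci(genotypes)
  rows <- purrr::map(loci, function(loc) {
    calls <- locus_calls(genotypes, loc)
    calls <- calls[!is.na(calls$a1), ]
    if (nrow(calls) == 0L) {
      return(tibble(locus = loc, flagged = FALSE, note = "no calls"))
    }
    het <- calls$a1 != calls$a2
    if (!all(het)) {
      return(tibble(locus = loc, flagged = FALSE, note = "Ho < 1"))
    }
    geno <- paste(pmin(calls$a1, calls$a2), pmax(calls$a1, calls$a2),
                  sep = "/")
    share <- max(table(geno)) / length(geno)
    if (share >= share_min) {
      tibble(locus = loc, flagged = TRUE,
             note = sprintf("fixed heterozygote %s in %.0f%% of individuals",
                            names(which.max(table(geno))), 100 * share))
    } else {
      tibble(locus = loc, flagged = FALSE,
             note = "heterozygous but multiple genotypes")
    }
  })
  bind_rows(rows)
}
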