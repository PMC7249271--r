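all_het <- function(n, a = 331L, b = 337L, locus = "locA", population = "P1") {
  make_genotypes(data.frame(a = rep(a, n), b = rep(b, n)), locus, population)
}

test_that("allele frequencies count allele copies with pairwise deletion", {
  gt <- all_het(23)
  af <- allele_frequencies(gt, "locA", "P1")
  expect_equal(af$n, 23L)
  expect_equal(unname(af$freq), c(0.5, 0.5))
  expect_equal(names(af$freq), c("331", "337"))

  gt <- make_genotypes(data.frame(a = c(rep(127L, 23)),
                                  b = c(rep(136L, 22), 127L)))
  af <- allele_frequencies(gt, "loc1", "P1")
  expect_equal(unname(af$freq), c(24 / 46, 22 / 46))

  gt <- make_genotypes(data.frame(a = rep(NA_integer_, 5),
                                  b = rep(NA_integer_, 5)))
  af <- allele_frequencies(gt, "loc1", "P1")
  expect_equal(af$n, 0L)
  expect_length(af$freq, 0L)
})

test_that("observed heterozygosity reproduces the printed panel cells", {
  gt <- make_genotypes(data.frame(a = rep(127L, 23),
                                  b = c(rep(136L, 22), 127L)))
  expect_equal(round(observed_het(gt, "loc1", "P1"), 3), 0.957)
  expect_equal(observed_het(all_het(24), "locA", "P1"), 1)
  gt <- make_genotypes(data.frame(a = rep(100L, 6), b = rep(100L, 6)))
  expect_equal(observed_het(gt, "loc1", "P1"), 0)
})

test_that("unbiased expected heterozygosity reproduces the printed panel cells", {
  expect_equal(round(unbiased_expected_het(c(0.5, 0.5), 23), 3), 0.511)
  expect_equal(round(unbiased_expected_het(c(0.5, 0.5), 24), 3), 0.511)
  expect_equal(round(unbiased_expected_het(c(24 / 46, 22 / 46), 23), 3), 0.510)
  expect_equal(unbiased_expected_het(1, 10), 0)
  expect_true(is.na(unbiased_expected_het(numeric(0), 0)))
})

test_that("Hs and Ho stay in [0,1] and Hs is invariant under relabeling", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    alleles <- sample(100:140, sample(1:5, 1))
    gt <- make_genotypes(data.frame(a = sample(alleles, n, replace = TRUE),
                                    b = sample(alleles, n, replace = TRUE)))
    af <- allele_frequencies(gt, "loc1", "P1")
    hs <- unbiased_expected_het(af$freq, af$n)
    ho <- observed_het(gt, "loc1", "P1")
    # the unbiased estimator attains 1 exactly when all 2n copies differ
    expect_true(hs >= 0 && hs <= 1)
    expect_true(ho >= 0 && ho <= 1)
    expect_equal(hs == 0, length(af$freq) == 1L)
    # relabeling alleles leaves Hs unchanged
    gt2 <- make_genotypes(data.frame(a = gt$loc1.1 + 1000L,
                                     b = gt$loc1.2 + 1000L))
    af2 <- allele_frequencies(gt2, "loc1", "P1")
    expect_equal(unbiased_expected_het(af2$freq, af2$n), hs)
  }
})

test_that("private alleles are those absent from every other population", {
  df <- tibble::tibble(
    population = c("pop1", "pop1", "pop2", "pop2"),
    individual = c("a", "b", "c", "d"),
    loc1.1 = c(100L, 102L, 100L, 100L),
    loc1.2 = c(100L, 102L, 100L, 100L))
  gt <- ssrskim:::new_genotypes(df)
  ap <- private_alleles(gt, "loc1")
  expect_equal(ap$Ap[ap$population == "pop1"], 1L)
  expect_equal(ap$Ap[ap$population == "pop2"], 0L)

  df$loc1.1 <- c(100L, 102L, 100L, 102L)
  df$loc1.2 <- df$loc1.1
  ap <- private_alleles(ssrskim:::new_genotypes(df), "loc1")
  expect_equal(ap$Ap, c(0L, 0L))

  expect_warning(
    ap1 <- private_alleles(ssrskim:::new_genotypes(df[df$population == "pop1", ]),
                           "loc1"),
    "single population")
  expect_true(all(is.na(ap1$Ap)))
})

test_that("populations given a unique simulated allele are exactly those with Ap >= 1", {
  cfg <- sim_config(seed = 72, missing_rate = 0,
                    populations = tibble::tibble(
                      name = sprintf("pop%d", 1:6),
                      n = c(23L, 23L, 24L, 24L, 30L, 29L), f = 0.5))
  shared <- c(`200` = 0.5, `204` = 0.5)
  freqs <- list(locA = list(
    pop1 = c(`200` = 0.4, `204` = 0.4, `210` = 0.2),
    pop2 = c(`200` = 0.4, `204` = 0.4, `212` = 0.2),
    pop3 = c(`200` = 0.4, `204` = 0.4, `214` = 0.2),
    pop4 = c(`200` = 0.4, `204` = 0.4, `216` = 0.2),
    pop5 = shared, pop6 = shared))
  sim <- simulate_genotype_matrix(freqs, cfg)
  ap <- private_alleles(sim$genotypes, "locA")
  with_private <- sort(ap$population[ap$Ap >= 1L])
  expect_equal(with_private, c("pop1", "pop2", "pop3", "pop4"))
})

test_that("diversity_table reproduces forced cells and drops monomorphic loci", {
  df <- tibble::tibble(
    population = c(rep("11", 23), rep("6", 23)),
    individual = sprintf("i%02d", 1:46),
    ssr2b.1 = c(rep(331L, 23), rep(331L, 23)),
    ssr2b.2 = c(rep(337L, 23), c(rep(337L, 22), 331L)),
    mono.1 = 250L, mono.2 = 250L)
  gt <- ssrskim:::new_genotypes(df)
  div <- suppressWarnings(diversity_table(gt, drop_monomorphic = TRUE))
  expect_s3_class(div, "ssr_diversity")
  expect_false("mono" %in% div$locus)
  cell <- div[div$population == "11" & div$locus == "ssr2b", ]
  expect_equal(cell$Ho, 1)
  expect_equal(round(cell$Hs, 3), 0.511)
  expect_equal(cell$n, 23L)
  cell6 <- div[div$population == "6" & div$locus == "ssr2b", ]
  expect_equal(round(cell6$Ho, 3), 0.957)
  expect_equal(round(cell6$Hs, 3), 0.510)
  # pooled rows are present with pooled allele counts
  expect_true("All" %in% div$population)
  expect_equal(div$A[div$population == "All"], 2L)

  with_mono <- suppressWarnings(diversity_table(gt, drop_monomorphic = FALSE))
  mono_cells <- with_mono[with_mono$locus == "mono" &
                            with_mono$population != "All", ]
  expect_true(all(mono_cells$monomorphic))
  expect_true(all(mono_cells$Ho == 0 & mono_cells$Hs == 0 &
                    mono_cells$hwe_p == 1))
})

test_that("summary rows equal direct recomputation over the emitted records", {
  set.seed(73)
  df <- tibble::tibble(
    population = rep(c("A", "B"), each = 12),
    individual = sprintf("i%02d", 1:24))
  for (loc in c("l1", "l2", "l3")) {
    a <- sample(c(100L, 104L, 108L), 24, replace = TRUE)
    b <- sample(c(100L, 104L, 108L), 24, replace = TRUE)
    df[[paste0(loc, ".1")]] <- pmin(a, b)
    df[[paste0(loc, ".2")]] <- pmax(a, b)
  }
  gt <- ssrskim:::new_genotypes(df)
  div <- diversity_table(gt, hwe_reps = 199, seed = 9)
  s <- diversity_summary(div)
  recA <- div[div$population == "A", ]
  expect_equal(s$A[s$population == "A" & s$statistic == "mean"], mean(recA$A))
  expect_equal(s$A[s$population == "A" & s$statistic == "sd"], sd(recA$A))
  expect_equal(s$Hs[s$population == "A" & s$statistic == "mean"],
               mean(recA$Hs))
  expect_equal(s$Ho[s$population == "A" & s$statistic == "sd"], sd(recA$Ho))
})

test_that("a universal heterozygote fingerprint is flagged as putative paralogy", {
  gt <- make_genotypes(data.frame(a = rep(119L, 30), b = rep(127L, 30)))
  fl <- paralogy_flag(gt)
  expect_true(fl$flagged)

  mixed <- make_genotypes(data.frame(
    a = c(rep(100L, 12), rep(104L, 16), rep(100L, 12)),
    b = c(rep(104L, 12), rep(108L, 16), rep(108L, 12))))
  expect_false(paralogy_flag(mixed)$flagged)

  not_all_het <- make_genotypes(data.frame(a = c(rep(119L, 29), 127L),
                                           b = rep(127L, 30)))
  expect_false(paralogy_flag(not_all_het)$flagged)
})

test_that("a simulated duplicated locus (merged fixed paralogs) is flagged", {
  cfg <- sim_config(seed = 74, missing_rate = 0,
                    populations = tibble::tibble(name = c("P1", "P2"),
                                                 n = c(25L, 25L), f = 0.9))
  # two fixed paralog alleles co-amplify: every individual reads 150/158
  sim <- simulate_genotype_matrix(list(dup = c(`150` = 1)), cfg)
  g <- tibble::as_tibble(sim$genotypes)
  g$dup.2 <- 158L
  fl <- paralogy_flag(ssrskim:::new_genotypes(g))
  expect_true(fl$flagged)
})
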