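fake_pair <- function(pair_penalty = 1.0, left_penalty = 0.5,
                      right_penalty = 0.5, left_tm = 60, right_tm = 60,
                      dist_left = 25L, dist_right = 25L,
                      product_size = 150L) {
  tibble::tibble(pair_penalty = pair_penalty, left_penalty = left_penalty,
                 right_penalty = right_penalty, left_tm = left_tm,
                 right_tm = right_tm, dist_left = dist_left,
                 dist_right = dist_right, product_size = product_size)
}

test_that("primer penalty is zero at the optimum and increases with deviations", {
  p <- primer_params()
  expect_equal(primer_penalty(60, 20L, 0.5, p), 0)
  expect_equal(primer_penalty(60, 21L, 0.5, p), 1.0)
  expect_equal(primer_penalty(60, 20L, 0.55, p), 0)  # inside the GC band
  expect_equal(primer_penalty(60, 20L, 0.7, p), 1.0)
  tms <- 60 + c(0, 0.5, 1, 2, 5)
  pen <- primer_penalty(tms, 20L, 0.5, p)
  expect_true(all(diff(pen) > 0))
  expect_equal(primer_penalty(58, 20L, 0.5, p), primer_penalty(62, 20L, 0.5, p))
})

test_that("retention filter applies the published thresholds with correct strictness", {
  inside <- fake_pair(pair_penalty = 1.69, left_penalty = 0.79,
                      right_penalty = 0.79, left_tm = 60, right_tm = 61.9,
                      dist_left = 21L, dist_right = 21L, product_size = 150L)
  expect_equal(nrow(filter_pairs(inside)), 1L)
  # pair penalty 1.7 is rejected: the bound is strict
  expect_equal(nrow(filter_pairs(fake_pair(pair_penalty = 1.7))), 0L)
  # a primer 3' end exactly 20 bp from the repeat is rejected: strict
  expect_equal(nrow(filter_pairs(fake_pair(dist_left = 20L))), 0L)
  expect_equal(nrow(filter_pairs(fake_pair(right_penalty = 0.8))), 0L)
  expect_equal(nrow(filter_pairs(fake_pair(left_tm = 60, right_tm = 62))), 0L)
  # product bounds are inclusive
  expect_equal(nrow(filter_pairs(fake_pair(product_size = 89L))), 1L)
  expect_equal(nrow(filter_pairs(fake_pair(product_size = 301L))), 1L)
  expect_equal(nrow(filter_pairs(fake_pair(product_size = 88L))), 0L)
  expect_equal(nrow(filter_pairs(fake_pair(product_size = 302L))), 0L)
})

test_that("filter_pairs is idempotent, order-preserving, and equals its predicate", {
  set.seed(41)
  pairs <- dplyr::bind_rows(lapply(1:200, function(i) {
    fake_pair(pair_penalty = runif(1, 0, 3), left_penalty = runif(1, 0, 1.2),
              right_penalty = runif(1, 0, 1.2), left_tm = runif(1, 55, 65),
              right_tm = runif(1, 55, 65),
              dist_left = sample(10:40, 1), dist_right = sample(10:40, 1),
              product_size = sample(60:350, 1))
  }))
  kept <- filter_pairs(pairs)
  expect_identical(kept, filter_pairs(kept))
  expect_identical(kept, pairs[oracle_pair_keep(pairs), ])
})

test_that("designed pairs are structurally sound and sorted by penalty", {
  set.seed(42)
  contig <- paste0(random_dna(180), strrep("AGC", 6), random_dna(180))
  locus <- tibble::tibble(locus_id = "L1", contig_id = "c1", start = 180L,
                          end = 198L, motif = "AGC", n_repeats = 6L)
  pairs <- design_primer_pairs(locus, contig)
  expect_gt(nrow(pairs), 0L)
  expect_true(all(pairs$left_end <= locus$start))
  expect_true(all(pairs$right_start >= locus$end))
  expect_true(all(pairs$product_size == pairs$right_end - pairs$left_start))
  expect_true(all(nchar(pairs$left_seq) >= 18 & nchar(pairs$left_seq) <= 27))
  expect_true(all(diff(pairs$pair_penalty) >= 0))
  # right primer is the reverse complement of its contig slice
  i <- 1L
  slice <- substr(contig, pairs$right_start[i] + 1, pairs$right_end[i])
  expect_equal(pairs$right_seq[i], revcomp(slice))
  # best surviving pair's product contains the repeat
  best <- filter_pairs(pairs)[1, ]
  expect_true(best$left_start < locus$start && best$right_end > locus$end)
})

test_that("loci too close to the contig edge yield no pairs, with a warning", {
  contig <- paste0(strrep("AT", 5), random_dna(200))
  locus <- tibble::tibble(start = 0L, end = 10L)
  expect_warning(pairs <- design_primer_pairs(locus, contig), "flank")
  expect_equal(nrow(pairs), 0L)
})

test_that("pair enumeration equals a brute-force window-pairing oracle", {
  set.seed(43)
  contig <- paste0(random_dna(120), strrep("AT", 7), random_dna(120))
  locus <- tibble::tibble(start = 120L, end = 134L)
  params <- primer_params(flank = 100L, product_range = NULL)
  got <- design_primer_pairs(locus, contig, params)

  # oracle: loop left windows, vectorised over right windows per iteration
  lefts <- do.call(rbind, lapply(18:27, function(llen) {
    cbind(ls = seq(20L, 120L - llen), le = seq(20L, 120L - llen) + llen)
  }))
  rights <- do.call(rbind, lapply(18:27, function(rlen) {
    rs <- seq(134L, min(234L, nchar(contig)) - rlen)
    cbind(rs = rs, re = rs + rlen)
  }))
  exp_keys <- unlist(lapply(seq_len(nrow(lefts)), function(i) {
    paste(lefts[i, "ls"], lefts[i, "le"], rights[, "rs"], rights[, "re"])
  }))
  key <- function(d) sort(paste(d$left_start, d$left_end, d$right_start,
                                d$right_end))
  expect_equal(key(got), sort(exp_keys))
  # spot-check scored fields against direct recomputation
  i <- sample(nrow(got), 5)
  expect_equal(got$left_tm[i],
               vapply(got$left_seq[i], melting_temp, 0, USE.NAMES = FALSE))
  expect_equal(got$pair_penalty[i],
               got$left_penalty[i] + got$right_penalty[i] +
                 0.5 * abs(got$left_tm[i] - got$right_tm[i]))
})

test_that("design_markers keeps one best pair per locus and names shared amplicons a/b", {
  set.seed(44)
  flank1 <- random_dna(150)
  mid <- random_dna(40)
  flank2 <- random_dna(150)
  contig <- paste0(flank1, strrep("AG", 5), mid, strrep("AT", 8), flank2)
  recs <- tibble::tibble(id = "c1", sequence = contig)
  loci <- find_ssrs(recs)
  expect_equal(nrow(loci), 2L)
  markers <- design_markers(recs, loci)
  expect_equal(nrow(markers), 2L)
  expect_false(any(duplicated(markers$marker_id)))
  # if both loci share one amplicon the ids end in a/b
  shared <- markers$left_start[1] == markers$left_start[2] &&
    markers$right_end[1] == markers$right_end[2]
  if (shared) {
    expect_match(markers$marker_id[1], "a$")
    expect_match(markers$marker_id[2], "b$")
  }
  # every reported pair satisfies the retention filter
  expect_equal(nrow(filter_pairs(markers)), nrow(markers))
})
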