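# A reference contig with one planted (AGC)5 and helpers to mutate copies.
planted_marker <- function(seed = 61, n_repeats = 5L, motif = "AGC",
                           flank = 150L) {
  set.seed(seed)
  left <- random_dna(flank)
  right <- random_dna(flank)
  seq <- paste0(left, strrep(motif, n_repeats), right)
  k <- nchar(motif)
  list(
    contig = tibble::tibble(id = "ref1", sequence = seq),
    locus = tibble::tibble(marker_id = "m1", contig_id = "ref1",
                           start = flank, end = flank + k * n_repeats,
                           motif = canonical_motif(motif),
                           motif_length = k, n_repeats = n_repeats),
    left = left, right = right, motif_raw = motif)
}

test_that("count_repeats recovers planted expansions and the reference count", {
  m <- planted_marker()
  expanded <- paste0(m$left, strrep(m$motif_raw, 7L), m$right)
  cr <- count_repeats(expanded, m$locus, m$contig$sequence)
  expect_equal(cr$status, "OK")
  expect_equal(cr$n_repeats, 7L)

  cr <- count_repeats(m$contig$sequence, m$locus, m$contig$sequence)
  expect_equal(cr$n_repeats, 5L)

  contracted <- paste0(m$left, strrep(m$motif_raw, 4L), m$right)
  expect_equal(count_repeats(contracted, m$locus, m$contig$sequence)$n_repeats,
               4L)
})

test_that("count_repeats works on the minus strand", {
  m <- planted_marker(seed = 62)
  expanded <- revcomp(paste0(m$left, strrep(m$motif_raw, 8L), m$right))
  cr <- count_repeats(expanded, m$locus, m$contig$sequence, strand = "-")
  expect_equal(cr$status, "OK")
  expect_equal(cr$n_repeats, 8L)
})

test_that("three substitutions in a 20-bp flank defeat anchoring", {
  m <- planted_marker(seed = 63)
  x <- strsplit(paste0(m$left, strrep(m$motif_raw, 5L), m$right), "")[[1]]
  # damage 3 of the 20 bases immediately left of the repeat
  for (pos in c(135L, 140L, 145L)) {
    x[pos] <- setdiff(c("A", "C", "G", "T"), x[pos])[1]
  }
  cr <- count_repeats(paste(x, collapse = ""), m$locus, m$contig$sequence)
  expect_equal(cr$status, "FLANK_NOT_ANCHORED")
  # two substitutions are still tolerated
  y <- strsplit(paste0(m$left, strrep(m$motif_raw, 5L), m$right), "")[[1]]
  for (pos in c(135L, 145L)) y[pos] <- setdiff(c("A", "C", "G", "T"), y[pos])[1]
  expect_equal(count_repeats(paste(y, collapse = ""), m$locus,
                             m$contig$sequence)$status, "OK")
})

test_that("classification applies the retention rules", {
  calls <- tibble::tibble(
    individual_id = c("i1", "i2", "i3"),
    n_repeats_observed = c(8L, 8L, 10L),
    mismatches = c(0L, 1L, 2L), reason = "OK")
  expect_equal(classify_marker(8L, calls)$status, "POLYMORPHIC")

  mono <- dplyr::mutate(calls, n_repeats_observed = 4L)
  expect_equal(classify_marker(4L, mono)$status, "MONOMORPHIC")

  # a call with 5 mismatches is invalid ("< 5" is strict); alone => INSUFFICIENT
  one <- tibble::tibble(individual_id = "i1", n_repeats_observed = 7L,
                        mismatches = 5L, reason = "OK")
  cl <- classify_marker(5L, one)
  expect_equal(cl$status, "INSUFFICIENT")
  expect_equal(cl$n_valid, 0L)
  expect_equal(cl$calls$reason, "TOO_MANY_MISMATCHES")

  expect_equal(classify_marker(3L, calls)$status, "DROPPED")
  expect_error(classify_marker(5L, calls, screen_thresholds(mismatch_max = 0)),
               "positive")
})

test_that("classification equals the brute-force predicate on random call tables", {
  set.seed(64)
  for (i in 1:200) {
    ref_n <- sample(3:9, 1)
    n <- sample(1:7, 1)
    calls <- tibble::tibble(
      individual_id = sprintf("i%d", seq_len(n)),
      n_repeats_observed = sample(c(NA, 4:9), n, replace = TRUE),
      mismatches = sample(0:7, n, replace = TRUE),
      reason = sample(c("OK", "NO_HIT", "FLANK_NOT_ANCHORED"), n,
                      replace = TRUE, prob = c(0.7, 0.15, 0.15)))
    calls$n_repeats_observed[calls$reason != "OK"] <- NA
    calls$mismatches[calls$reason == "NO_HIT"] <- NA
    expect_equal(classify_marker(ref_n, calls)$status,
                 oracle_classify(ref_n, calls))
  }
})

test_that("raising the mismatch tolerance never decreases the valid-call count", {
  set.seed(65)
  calls <- tibble::tibble(
    individual_id = sprintf("i%d", 1:20),
    n_repeats_observed = sample(4:8, 20, replace = TRUE),
    mismatches = sample(0:8, 20, replace = TRUE), reason = "OK")
  nv <- vapply(1:9, function(mm) {
    classify_marker(6L, calls, screen_thresholds(mismatch_max = mm))$n_valid
  }, integer(1))
  expect_true(all(diff(nv) >= 0))
})

test_that("screening simulated individuals recovers exactly the planted polymorphisms", {
  cfg <- sim_config(seed = 66, n_contigs = 8L, contig_len_bp = 500L,
                    n_individuals = 4L,
                    repeat_shift_probs = c(`0` = 1), flank_mut_rate = 0)
  ref <- simulate_reference(cfg)
  sim <- simulate_individuals(ref, cfg)
  markers <- dplyr::rename(ref$truth, marker_id = "locus_id")

  # no shifts anywhere: every marker monomorphic
  scr0 <- suppressMessages(screen_markers(markers, ref$contigs,
                                          sim$individuals))
  expect_true(all(scr0$status == "MONOMORPHIC"))

  # plant expansions at three known markers in one individual
  shifted <- c(1L, 3L, 5L)
  ind <- sim$individuals[[1]]
  for (mi in shifted) {
    tr <- ref$truth[mi, ]
    ci <- which(ind$id == paste0("ind01_", tr$contig_id))
    s <- ind$sequence[ci]
    frame <- substr(s, tr$start + 1L, tr$start + tr$motif_length)
    ind$sequence[ci] <- paste0(substr(s, 1, tr$start),
                               strrep(frame, tr$n_repeats + 2L),
                               substr(s, tr$end + 1L, nchar(s)))
  }
  sim$individuals[[1]] <- ind
  scr <- suppressMessages(screen_markers(markers, ref$contigs,
                                         sim$individuals))
  expect_equal(sort(scr$marker_id[scr$status == "POLYMORPHIC"]),
               sort(markers$marker_id[shifted]))
  expect_true(all(scr$status[!scr$marker_id %in% markers$marker_id[shifted]] ==
                    "MONOMORPHIC"))

  # determinism
  scr2 <- suppressMessages(screen_markers(markers, ref$contigs,
                                          sim$individuals))
  expect_identical(as.data.frame(tidy(scr)), as.data.frame(tidy(scr2)))
})

test_that("individuals with zero contigs warn and screen as NO_HIT", {
  m <- planted_marker(seed = 67)
  inds <- list(ok = m$contig, empty = m$contig[0, ])
  expect_warning(
    scr <- suppressMessages(screen_markers(m$locus, m$contig, inds)),
    "zero contigs")
  calls <- tidy(scr)
  expect_equal(calls$reason[calls$individual_id == "empty"], "NO_HIT")
  expect_equal(scr$status, "MONOMORPHIC")
})
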