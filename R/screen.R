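#' Screening thresholds for in-silico polymorphism calls
#'
#' @param min_repeats Minimum reference repeat count for a marker to be
#'   screened at all (markers below are dropped).
#' @param mismatch_max A call is invalid when the alignment carries this many
#'   mismatches or more (the published rule keeps `< 5`).
#' @param min_individuals Minimum number of valid calls for a marker to be
#'   classifiable (below: `INSUFFICIENT`).
#' @param flank_len Length (bp) of the reference flank used to anchor the
#'   repeat region in the individual's contig.
#' @param flank_max_mismatch Substitutions tolerated per flank anchor.
#' @return Named list of thresholds.
#' @export
screen_thresholds <- function(min_repeats = 4L, mismatch_max = 5L,
                              min_individuals = 1L, flank_len = 20L,
                              flank_max_mismatch = 2L) {
  th <- list(min_repeats = as.integer(min_repeats),
             mismatch_max = as.integer(mismatch_max),
             min_individuals = as.integer(min_individuals),
             flank_len = as.integer(flank_len),
             flank_max_mismatch = as.integer(flank_max_mismatch))
  if (any(unlist(th) <= 0L)) abort("screening thresholds must be positive")
  th
}

#' Count motif repeats in an individual's copy of a marker region
#'
#' Locates the two reference flanks adjacent to the repeat region inside the
#' individual's contig (each `flank_len` bp, allowing up to
#' `flank_max_mismatch` substitutions), then counts the maximal perfect
#' tandem run of the locus motif (any rotation) between the anchors.  For
#' minus-strand hits the individual contig is reverse-complemented first.
#'
#' @param individual_seq The individual's contig sequence.
#' @param locus One-row locus (needs `start`, `end`, `motif`, `motif_length`).
#' @param ref_seq The marker's reference contig sequence.
#' @param strand `"+"` or `"-"`: strand of the individual's hit.
#' @param flank_len,flank_max_mismatch Anchoring tolerances
#'   (see [screen_thresholds()]).
#' @return A list with `status` (`"OK"` or `"FLANK_NOT_ANCHORED"`) and
#'   `n_repeats` (integer, `NA` when not anchored).
#' @export
count_repeats <- function(individual_seq, locus, ref_seq, strand = "+",
                          flank_len = 20L, flank_max_mismatch = 2L) {
  if (strand == "-") individual_seq <- revcomp(individual_seq)
  start <- locus$start[1]
  end <- locus$end[1]
  k <- (locus[["motif_length"]] %||% nchar(locus$motif))[1]
  left_flank <- substr(ref_seq, max(1L, start - flank_len + 1L), start)
  right_flank <- substr(ref_seq, end + 1L, min(nchar(ref_seq), end + flank_len))
  if (nchar(left_flank) < 8L || nchar(right_flank) < 8L) {
    return(list(status = "FLANK_NOT_ANCHORED", n_repeats = NA_integer_))
  }
  subj <- Biostrings::DNAString(individual_seq)
  left <- best_flank_match(left_flank, subj, flank_max_mismatch, after = 0L)
  if (is.null(left)) {
    return(list(status = "FLANK_NOT_ANCHORED", n_repeats = NA_integer_))
  }
  right <- best_flank_match(right_flank, subj, flank_max_mismatch,
                            after = left$end)
  if (is.null(right)) {
    return(list(status = "FLANK_NOT_ANCHORED", n_repeats = NA_integer_))
  }
  segment <- substr(individual_seq, left$end + 1L, right$start - 1L)
  n <- max_tandem_count(segment, locus$motif[1], k)
  list(status = "OK", n_repeats = n)
}

# Best approximate occurrence of a flank: fewest mismatches, then leftmost,
# restricted to matches starting after position `after` (1-based).
best_flank_match <- function(flank, subj, max_mm, after = 0L) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(flank), subj,
                                max.mismatch = max_mm, with.indels = FALSE)
  if (length(m) == 0L) return(NULL)
  starts <- Biostrings::start(m)
  keep <- starts > after
  if (!any(keep)) return(NULL)
  starts <- starts[keep]
  views <- as.character(m)[keep]
  fl <- strsplit(flank, "", fixed = TRUE)[[1]]
  mm <- vapply(views, function(v) {
    sum(strsplit(v, "", fixed = TRUE)[[1]] != fl)
  }, numeric(1), USE.NAMES = FALSE)
  best <- order(mm, starts)[1]
  list(start = starts[best], end = starts[best] + nchar(flank) - 1L,
       mismatches = mm[best])
}

# Maximal number of perfect tandem copies of `motif` (any rotation, either
# strand orientation via the canonical class) inside `segment`.
max_tandem_count <- function(segment, motif, k) {
  canon <- canonical_motif(motif)
  len <- nchar(segment)
  if (len < k) return(0L)
  x <- strsplit(segment, "", fixed = TRUE)[[1]]
  best <- 0L
  if (len >= 2L * k) {
    eq <- x[seq_len(len - k)] == x[(k + 1L):len]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts[j]
      n_rep <- (r$lengths[j] + k) %/% k
      anchor <- paste(x[a:(a + k - 1L)], collapse = "")
      if (!grepl("^[ACGT]+$", anchor) || smallest_period(anchor) < k) next
      if (identical(canonical_motif(anchor), canon)) best <- max(best, n_rep)
    }
  }
  if (best == 0L) {
    rots <- unique(c(rotations(motif), rotations(revcomp(motif))))
    if (any(vapply(rots, function(r) grepl(r, segment, fixed = TRUE),
                   logical(1)))) {
      best <- 1L
    }
  }
  as.integer(best)
}

#' Classify one marker from its per-individual repeat calls
#'
#' Applies the retention rules: calls with `mismatches >= mismatch_max` are
#' invalidated; a marker whose reference repeat count is below `min_repeats`
#' is `DROPPED`; otherwise the marker is `POLYMORPHIC` when at least one
#' valid call differs from the reference repeat count, `MONOMORPHIC` when all
#' valid calls equal it, and `INSUFFICIENT` when fewer than `min_individuals`
#' valid calls remain.
#'
#' @param ref_n_repeats Reference repeat count of the marker.
#' @param calls Tibble of calls with columns `individual_id`,
#'   `n_repeats_observed`, `mismatches`, `reason`.
#' @param thresholds See [screen_thresholds()].
#' @return A list with `status`, `n_valid` and the (revalidated) `calls`.
#' @export
classify_marker <- function(ref_n_repeats, calls,
                            thresholds = screen_thresholds()) {
  calls <- mutate(calls,
                  reason = ifelse(.data$reason == "OK" &
                                    .data$mismatches >= thresholds$mismatch_max,
                                  "TOO_MANY_MISMATCHES", .data$reason),
                  valid = .data$reason == "OK")
  n_valid <- sum(calls$valid)
  status <- if (ref_n_repeats < thresholds$min_repeats) {
    "DROPPED"
  } else if (n_valid < thresholds$min_individuals) {
    "INSUFFICIENT"
  } else if (any(calls$valid &
                 calls$n_repeats_observed != ref_n_repeats, na.rm = TRUE)) {
    "POLYMORPHIC"
  } else {
    "MONOMORPHIC"
  }
  list(status = status, n_valid = n_valid, calls = calls)
}

#' Screen markers for in-silico repeat-count polymorphism
#'
#' For every marker, aligns each individual's contigs to the marker's
#' reference contig (best hit only), re-counts the motif repeats between
#' anchored flanks, and classifies the marker
#' (see [classify_marker()]).  Markers whose reference repeat count is below
#' `thresholds$min_repeats` are dropped from the output.
#'
#' @param markers Marker tibble (needs `marker_id`, `contig_id`, `start`,
#'   `end`, `motif`, `motif_length`, `n_repeats`), e.g. from
#'   [design_markers()] joined to its loci, or directly from [find_ssrs()]
#'   with a `marker_id` column.
#' @param ref_records Reference contig tibble.
#' @param individuals Named list of per-individual contig tibbles.
#' @param align See [align_params()].
#' @param thresholds See [screen_thresholds()].
#' @return A tibble of class `ssr_screen`: one row per retained marker with
#'   `marker_id`, `status`, `n_valid`, `ref_n_repeats` and a `calls`
#'   list-column of per-individual calls.
#' @export
screen_markers <- function(markers, ref_records, individuals,
                           align = align_params(),
                           thresholds = screen_thresholds()) {
  if (length(individuals) < 1L) abort("screen_markers needs >= 1 individual")
  if (is.null(names(individuals)) || any(!nzchar(names(individuals)))) {
    abort("'individuals' must be a named list of contig tibbles")
  }
  if (!"motif_length" %in% names(markers)) {
    markers$motif_length <- nchar(markers$motif)
  }
  ref_seqs <- setNames(ref_records$sequence, ref_records$id)
  empty_inds <- names(individuals)[vapply(individuals, nrow, 0L) == 0L]
  if (length(empty_inds) > 0L) {
    warn(sprintf("individual(s) with zero contigs: %s",
                 paste(empty_inds, collapse = ", ")))
  }
  rows <- purrr::map(seq_len(nrow(markers)), function(i) {
    marker <- markers[i, ]
    ref_seq <- ref_seqs[[marker$contig_id]]
    marker_contig <- tibble(id = marker$contig_id, sequence = ref_seq)
    calls <- purrr::imap(individuals, function(contigs, ind_id) {
      if (nrow(contigs) == 0L) {
        return(tibble(individual_id = ind_id, marker_id = marker$marker_id,
                      n_repeats_observed = NA_integer_,
                      mismatches = NA_integer_, reason = "NO_HIT"))
      }
      hit <- best_hit(contigs, marker_contig, align)
      if (nrow(hit) == 0L) {
        return(tibble(individual_id = ind_id, marker_id = marker$marker_id,
                      n_repeats_observed = NA_integer_,
                      mismatches = NA_integer_, reason = "NO_HIT"))
      }
      qseq <- contigs$sequence[match(hit$query_id, contigs$id)]
      cr <- count_repeats(qseq, marker, ref_seq, strand = hit$strand,
                          flank_len = thresholds$flank_len,
                          flank_max_mismatch = thresholds$flank_max_mismatch)
      tibble(individual_id = ind_id, marker_id = marker$marker_id,
             n_repeats_observed = if (cr$status == "OK") cr$n_repeats
             else NA_integer_,
             mismatches = hit$mismatches,
             reason = if (cr$status == "OK") "OK" else cr$status)
    })
    calls <- bind_rows(calls)
    cl <- classify_marker(marker$n_repeats, calls, thresholds)
    tibble(marker_id = marker$marker_id, status = cl$status,
           n_valid = cl$n_valid, ref_n_repeats = marker$n_repeats,
           calls = list(cl$calls))
  })
  out <- bind_rows(rows)
  dropped <- sum(out$status == "DROPPED")
  if (dropped > 0L) {
    inform(sprintf("screen_markers: dropped %d marker(s) with reference repeat count < %d",
                   dropped, thresholds$min_repeats))
    out <- filter(out, .data$status != "DROPPED")
  }
  counts <- table(out$status)
  inform(paste0("screen_markers: ",
                paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                      collapse = ", ")))
  structure(out, class = c("ssr_screen", class(out)))
}
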