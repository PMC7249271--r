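#' Alignment scoring parameters for the built-in local aligner
#'
#' @param match,mismatch Per-base scores.
#' @param gap_open,gap_extend Gap penalties (positive costs; a gap of length
#'   L costs `gap_open + L * gap_extend`).
#' @param min_score Best-local-alignment score below which a comparison is
#'   reported as no hit.
#' @return Named list of parameters.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 2,
                         gap_extend = 1, min_score = 30) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, min_score = min_score)
}

align_submat <- function(params) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- params$match
  m["N", ] <- params$mismatch
  m[, "N"] <- params$mismatch
  m
}

#' Align an individual's contig to a marker contig
#'
#' Best-scoring Smith-Waterman local alignment of `query` against `subject`
#' on both strands.  The result uses the 12-column tabular hit convention:
#' 1-based inclusive coordinates, with `s_start > s_end` encoding a
#' minus-strand hit.  Returns a zero-row tibble when the best score is below
#' `params$min_score`.
#'
#' @param query,subject One-row tibbles (or lists) with `id` and `sequence`.
#' @param params See [align_params()].
#' @return A hit tibble (see [read_hits_table()]) with 0 or 1 rows, plus a
#'   `score` column.
#' @export
align_to_marker <- function(query, subject, params = align_params()) {
  submat <- align_submat(params)
  q <- Biostrings::DNAString(query$sequence[1])
  s_fwd <- Biostrings::DNAString(subject$sequence[1])
  s_rev <- Biostrings::reverseComplement(s_fwd)
  aln_f <- Biostrings::pairwiseAlignment(
    q, s_fwd, type = "local", substitutionMatrix = submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  aln_r <- Biostrings::pairwiseAlignment(
    q, s_rev, type = "local", substitutionMatrix = submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  minus <- Biostrings::score(aln_r) > Biostrings::score(aln_f)
  aln <- if (minus) aln_r else aln_f
  sc <- Biostrings::score(aln)
  if (sc < params$min_score) return(empty_hit_with_score())

  n_match <- Biostrings::nmatch(aln)
  n_mm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  ins_w <- sum(Biostrings::insertion(ind)[, "WidthSum"])
  del_w <- sum(Biostrings::deletion(ind)[, "WidthSum"])
  gapopens <- sum(Biostrings::insertion(ind)[, "Length"]) +
    sum(Biostrings::deletion(ind)[, "Length"])
  aln_len <- n_match + n_mm + ins_w + del_w
  qs <- Biostrings::start(Biostrings::pattern(aln))
  qe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  slen <- length(s_fwd)
  if (minus) {
    tmp <- ss
    ss <- slen - ss + 1L   # coordinates back on the plus strand of subject
    se <- slen - se + 1L
  }
  tibble(
    query_id = query$id[1], subject_id = subject$id[1],
    pct_identity = 100 * n_match / aln_len, aln_length = as.integer(aln_len),
    mismatches = as.integer(n_mm), gap_opens = as.integer(gapopens),
    q_start = as.integer(qs), q_end = as.integer(qe),
    s_start = as.integer(ss), s_end = as.integer(se),
    evalue = 0, bitscore = sc,
    strand = if (minus) "-" else "+", score = sc
  )
}

empty_hit_with_score <- function() {
  mutate(empty_hits(), score = numeric(0))
}

#' Best hit of an individual's assembly against one marker contig
#'
#' Aligns every contig of one individual against the marker contig and keeps
#' the single best hit (highest score, ties by bitscore then subject start).
#'
#' @param contigs Contig tibble for one individual.
#' @param marker_contig One-row tibble with `id`, `sequence` for the marker's
#'   reference contig.
#' @inheritParams align_to_marker
#' @return Hit tibble with 0 or 1 rows.
#' @export
best_hit <- function(contigs, marker_contig, params = align_params()) {
  hits <- purrr::map(seq_len(nrow(contigs)), function(i) {
    align_to_marker(contigs[i, ], marker_contig, params)
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) return(hits)
  hits <- arrange(hits, dplyr::desc(.data$score), dplyr::desc(.data$bitscore),
                  pmin(.data$s_start, .data$s_end))
  hits[1, ]
}
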