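#' Primer scoring parameters
#'
#' Defaults for primer enumeration and scoring.  The per-primer penalty is a
#' primer3-like weighted sum of deviations from an optimum:
#' `w_tm * |Tm - tm_opt| + w_len * |len - len_opt| + w_gc * max(0, |gc - 0.5| - 0.1)`,
#' zero when the primer sits at all optima, strictly increasing in each
#' deviation.  The pair penalty adds a melting-temperature mismatch term:
#' `left + right + w_pair_tm * |Tm_left - Tm_right|`.
#'
#' @param flank Flank length (bp) searched on each side of the repeat.
#' @param len_range Allowed primer lengths, inclusive (nt).
#' @param product_range Amplicon sizes enumerated, inclusive (bp); `NULL`
#'   for unbounded.
#' @param tm_opt,len_opt Penalty optima (deg C, nt).
#' @param w_tm,w_len,w_gc,w_pair_tm Penalty weights (per deg C, per nt,
#'   per GC fraction beyond the 0.4-0.6 band, per deg C of pair Tm
#'   difference).
#' @param primer_nM,na_mM Concentrations passed to [melting_temp()].
#' @return A named list of parameters.
#' @export
primer_params <- function(flank = 150L, len_range = c(18L, 27L),
                          product_range = c(89L, 301L),
                          tm_opt = 60, len_opt = 20L,
                          w_tm = 1, w_len = 1, w_gc = 10, w_pair_tm = 0.5,
                          primer_nM = 50, na_mM = 200) {
  list(flank = as.integer(flank), len_range = as.integer(len_range),
       product_range = if (!is.null(product_range)) as.integer(product_range),
       tm_opt = tm_opt, len_opt = as.integer(len_opt),
       w_tm = w_tm, w_len = w_len, w_gc = w_gc, w_pair_tm = w_pair_tm,
       primer_nM = primer_nM, na_mM = na_mM)
}

#' Per-primer penalty
#'
#' @param tm Melting temperature (deg C).
#' @param len Primer length (nt).
#' @param gc GC fraction (0-1).
#' @param params See [primer_params()].
#' @return Penalty, a dimensionless nonnegative real.
#' @export
primer_penalty <- function(tm, len, gc, params = primer_params()) {
  params$w_tm * abs(tm - params$tm_opt) +
    params$w_len * abs(len - params$len_opt) +
    params$w_gc * pmax(0, abs(gc - 0.5) - 0.1)
}

#' Enumerate candidate primer pairs around a repeat locus
#'
#' Enumerates every plus-strand left primer and every minus-strand right
#' primer of allowed length inside the flanks of the repeat, and pairs them
#' combinatorially.  Every returned pair is structurally valid: the left
#' primer ends at or before the repeat start, the right primer starts at or
#' after the repeat end, so the product spans the repeat.  Pairs are sorted
#' by `pair_penalty`, ties by `product_size` then `left_start`.
#'
#' Coordinates are 0-based half-open on the plus strand of the contig; the
#' right primer sequence is the reverse complement of its contig slice.
#' `dist_left`/`dist_right` are the distances (bp) from each primer's 3' end
#' to the repeat-region boundary; `product_size` is `right_end - left_start`
#' (the amplicon including both primers).
#'
#' @param locus One-row repeat locus (as from [find_ssrs()]): needs `start`,
#'   `end`, and optionally `locus_id`, `contig_id`.
#' @param contig_seq The contig sequence the locus lies on.
#' @param params See [primer_params()].
#' @return Tibble of primer pairs; empty (with a warning) when either flank
#'   is shorter than 40 bp.
#' @export
design_primer_pairs <- function(locus, contig_seq, params = primer_params()) {
  start <- locus$start[1]
  end <- locus$end[1]
  L <- nchar(contig_seq)
  if (min(start, L - end) < 40L) {
    warn(sprintf("flanks too short for locus at %d-%d (contig length %d)",
                 start, end, L))
    return(empty_pairs())
  }
  left <- enumerate_windows(contig_seq, max(0L, start - params$flank), start,
                            params)
  right <- enumerate_windows(contig_seq, end, min(L, end + params$flank),
                             params)
  if (nrow(left) == 0L || nrow(right) == 0L) return(empty_pairs())
  right$seq <- revcomp(right$seq)

  idx <- tidyr::expand_grid(li = seq_len(nrow(left)), ri = seq_len(nrow(right)))
  product_size <- right$end[idx$ri] - left$start[idx$li]
  if (!is.null(params$product_range)) {
    keep <- product_size >= params$product_range[1] &
      product_size <= params$product_range[2]
    idx <- idx[keep, ]
    product_size <- product_size[keep]
  }
  if (nrow(idx) == 0L) return(empty_pairs())
  pairs <- tibble(
    locus_id = (locus[["locus_id"]] %||% NA_character_)[1],
    contig_id = (locus[["contig_id"]] %||% NA_character_)[1],
    left_start = left$start[idx$li], left_end = left$end[idx$li],
    left_seq = left$seq[idx$li], left_tm = left$tm[idx$li],
    left_gc = left$gc[idx$li], left_penalty = left$penalty[idx$li],
    right_start = right$start[idx$ri], right_end = right$end[idx$ri],
    right_seq = right$seq[idx$ri], right_tm = right$tm[idx$ri],
    right_gc = right$gc[idx$ri], right_penalty = right$penalty[idx$ri],
    product_size = product_size,
    dist_left = start - left$end[idx$li],
    dist_right = right$start[idx$ri] - end
  )
  pairs <- mutate(pairs,
                  pair_penalty = .data$left_penalty + .data$right_penalty +
                    params$w_pair_tm * abs(.data$left_tm - .data$right_tm))
  arrange(pairs, .data$pair_penalty, .data$product_size, .data$left_start)
}

enumerate_windows <- function(contig_seq, lo, hi, params) {
  lens <- seq(params$len_range[1], params$len_range[2])
  rows <- purrr::map(lens, function(len) {
    if (hi - lo < len) return(NULL)
    starts <- seq(lo, hi - len)      # 0-based window starts
    tibble(start = starts, end = starts + len,
           seq = substring(contig_seq, starts + 1L, starts + len))
  })
  win <- bind_rows(rows)
  if (nrow(win) == 0L) return(win)
  win$tm <- vapply(win$seq, melting_temp, numeric(1),
                   primer_nM = params$primer_nM, na_mM = params$na_mM,
                   USE.NAMES = FALSE)
  win$gc <- gc_fraction(win$seq)
  win$penalty <- primer_penalty(win$tm, nchar(win$seq), win$gc, params)
  win
}

empty_pairs <- function() {
  tibble(locus_id = character(), contig_id = character(),
         left_start = integer(), left_end = integer(), left_seq = character(),
         left_tm = numeric(), left_gc = numeric(), left_penalty = numeric(),
         right_start = integer(), right_end = integer(), right_seq = character(),
         right_tm = numeric(), right_gc = numeric(), right_penalty = numeric(),
         product_size = integer(), dist_left = integer(), dist_right = integer(),
         pair_penalty = numeric())
}

#' Retention filter for scored primer pairs
#'
#' Applies the marker-retention filter: a pair is kept iff
#' `pair_penalty < 1.7`, both per-primer penalties `< 0.8`, melting
#' temperature difference `< 2` deg C, both primer 3' ends `> 20` bp from the
#' repeat region, and product size within 89-301 bp (bounds inclusive).
#' The penalty, Tm-difference and distance thresholds are strict; the filter
#' is idempotent and order-preserving.
#'
#' @param pairs Pair tibble from [design_primer_pairs()].
#' @param pair_penalty_max,primer_penalty_max,tm_diff_max,min_dist,product_range
#'   Filter thresholds; defaults are the published values.
#' @return The retained rows of `pairs`, in input order.
#' @export
filter_pairs <- function(pairs, pair_penalty_max = 1.7,
                         primer_penalty_max = 0.8, tm_diff_max = 2,
                         min_dist = 20L, product_range = c(89L, 301L)) {
  keep <- pairs$pair_penalty < pair_penalty_max &
    pairs$left_penalty < primer_penalty_max &
    pairs$right_penalty < primer_penalty_max &
    abs(pairs$left_tm - pairs$right_tm) < tm_diff_max &
    pairs$dist_left > min_dist &
    pairs$dist_right > min_dist &
    pairs$product_size >= product_range[1] &
    pairs$product_size <= product_range[2]
  pairs[keep, ]
}

#' Design one retained marker per repeat locus
#'
#' Driver over [design_primer_pairs()] and [filter_pairs()]: for every locus
#' it keeps the single surviving pair with the smallest `pair_penalty`
#' (ties: smaller product, then leftmost).  Loci whose chosen amplicons are
#' identical (two repeat regions inside one product) share the pair and are
#' named with `a`/`b` suffixes in coordinate order, mirroring how compound
#' loci are reported as independent markers.
#'
#' @param records Contig tibble (see [read_fasta()]).
#' @param loci Repeat-locus tibble from [find_ssrs()].
#' @param params See [primer_params()].
#' @param chromosome_map Optional tibble `contig_id`, `chromosome` used to
#'   annotate markers; unmatched contigs get `NA`.
#' @return A marker-candidate tibble: locus columns, chosen-pair columns and
#'   a unique `marker_id`.
#' @export
design_markers <- function(records, loci, params = primer_params(),
                           chromosome_map = NULL) {
  seqs <- setNames(records$sequence, records$id)
  chosen <- purrr::map(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    if (!locus$contig_id %in% names(seqs)) {
      abort(sprintf("locus %s references unknown contig %s",
                    locus$locus_id, locus$contig_id))
    }
    pairs <- suppressWarnings(
      design_primer_pairs(locus, seqs[[locus$contig_id]], params))
    best <- head(filter_pairs(pairs), 1L)
    if (nrow(best) == 0L) return(NULL)
    bind_cols(locus[c("locus_id", "contig_id", "start", "end", "motif",
                      "n_repeats")],
              best[setdiff(names(best), c("locus_id", "contig_id"))])
  })
  markers <- bind_rows(chosen)
  if (nrow(markers) == 0L) {
    inform("design_markers: no locus survived the primer filter")
    return(markers)
  }
  markers <- markers |>
    mutate(amplicon = sprintf("%s:%d-%d", .data$contig_id, .data$left_start,
                              .data$right_end)) |>
    group_by(.data$amplicon) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(marker_id = if (n() == 1L) .data$amplicon
           else paste0(.data$amplicon, letters[row_number()])) |>
    ungroup() |>
    select(-"amplicon") |>
    arrange(.data$contig_id, .data$start)
  if (!is.null(chromosome_map)) {
    markers <- left_join(markers, chromosome_map, by = "contig_id")
  } else {
    markers$chromosome <- NA_character_
  }
  markers[c("marker_id", setdiff(names(markers), "marker_id"))]
}
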