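#' Scan a contig for perfect microsatellite repeats
#'
#' Finds every maximal perfect run of a di-, tri- or tetranucleotide motif in
#' one sequence.  A run is maximal when it cannot be extended by one full
#' motif copy in either direction; each run is attributed to its shortest
#' period (an `(AT)6` tract is one dinucleotide locus, never an `(ATAT)3`
#' tetranucleotide locus), and runs are broken at any non-ACGT base.
#' Overlapping runs of different canonical motifs are all reported.
#'
#' The reported interval covers exactly `n_repeats` full motif copies,
#' anchored at the leftmost position of the run; motifs are named by their
#' canonical class representative (see [canonical_motif()]).
#'
#' @param id Contig id.
#' @param sequence DNA string (uppercase; `N` allowed).
#' @param min_repeats Named integer vector giving the minimum number of motif
#'   repeats per class, names `di`, `tri`, `tetra`.  All values must be >= 2.
#' @return A tibble with one row per repeat locus: `contig_id`, `start`,
#'   `end` (0-based half-open), `motif` (canonical), `n_repeats`,
#'   `motif_length`, `region_seq`, ordered by `start` then `motif_length`.
#' @examples
#' scan_sequence("c1", paste0("GG", strrep("AT", 5), "CC"))
#' @export
scan_sequence <- function(id, sequence,
                          min_repeats = c(di = 4L, tri = 4L, tetra = 4L)) {
  min_by_k <- min_repeats_by_k(min_repeats)
  x <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(x)
  valid <- x %in% c("A", "C", "G", "T")
  out <- list()
  for (k in as.integer(names(min_by_k))) {
    min_rep <- min_by_k[[as.character(k)]]
    if (L < k * min_rep) next
    eq <- x[seq_len(L - k)] == x[(k + 1L):L] &
      valid[seq_len(L - k)] & valid[(k + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run_len <- r$lengths[j]
      n_rep <- (run_len + k) %/% k
      if (n_rep < min_rep) next
      a <- starts[j]                       # 1-based position of run start
      anchor <- paste(x[a:(a + k - 1L)], collapse = "")
      if (smallest_period(anchor) < k) next  # belongs to a shorter period
      canon <- canonical_motif(anchor)
      start0 <- a - 1L
      end0 <- start0 + n_rep * k
      out[[length(out) + 1L]] <- tibble(
        contig_id = id, start = start0, end = end0, motif = canon,
        n_repeats = n_rep, motif_length = k,
        region_seq = paste(x[a:(a + n_rep * k - 1L)], collapse = "")
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  motif = character(), n_repeats = integer(),
                  motif_length = integer(), region_seq = character()))
  }
  arrange(bind_rows(out), .data$start, .data$motif_length)
}

min_repeats_by_k <- function(min_repeats) {
  names_k <- c(di = "2", tri = "3", tetra = "4")
  if (is.null(names(min_repeats)) || !all(names(min_repeats) %in% names(names_k))) {
    abort("min_repeats must be named with 'di', 'tri', 'tetra'")
  }
  if (any(min_repeats < 2L)) abort("min_repeats must be >= 2 for every class")
  setNames(as.integer(min_repeats), names_k[names(min_repeats)])
}

#' Find microsatellite loci in a set of contigs
#'
#' Batch driver over [scan_sequence()], assigning each locus a stable id of
#' the form `"<contig>:<start>-<end>:<motif>"`.  Output is deterministic for
#' a fixed input.
#'
#' @param records Contig tibble with columns `id`, `sequence` (see
#'   [read_fasta()]).
#' @inheritParams scan_sequence
#' @return Tibble of repeat loci as in [scan_sequence()], with a leading
#'   `locus_id` column.
#' @export
find_ssrs <- function(records, min_repeats = c(di = 4L, tri = 4L, tetra = 4L)) {
  loci <- purrr::map2(records$id, records$sequence, scan_sequence,
                      min_repeats = min_repeats)
  loci <- bind_rows(loci)
  if (nrow(loci) == 0L) {
    return(mutate(loci, locus_id = character())[
      c("locus_id", setdiff(names(loci), "locus_id"))])
  }
  loci <- mutate(loci, locus_id = sprintf("%s:%d-%d:%s", .data$contig_id,
                                          .data$start, .data$end, .data$motif))
  loci[c("locus_id", setdiff(names(loci), "locus_id"))]
}
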