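#' DNA string utilities and motif canonicalisation
#'
#' Microsatellite motifs form equivalence classes under rotation and reverse
#' complement: an `(AG)n` tract on one strand is a `(CT)n` tract on the other,
#' and the same tract can be read in any rotational frame.  Marker tables
#' therefore name each repeat class by a single canonical representative: the
#' lexicographically smallest string among all rotations of the motif and all
#' rotations of its reverse complement.
#'
#' Motifs that are themselves tandems of a shorter motif (e.g. `"ATAT"`,
#' `"CC"`) do not name a distinct repeat class — their runs are attributed to
#' the shorter period — and are rejected.
#'
#' @param motif A DNA string over `A`, `C`, `G`, `T` of length 2–4 (a single
#'   character string).
#' @return `canonical_motif()` returns the canonical string, or `NA_character_`
#'   when the motif is a tandem repetition of a shorter motif.
#' @examples
#' canonical_motif("GCA")  # "AGC"
#' canonical_motif("GA")   # "AG"
#' canonical_motif("ATAT") # NA: period-2 inside length 4
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, !is.na(motif))
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) {
    abort(sprintf("motif '%s' contains non-ACGT characters", motif))
  }
  k <- nchar(motif)
  if (k < 2L || k > 6L) {
    abort(sprintf("motif length must be 2-6, got %d ('%s')", k, motif))
  }
  if (smallest_period(motif) < k) {
    return(NA_character_)
  }
  min(c(rotations(motif), rotations(revcomp(motif))))
}

rotations <- function(s) {
  k <- nchar(s)
  vapply(seq_len(k), function(i) {
    paste0(substr(s, i, k), substr(s, 1, i - 1L))
  }, character(1))
}

smallest_period <- function(s) {
  k <- nchar(s)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L &&
        s == strrep(substr(s, 1L, p), k %/% p)) {
      return(p)
    }
  }
  k
}

#' @rdname canonical_motif
#' @param seq DNA string (may contain `N`).
#' @return `revcomp()` returns the reverse complement string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

gc_fraction <- function(seq) {
  n_gc <- nchar(gsub("[^GCgc]", "", seq))
  n_gc / nchar(seq)
}
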