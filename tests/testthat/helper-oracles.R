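# Independent brute-force oracles used to check the fast implementations.

# Regex-enumeration repeat scanner: tries every non-degenerate motif of each
# class against the sequence, trims matches to whole copies, and keeps, per
# canonical class, only maximal (longest, leftmost) non-contained matches.
oracle_scan <- function(id, sequence, min_repeats = c(di = 4L, tri = 4L, tetra = 4L)) {
  min_by_k <- c(`2` = unname(min_repeats["di"]), `3` = unname(min_repeats["tri"]),
                `4` = unname(min_repeats["tetra"]))
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (k in 2:4) {
    min_rep <- min_by_k[[as.character(k)]]
    motifs <- apply(expand.grid(rep(list(bases), k)), 1, paste, collapse = "")
    for (m in motifs) {
      canon <- canonical_motif(m)
      if (is.na(canon)) next
      pat <- sprintf("(?:%s){%d,}", m, min_rep)
      hits <- gregexpr(pat, sequence, perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      lens <- attr(hits, "match.length")
      for (i in seq_along(hits)) {
        n <- lens[i] %/% k
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = id, start = hits[i] - 1L, end = hits[i] - 1L + n * k,
          motif = canon, n_repeats = n, len = n * k,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      n_repeats = integer()))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$motif, -df$len, df$start), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    same <- which(keep & df$motif == df$motif[i] & seq_len(nrow(df)) > i)
    overlaps <- same[df$start[same] < df$end[i] & df$end[same] > df$start[i]]
    keep[overlaps] <- FALSE
  }
  df <- df[keep, c("contig_id", "start", "end", "motif", "n_repeats")]
  df[order(df$start, df$motif), ]
}

# One-line predicate form of the primer-pair retention filter.
oracle_pair_keep <- function(p) {
  p$pair_penalty < 1.7 & p$left_penalty < 0.8 & p$right_penalty < 0.8 &
    abs(p$left_tm - p$right_tm) < 2 & p$dist_left > 20 & p$dist_right > 20 &
    p$product_size >= 89 & p$product_size <= 301
}

# Brute-force predicate form of marker classification.
oracle_classify <- function(ref_n, calls, min_repeats = 4L, mismatch_max = 5L,
                            min_individuals = 1L) {
  valid <- calls$reason == "OK" & calls$mismatches < mismatch_max
  if (ref_n < min_repeats) return("DROPPED")
  if (sum(valid) < min_individuals) return("INSUFFICIENT")
  if (any(valid & calls$n_repeats_observed != ref_n, na.rm = TRUE)) {
    return("POLYMORPHIC")
  }
  "MONOMORPHIC"
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Genotype tibble builder: one population, one locus, explicit calls.
make_genotypes <- function(calls, locus = "loc1", population = "P1") {
  n <- nrow(calls)
  df <- tibble::tibble(
    population = rep(population, length.out = n),
    individual = sprintf("ind%03d", seq_len(n)))
  df[[paste0(locus, ".1")]] <- as.integer(calls[[1]])
  df[[paste0(locus, ".2")]] <- as.integer(calls[[2]])
  ssrskim:::new_genotypes(df)
}

# Multi-locus builder from a named list of two-column allele data frames.
make_genotypes_multi <- function(loci_calls, population = "P1") {
  n <- nrow(loci_calls[[1]])
  df <- tibble::tibble(
    population = rep(population, length.out = n),
    individual = sprintf("ind%03d", seq_len(n)))
  for (loc in names(loci_calls)) {
    df[[paste0(loc, ".1")]] <- as.integer(loci_calls[[loc]][[1]])
    df[[paste0(loc, ".2")]] <- as.integer(loci_calls[[loc]][[2]])
  }
  ssrskim:::new_genotypes(df)
}
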