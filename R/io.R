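#' Read contigs from a FASTA file
#'
#' Reads a (possibly gzip-compressed, multi-line) FASTA file into a tibble of
#' sequence records.  The id of each record is the header token before the
#' first whitespace; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `sequence` (uppercase
#'   DNA over `A`,`C`,`G`,`T`,`N`), in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 a contig", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) abort(sprintf("FASTA file is empty: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) abort("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) abort("FASTA record with empty sequence")
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequence records to a FASTA file
#'
#' @param records Tibble with columns `id`, `sequence` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "evalue", "bitscore")

#' Read a 12-column tabular alignment-hit file
#'
#' Parses the standard 12-column tab-separated hit table (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) produced
#' by BLAST-style aligners with tabular output.  A subject start greater than
#' the subject end encodes a minus-strand hit; the `strand` column makes this
#' explicit.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return A tibble with the twelve standard columns plus `strand`
#'   (`"+"`/`"-"`).
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("hits file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d of %s has %d columns (expected 12)",
                  bad[1], path, nf[bad[1]]))
  }
  m <- do.call(rbind, parts)
  hits <- tibble(
    query_id   = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (anyNA(hits[3:12])) abort(sprintf("non-numeric field in hits table %s", path))
  mutate(hits, strand = ifelse(.data$s_start > .data$s_end, "-", "+"))
}

empty_hits <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric(), strand = character()
  )
}

#' Format alignment hits as 12-column tabular lines
#'
#' Inverse of [read_hits_table()]: renders a hit tibble back to the tab
#' separated 12-column dialect (the `strand` column is implicit in the
#' subject coordinates and is dropped).
#'
#' @param hits Hit tibble as returned by [read_hits_table()].
#' @return Character vector of tab-separated lines.
#' @export
format_hits <- function(hits) {
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(h$query_id, h$subject_id,
          formatC(h$pct_identity, format = "f", digits = 3),
          h$aln_length, h$mismatches, h$gap_opens,
          h$q_start, h$q_end, h$s_start, h$s_end,
          format(h$evalue), formatC(h$bitscore, format = "f", digits = 1),
          sep = "\t")
  }, character(1))
}

#' Read a diploid genotype table
#'
#' Reads a CSV genotype table in a two-columns-per-locus layout (GenAlEx
#' style), with alleles coded as integer fragment sizes in base pairs:
#'
#' ```
#' population,individual,ssr1.1,ssr1.2,ssr2.1,ssr2.2
#' P1,ind01,215,233,127,127
#' ```
#'
#' Column pairs `<locus>.1`/`<locus>.2` hold the two alleles of each diploid
#' call.  A call is either fully present or fully missing: both alleles equal
#' to `missing_code` mark a missing call (stored as `NA`), and a half-missing
#' call is an error.
#'
#' @param path Path to the CSV file.
#' @param missing_code Allele code marking a missing call (default `"0"`).
#' @return A tibble of class `ssr_genotypes` with columns `population`,
#'   `individual` and two integer allele columns per locus.
#' @export
read_genotype_table <- function(path, missing_code = "0") {
  if (!file.exists(path)) abort(sprintf("genotype file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("population", "individual") %in% names(df))) {
    abort("genotype table must have 'population' and 'individual' columns")
  }
  allele_cols <- setdiff(names(df), c("population", "individual"))
  if (length(allele_cols) == 0L || length(allele_cols) %% 2L != 0L) {
    abort("genotype table needs an even, nonzero number of allele columns")
  }
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  expected <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!setequal(allele_cols, expected)) {
    abort("allele columns must come in '<locus>.1'/'<locus>.2' pairs")
  }
  out <- df[c("population", "individual")]
  for (loc in loci) {
    a1 <- df[[paste0(loc, ".1")]]
    a2 <- df[[paste0(loc, ".2")]]
    m1 <- a1 == missing_code
    m2 <- a2 == missing_code
    if (any(xor(m1, m2))) {
      bad <- which(xor(m1, m2))[1]
      abort(sprintf("half-missing call at individual '%s', locus '%s'",
                    df$individual[bad], loc))
    }
    v1 <- suppressWarnings(as.integer(a1))
    v2 <- suppressWarnings(as.integer(a2))
    if (any(is.na(v1) & !m1) || any(is.na(v2) & !m2) ||
        any(a1[!m1] != as.character(v1[!m1])) || any(a2[!m2] != as.character(v2[!m2]))) {
      abort(sprintf("non-integer allele code at locus '%s'", loc))
    }
    if (any(v1[!m1] <= 0L) || any(v2[!m2] <= 0L)) {
      abort(sprintf("allele sizes must be positive at locus '%s'", loc))
    }
    v1[m1] <- NA_integer_
    v2[m2] <- NA_integer_
    out[[paste0(loc, ".1")]] <- v1
    out[[paste0(loc, ".2")]] <- v2
  }
  new_genotypes(out)
}

new_genotypes <- function(df) {
  structure(as_tibble(df), class = c("ssr_genotypes", class(as_tibble(df))))
}

#' Build a genotype matrix from a data frame
#'
#' Validates and classes an in-memory data frame in the same layout as
#' [read_genotype_table()]: `population`, `individual`, and paired integer
#' allele columns `<locus>.1`/`<locus>.2` (missing calls as `NA` in both
#' slots).
#'
#' @param df A data frame in the genotype layout.
#' @return An `ssr_genotypes` tibble.
#' @export
as_genotypes <- function(df) {
  df <- as_tibble(df)
  if (!all(c("population", "individual") %in% names(df))) {
    abort("genotype data needs 'population' and 'individual' columns")
  }
  allele_cols <- setdiff(names(df), c("population", "individual"))
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  expected <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (length(allele_cols) == 0L || !setequal(allele_cols, expected)) {
    abort("allele columns must come in '<locus>.1'/'<locus>.2' pairs")
  }
  for (loc in loci) {
    a1 <- df[[paste0(loc, ".1")]]
    a2 <- df[[paste0(loc, ".2")]]
    if (any(xor(is.na(a1), is.na(a2)))) {
      abort(sprintf("half-missing call at locus '%s'", loc))
    }
    if (any(a1[!is.na(a1)] <= 0) || any(a2[!is.na(a2)] <= 0)) {
      abort(sprintf("allele sizes must be positive at locus '%s'", loc))
    }
    df[[paste0(loc, ".1")]] <- as.integer(a1)
    df[[paste0(loc, ".2")]] <- as.integer(a2)
  }
  new_genotypes(df)
}

#' @rdname read_genotype_table
#' @param genotypes An `ssr_genotypes` tibble.
#' @return `genotype_loci()` returns the locus names; `write_genotype_table()`
#'   writes the CSV (missing calls coded as `missing_code`) and returns `path`
#'   invisibly.
#' @export
genotype_loci <- function(genotypes) {
  unique(sub("\\.[12]$", "",
             setdiff(names(genotypes), c("population", "individual"))))
}

#' @rdname read_genotype_table
#' @export
write_genotype_table <- function(genotypes, path, missing_code = "0") {
  df <- as_tibble(genotypes)
  for (col in setdiff(names(df), c("population", "individual"))) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- missing_code
    df[[col]] <- v
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write and read marker and diversity report tables
#'
#' Reports are tab-separated with a fixed, deterministic column order and all
#' real-valued statistics printed at 3 decimal places, so a written table
#' read back compares equal at that precision.
#'
#' @param x A marker-candidate tibble (for `write_marker_table()`) or a
#'   diversity-record tibble (for `write_diversity_table()`).
#' @param path Output path (TSV).
#' @return The path, invisibly; readers return the corresponding tibble.
#' @export
write_marker_table <- function(x, path) {
  cols <- c("marker_id", "contig_id", "motif", "n_repeats", "start", "end",
            "left_seq", "right_seq", "left_tm", "right_tm", "left_penalty",
            "right_penalty", "pair_penalty", "product_size",
            "dist_left", "dist_right", "chromosome")
  df <- as_tibble(x)
  for (col in setdiff(cols, names(df))) df[[col]] <- NA
  df <- df[cols]
  write_report(df, path,
               num3 = c("left_tm", "right_tm", "left_penalty",
                        "right_penalty", "pair_penalty"))
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = "c", contig_id = "c", motif = "c", n_repeats = "i",
    start = "i", end = "i", left_seq = "c", right_seq = "c",
    left_tm = "d", right_tm = "d", left_penalty = "d", right_penalty = "d",
    pair_penalty = "d", product_size = "i", dist_left = "i",
    dist_right = "i", chromosome = "c"), progress = FALSE)
}

#' @rdname write_marker_table
#' @export
write_diversity_table <- function(x, path) {
  cols <- c("population", "locus", "n", "A", "Ap", "Ho", "Hs", "hwe_p",
            "monomorphic")
  df <- as_tibble(x)
  for (col in setdiff(cols, names(df))) df[[col]] <- NA
  df <- df[cols]
  write_report(df, path, num3 = c("Ho", "Hs", "hwe_p"))
}

#' @rdname write_marker_table
#' @export
read_diversity_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    population = "c", locus = "c", n = "i", A = "i", Ap = "i",
    Ho = "d", Hs = "d", hwe_p = "d", monomorphic = "l"), progress = FALSE)
}

write_report <- function(df, path, num3 = character()) {
  out <- df
  for (col in intersect(num3, names(out))) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), NA_character_,
                         formatC(round(as.numeric(v), 3), format = "f", digits = 3))
  }
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE, na = "NA"),
    error = function(e) abort(sprintf("cannot write report to '%s': %s",
                                      path, conditionMessage(e)))
  )
  invisible(path)
}
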