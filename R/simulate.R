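#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: a skim-level
#' reference of modest contigs with one planted perfect repeat per contig,
#' seven resequenced individuals whose repeat counts shift by small deltas,
#' and six populations of highly selfing diploids genotyped at fragment-size
#' alleles.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @param n_contigs,contig_len_bp Reference shape.
#' @param planted_ssrs Optional tibble `contig` (1-based index), `motif`,
#'   `n_repeats`, `position` (0-based start).  `NULL` plants one repeat per
#'   contig at a seeded position with motif drawn from the canonical di-/
#'   tri-/tetranucleotide classes and 4-10 repeats.
#' @param n_individuals Number of skim individuals.
#' @param repeat_shift_probs Named numeric distribution over repeat-count
#'   deltas applied per individual per locus.
#' @param flank_mut_rate Per-bp substitution probability outside repeat
#'   regions in individual assemblies.
#' @param populations Tibble `name`, `n`, `f` (inbreeding coefficient); the
#'   default mirrors six populations of 23-30 individuals under strong
#'   selfing.
#' @param missing_rate Per-call missingness rate in simulated genotype
#'   matrices.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 50L, contig_len_bp = 600L,
                       planted_ssrs = NULL, n_individuals = 7L,
                       repeat_shift_probs = c(`-1` = 0.2, `0` = 0.5,
                                              `1` = 0.2, `2` = 0.1),
                       flank_mut_rate = 0.005,
                       populations = tibble(
                         name = c("P1", "P2", "P3", "P4", "P5", "P6"),
                         n = c(23L, 23L, 24L, 24L, 30L, 29L),
                         f = 0.9),
                       missing_rate = 0.0123) {
  if (abs(sum(repeat_shift_probs) - 1) > 1e-8) {
    abort("repeat_shift_probs must sum to 1")
  }
  if (any(populations$f < 0 | populations$f > 1)) {
    abort("inbreeding coefficients must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_len_bp = as.integer(contig_len_bp),
                 planted_ssrs = planted_ssrs,
                 n_individuals = as.integer(n_individuals),
                 repeat_shift_probs = repeat_shift_probs,
                 flank_mut_rate = flank_mut_rate,
                 populations = populations,
                 missing_rate = missing_rate),
            class = "sim_config")
}

canonical_motif_classes <- function() {
  all_motifs <- unlist(purrr::map(2:4, function(k) {
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1, paste,
          collapse = "")
  }))
  sort(unique(stats::na.omit(vapply(all_motifs, canonical_motif, character(1),
                                    USE.NAMES = FALSE))))
}

#' Simulate a reference assembly with planted repeats
#'
#' Background composition is uniform over ACGT; planted repeats are perfect,
#' and the single base on each side of a planted region is constrained so the
#' region cannot be extended, making the truth table exact.  Spurious repeats
#' arising by chance in the background are allowed (and are what makes
#' detector precision, as opposed to recall, interesting to measure).
#'
#' @param config See [sim_config()].
#' @return List with `contigs` (tibble `id`, `sequence`) and `truth` (tibble
#'   `locus_id`, `contig_id`, `start`, `end`, `motif`, `n_repeats`,
#'   `motif_length`).
#' @export
simulate_reference <- function(config = sim_config()) {
  with_preserved_seed(config$seed, {
    bases <- c("A", "C", "G", "T")
    contigs <- tibble(
      id = sprintf("contig%03d", seq_len(config$n_contigs)),
      sequence = vapply(seq_len(config$n_contigs), function(i) {
        paste(sample(bases, config$contig_len_bp, replace = TRUE),
              collapse = "")
      }, character(1))
    )
    planted <- config$planted_ssrs
    if (is.null(planted)) {
      classes <- canonical_motif_classes()
      planted <- tibble(
        contig = seq_len(config$n_contigs),
        motif = sample(classes, config$n_contigs, replace = TRUE),
        n_repeats = sample(4:10, config$n_contigs, replace = TRUE)
      )
      planted$position <- vapply(seq_len(nrow(planted)), function(i) {
        w <- nchar(planted$motif[i]) * planted$n_repeats[i]
        as.integer(sample(seq(60L, config$contig_len_bp - w - 60L), 1))
      }, integer(1))
    }
    truth_rows <- list()
    for (ci in sort(unique(planted$contig))) {
      rows <- planted[planted$contig == ci, ]
      rows <- rows[order(rows$position), ]
      widths <- nchar(rows$motif) * rows$n_repeats
      ends <- rows$position + widths
      if (any(rows$position < 1L) ||
          any(ends > config$contig_len_bp - 1L) ||
          (nrow(rows) > 1L && any(rows$position[-1] <= ends[-nrow(rows)] + 1L))) {
        abort(sprintf("planted repeats overlap or touch contig bounds on contig %d", ci))
      }
      x <- strsplit(contigs$sequence[ci], "", fixed = TRUE)[[1]]
      for (ri in seq_len(nrow(rows))) {
        motif <- rows$motif[ri]
        if (is.na(canonical_motif(motif))) {
          abort(sprintf("planted motif '%s' is degenerate", motif))
        }
        k <- nchar(motif)
        n <- rows$n_repeats[ri]
        pos <- rows$position[ri]          # 0-based start
        region <- strsplit(strrep(motif, n), "", fixed = TRUE)[[1]]
        x[(pos + 1L):(pos + k * n)] <- region
        # break extension: the base left of the region must not equal the
        # base one period inside, and likewise on the right
        x[pos] <- sample(setdiff(bases, x[pos + k]), 1)
        x[pos + k * n + 1L] <- sample(setdiff(bases, x[pos + k * n + 1L - k]), 1)
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          contig_id = contigs$id[ci], start = pos, end = pos + k * n,
          motif = canonical_motif(motif), n_repeats = n, motif_length = k
        )
      }
      contigs$sequence[ci] <- paste(x, collapse = "")
    }
    truth <- bind_rows(truth_rows)
    truth <- mutate(truth, locus_id = sprintf("%s:%d-%d:%s", .data$contig_id,
                                              .data$start, .data$end,
                                              .data$motif))
    truth <- truth[c("locus_id", "contig_id", "start", "end", "motif",
                     "n_repeats", "motif_length")]
    list(contigs = contigs, truth = truth)
  })
}

#' Simulate individual assemblies from a reference
#'
#' Each individual's contigs copy the reference with every planted repeat
#' count shifted by a delta drawn from `repeat_shift_probs` and flanking
#' sequence mutated by substitutions at `flank_mut_rate`.  The truth table
#' records every individual's realised repeat count.
#'
#' @param reference Output of [simulate_reference()].
#' @param config See [sim_config()]; the seed is offset so reference and
#'   individuals draw from distinct streams.
#' @return List with `individuals` (named list of contig tibbles) and
#'   `truth` (tibble `individual_id`, `locus_id`, `n_repeats`).
#' @export
simulate_individuals <- function(reference, config = sim_config()) {
  with_preserved_seed(config$seed + 1L, {
    bases <- c("A", "C", "G", "T")
    deltas <- as.integer(names(config$repeat_shift_probs))
    truth <- reference$truth
    out_truth <- list()
    individuals <- list()
    for (ind in seq_len(config$n_individuals)) {
      ind_id <- sprintf("ind%02d", ind)
      contigs <- reference$contigs
      for (ci in seq_len(nrow(contigs))) {
        loci <- truth[truth$contig_id == contigs$id[ci], ]
        seq_ref <- contigs$sequence[ci]
        if (nrow(loci) == 0L) {
          contigs$sequence[ci] <- mutate_flanks(seq_ref, integer(0),
                                                integer(0),
                                                config$flank_mut_rate, bases)
          next
        }
        loci <- loci[order(loci$start), ]
        pieces <- character(0)
        cursor <- 0L            # 0-based position consumed so far
        for (li in seq_len(nrow(loci))) {
          loc <- loci[li, ]
          delta <- sample(deltas, 1, prob = config$repeat_shift_probs)
          n_new <- max(1L, loc$n_repeats + delta)
          frame <- substr(seq_ref, loc$start + 1L, loc$start + loc$motif_length)
          pieces <- c(pieces,
                      substr(seq_ref, cursor + 1L, loc$start),
                      strrep(frame, n_new))
          cursor <- loc$end
          out_truth[[length(out_truth) + 1L]] <- tibble(
            individual_id = ind_id, locus_id = loc$locus_id,
            n_repeats = n_new)
        }
        pieces <- c(pieces, substr(seq_ref, cursor + 1L, nchar(seq_ref)))
        newseq <- paste(pieces, collapse = "")
        # mutate everything outside the (possibly shifted) repeat regions
        regions <- locate_regions(loci, newseq, seq_ref)
        contigs$sequence[ci] <- mutate_flanks(newseq, regions$start,
                                              regions$end,
                                              config$flank_mut_rate, bases)
      }
      contigs$id <- paste0(ind_id, "_", contigs$id)
      individuals[[ind_id]] <- contigs
    }
    list(individuals = individuals, truth = bind_rows(out_truth))
  })
}

# Repeat-region coordinates after repeat-count shifts: recompute by walking
# the same segment arithmetic used to build the sequence.
locate_regions <- function(loci, newseq, refseq) {
  starts <- integer(0)
  ends <- integer(0)
  offset <- 0L
  for (li in seq_len(nrow(loci))) {
    loc <- loci[li, ]
    ref_w <- loc$end - loc$start
    # width in newseq: difference accumulated so far handled via offset
    s <- loc$start + offset
    # width of the shifted region: find run length of the motif frame
    frame_w <- loc$motif_length
    w <- 0L
    frame <- substr(newseq, s + 1L, s + frame_w)
    while (substr(newseq, s + w + 1L, s + w + frame_w) == frame) {
      w <- w + frame_w
    }
    starts <- c(starts, s)
    ends <- c(ends, s + w)
    offset <- offset + (w - ref_w)
  }
  list(start = starts, end = ends)
}

mutate_flanks <- function(seq, region_starts, region_ends, rate, bases) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  protected <- logical(length(x))
  for (i in seq_along(region_starts)) {
    protected[(region_starts[i] + 1L):region_ends[i]] <- TRUE
  }
  hit <- which(runif(length(x)) < rate & !protected)
  for (i in hit) x[i] <- sample(setdiff(bases, x[i]), 1)
  paste(x, collapse = "")
}

#' Simulate a diploid genotype matrix under partial selfing
#'
#' Per population and locus, genotypes are drawn under the
#' inbreeding-coefficient model: with probability `f` the two allele copies
#' are identical by descent (one draw from the allele frequencies used
#' twice), otherwise they are independent draws.  At a biallelic locus this
#' gives `P(het) = 2pq(1 - f)` and homozygote probabilities `p^2 + pq f`,
#' `q^2 + pq f`.  Missing calls are sprinkled at `missing_rate` per call.
#'
#' @param allele_freqs Named list: one element per locus, itself either a
#'   single named numeric vector of allele-size frequencies (shared by all
#'   populations) or a named list of per-population vectors.
#' @param config See [sim_config()]; uses `populations`, `missing_rate` and
#'   `seed` (offset to a third stream).
#' @return List with `genotypes` (an `ssr_genotypes` tibble) and `truth`
#'   (the frequency list and population table actually used).
#' @export
simulate_genotype_matrix <- function(allele_freqs, config = sim_config()) {
  with_preserved_seed(config$seed + 2L, {
    pops <- config$populations
    loci <- names(allele_freqs)
    rows <- purrr::map(seq_len(nrow(pops)), function(pi) {
      pop <- pops[pi, ]
      out <- tibble(population = pop$name,
                    individual = sprintf("%s_%03d", pop$name, seq_len(pop$n)))
      for (loc in loci) {
        fr <- allele_freqs[[loc]]
        if (is.list(fr)) fr <- fr[[pop$name]]
        if (abs(sum(fr) - 1) > 1e-8) {
          abort(sprintf("allele frequencies at %s do not sum to 1", loc))
        }
        sizes <- as.integer(names(fr))
        a1 <- sizes[sample.int(length(sizes), pop$n, replace = TRUE, prob = fr)]
        a2 <- sizes[sample.int(length(sizes), pop$n, replace = TRUE, prob = fr)]
        ibd <- runif(pop$n) < pop$f
        a2[ibd] <- a1[ibd]
        miss <- runif(pop$n) < config$missing_rate
        a1[miss] <- NA_integer_
        a2[miss] <- NA_integer_
        lo <- pmin(a1, a2)
        hi <- pmax(a1, a2)
        out[[paste0(loc, ".1")]] <- lo
        out[[paste0(loc, ".2")]] <- hi
      }
      out
    })
    list(genotypes = new_genotypes(bind_rows(rows)),
         truth = list(allele_freqs = allele_freqs,
                      populations = pops,
                      missing_rate = config$missing_rate))
  })
}
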