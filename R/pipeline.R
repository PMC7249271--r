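#' Pipeline configuration
#'
#' Assembles (from a YAML file or a list) the full configuration of the
#' marker-development pipeline, filling every threshold with its default:
#' repeat-detection minima, primer enumeration and retention thresholds,
#' screening tolerances, and the statistics settings.  The configuration
#' round-trips through [yaml::write_yaml()]/[pipeline_config()].
#'
#' @param config A list or the path of a YAML file.  Recognised fields:
#'   `reference_fasta`, `individual_fastas` (named list/vector of paths),
#'   `genotypes_csv`, `out_dir`, `seed`, `min_repeats` (di/tri/tetra),
#'   `primer` (see [primer_params()]), `filter` (see [filter_pairs()]
#'   thresholds), `align` (see [align_params()]), `screen` (see
#'   [screen_thresholds()]), `hwe_reps`, `n_perm`, `drop_monomorphic`,
#'   `all_method`.
#' @return A validated list of class `ssr_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    reference_fasta = NULL, individual_fastas = NULL, genotypes_csv = NULL,
    out_dir = ".", seed = 1L,
    min_repeats = list(di = 4L, tri = 4L, tetra = 4L),
    primer = list(), filter = list(), align = list(), screen = list(),
    hwe_reps = 999L, n_perm = 999L, drop_monomorphic = TRUE,
    all_method = "pooled"
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$primer <- do.call(primer_params, cfg$primer)
  cfg$filter <- utils::modifyList(
    list(pair_penalty_max = 1.7, primer_penalty_max = 0.8, tm_diff_max = 2,
         min_dist = 20L, product_range = c(89L, 301L)), cfg$filter)
  cfg$align <- do.call(align_params, cfg$align)
  cfg$screen <- do.call(screen_thresholds, cfg$screen)
  cfg$min_repeats <- unlist(cfg$min_repeats)
  structure(cfg, class = "ssr_config")
}

#' Run the full marker-development pipeline
#'
#' Stage order: repeat discovery on the reference contigs, primer design and
#' retention filtering, in-silico polymorphism screening across individuals
#' (when individual assemblies are configured), and the diversity/linkage
#' statistics panel (when a genotype table is configured).  Stage outputs
#' are written as TSV under `out_dir` together with a machine-readable
#' `summary.tsv` of per-stage counts; the run is a pure function of inputs,
#' configuration and seed.
#'
#' @param config See [pipeline_config()]; a list or YAML path is accepted.
#' @return A list of class `ssr_pipeline` with elements `summary` (tibble of
#'   per-stage counts), `loci`, `markers`, `screen`, `diversity`, `ld`,
#'   `paralogy` (the in-memory results) and `paths`.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "ssr_config")) config else pipeline_config(config)
  if (is.null(cfg$reference_fasta)) {
    abort("stage discover: no reference FASTA configured")
  }
  if (!file.exists(cfg$reference_fasta)) {
    abort(sprintf("stage discover: reference FASTA not found: %s",
                  cfg$reference_fasta))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  summary_rows <- list()
  log_stage <- function(stage, what, n) {
    inform(sprintf("[%s] %s: %d", stage, what, n))
    summary_rows[[length(summary_rows) + 1L]] <<-
      tibble(stage = stage, quantity = what, count = as.integer(n))
  }

  records <- read_fasta(cfg$reference_fasta)
  loci <- find_ssrs(records, min_repeats = cfg$min_repeats)
  paths$loci <- file.path(cfg$out_dir, "loci.tsv")
  readr::write_tsv(loci, paths$loci, progress = FALSE)
  log_stage("discover", "repeat_loci", nrow(loci))

  markers <- design_markers(records, loci, params = cfg$primer)
  paths$markers <- file.path(cfg$out_dir, "markers.tsv")
  write_marker_table(markers, paths$markers)
  log_stage("design", "retained_markers", nrow(markers))

  screen <- NULL
  if (!is.null(cfg$individual_fastas) && length(cfg$individual_fastas) > 0L) {
    files <- unlist(cfg$individual_fastas)
    missing <- files[!file.exists(files)]
    if (length(missing) > 0L) {
      abort(sprintf("stage screen: individual FASTA not found: %s",
                    paste(missing, collapse = ", ")))
    }
    ids <- names(files) %||% tools::file_path_sans_ext(basename(files))
    if (is.null(names(files)) || any(!nzchar(ids))) names(files) <- ids
    individuals <- purrr::map(files, read_fasta)
    screen <- screen_markers(markers, records, individuals,
                             align = cfg$align, thresholds = cfg$screen)
    paths$screen <- file.path(cfg$out_dir, "screen.tsv")
    readr::write_tsv(tidy(screen), paths$screen, progress = FALSE)
    for (st in c("POLYMORPHIC", "MONOMORPHIC", "INSUFFICIENT")) {
      log_stage("screen", tolower(st), sum(screen$status == st))
    }
  }

  diversity <- NULL
  ld <- NULL
  paralogy <- NULL
  if (!is.null(cfg$genotypes_csv)) {
    if (!file.exists(cfg$genotypes_csv)) {
      abort(sprintf("stage stats: genotype table not found: %s",
                    cfg$genotypes_csv))
    }
    genotypes <- read_genotype_table(cfg$genotypes_csv)
    diversity <- diversity_table(genotypes,
                                 drop_monomorphic = cfg$drop_monomorphic,
                                 hwe_reps = cfg$hwe_reps, seed = cfg$seed,
                                 all_method = cfg$all_method)
    paths$diversity <- file.path(cfg$out_dir, "diversity.tsv")
    write_diversity_table(diversity, paths$diversity)
    if (length(genotype_loci(genotypes)) >= 2L) {
      ld <- ld_table(genotypes, n_perm = cfg$n_perm, seed = cfg$seed)
      paths$ld <- file.path(cfg$out_dir, "ld.tsv")
      readr::write_tsv(as_tibble(ld), paths$ld, progress = FALSE)
    }
    paralogy <- paralogy_flag(genotypes)
    paths$paralogy <- file.path(cfg$out_dir, "paralogy.tsv")
    readr::write_tsv(paralogy, paths$paralogy, progress = FALSE)
    log_stage("stats", "diversity_records", nrow(diversity))
    log_stage("stats", "paralogy_flagged", sum(paralogy$flagged))
  }

  summary <- bind_rows(summary_rows)
  paths$summary <- file.path(cfg$out_dir, "summary.tsv")
  readr::write_tsv(summary, paths$summary, progress = FALSE)
  structure(list(summary = summary, loci = loci, markers = markers,
                 screen = screen, diversity = diversity, ld = ld,
                 paralogy = paralogy, paths = paths, config = cfg),
            class = "ssr_pipeline")
}
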