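# Orchestration: configuration validation and the end-to-end run
# (aggregate -> normalize -> select/filter -> target & non-target
# composition -> correlations -> ITA -> reports). Every stage logs its
# row counts; re-running on identical inputs is byte-identical.

#' Pipeline run configuration
#'
#' Bundles input paths and analysis thresholds. `pipeline_config()` fills
#' defaults and `validate_config()` checks ranges and file existence
#' before any computation.
#'
#' @param isomir_counts,mrna_counts,isomir_seqs,transcripts_fasta,regions,
#'   rna22,targetscan,sample_groups input file paths (see the readers for
#'   the formats). `rna22` and `targetscan` may individually be `NULL` (at
#'   least one prediction table is required).
#' @param outdir output directory.
#' @param rho_max,fdr_max anti-correlation thresholds (defaults -0.3,
#'   0.05).
#' @param active_fdr_max Fisher-FDR threshold declaring an isomiR active.
#' @param coverage median-expression coverage for isomiR selection
#'   (default 0.99).
#' @param min_group_size smallest analyzable sample group.
#' @param strata stratification of ITA records: `"pooled"`,
#'   `"seed_type"`, `"region"` or `"seed_type_region"`.
#' @param groups optional subset of group labels to analyze.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(isomir_counts, mrna_counts, isomir_seqs,
                            transcripts_fasta, regions,
                            rna22 = NULL, targetscan = NULL,
                            sample_groups, outdir,
                            rho_max = -0.3, fdr_max = 0.05,
                            active_fdr_max = 0.05,
                            coverage = 0.99, min_group_size = 3L,
                            strata = "pooled", groups = NULL) {
  structure(list(
    isomir_counts = isomir_counts, mrna_counts = mrna_counts,
    isomir_seqs = isomir_seqs, transcripts_fasta = transcripts_fasta,
    regions = regions, rna22 = rna22, targetscan = targetscan,
    sample_groups = sample_groups, outdir = outdir,
    rho_max = rho_max, fdr_max = fdr_max, active_fdr_max = active_fdr_max,
    coverage = coverage, min_group_size = as.integer(min_group_size),
    strata = strata, groups = groups
  ), class = "pipeline_config")
}

#' Configuration for a fixture bundle directory
#'
#' Convenience wrapper building a [pipeline_config()] from the standard
#' [bundle_paths()] layout.
#'
#' @param dir bundle directory (from [write_fixture_bundle()]).
#' @param outdir output directory (default `file.path(dir, "output")`).
#' @param ... further arguments to [pipeline_config()].
#' @export
bundle_config <- function(dir, outdir = file.path(dir, "output"), ...) {
  p <- bundle_paths(dir)
  pipeline_config(
    isomir_counts = p$isomir_counts, mrna_counts = p$mrna_counts,
    isomir_seqs = p$isomir_seqs, transcripts_fasta = p$transcripts_fasta,
    regions = p$regions, rna22 = p$rna22, targetscan = p$targetscan,
    sample_groups = p$sample_groups, outdir = outdir, ...
  )
}

#' @param cfg a `pipeline_config`.
#' @rdname pipeline_config
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!cfg$strata %in% c("pooled", "seed_type", "region", "seed_type_region")) {
    .stop_invalid("unknown stratum selection: ", cfg$strata)
  }
  if (!(cfg$rho_max > -1 && cfg$rho_max < 1)) .stop_invalid("rho_max must be in (-1, 1)")
  for (thr in c("fdr_max", "active_fdr_max", "coverage")) {
    if (!(cfg[[thr]] > 0 && cfg[[thr]] <= 1)) {
      .stop_invalid(thr, " must be in (0, 1]")
    }
  }
  if (is.null(cfg$rna22) && is.null(cfg$targetscan)) {
    .stop_invalid("at least one prediction table (rna22/targetscan) is required")
  }
  files <- c("isomir_counts", "mrna_counts", "isomir_seqs",
             "transcripts_fasta", "regions", "rna22", "targetscan",
             "sample_groups")
  for (f in files) {
    path <- cfg[[f]]
    if (!is.null(path) && !file.exists(path)) {
      .stop_invalid("input file for '", f, "' does not exist: ", path)
    }
  }
  invisible(cfg)
}

.stage <- function(name, ...) message("[", name, "] ", ...)

#' Run the full isomiR targeting-activity pipeline
#'
#' Executes, in order: 3'-variant aggregation to 5'-isomiRs; size-factor
#' normalization (FPM for isomiRs, FPKM for transcripts) and log2(x+1);
#' isomiR selection by median-expression coverage; the transcript
#' low-expression filter; prediction-table reading (re-classified against
#' the sequences) and site-level union; non-target set composition via the
#' 6-mer index; per-group Spearman correlations and ITA records; active-set
#' reporting. Each stage writes its TSV under `cfg$outdir` and logs record
#' counts to the message stream.
#'
#' @param cfg a validated [pipeline_config()].
#' @return invisibly, a list with `selected_isomirs`, `interactions`,
#'   `nontargets`, `profile` (see [compute_ita_profile()]), `active`
#'   (see [report_active_sets()]; `NULL` with one group) and `files`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  .stage("aggregate", "reading isomiR counts: ", cfg$isomir_counts)
  iso_raw <- read_count_matrix(cfg$isomir_counts)
  iso_counts <- aggregate_5prime_isomirs(iso_raw)
  .stage("aggregate", nrow(iso_raw), " isomiR variant rows -> ",
         nrow(iso_counts), " 5'-isomiRs")

  groups_df <- read_sample_groups(cfg$sample_groups)
  samples <- intersect(colnames(iso_counts), groups_df$sample_id)
  if (!is.null(cfg$groups)) {
    keep <- groups_df$sample_id[groups_df$group %in% cfg$groups]
    samples <- intersect(samples, keep)
  }
  iso_counts <- iso_counts[, samples, drop = FALSE]

  .stage("normalize", "isomiR FPM over ", length(samples), " samples")
  iso_fpm <- normalize_counts(iso_counts, mode = "FPM", log2 = TRUE)
  medians <- apply(iso_fpm, 1L, stats::median)
  selected <- select_top_isomirs(medians, coverage = cfg$coverage)
  .stage("select", length(selected), " of ", nrow(iso_fpm),
         " isomiRs cover ", format(cfg$coverage), " of total median expression")

  .stage("mrna", "reading transcript counts: ", cfg$mrna_counts)
  mrna_raw <- read_count_matrix(cfg$mrna_counts)
  mrna_raw <- mrna_raw[, samples, drop = FALSE]
  mrna_counts <- filter_low_transcripts(mrna_raw)
  .stage("filter", nrow(mrna_raw) - nrow(mrna_counts),
         " transcripts dropped (zero in more than half of samples); ",
         nrow(mrna_counts), " kept")

  transcripts <- read_transcripts(cfg$transcripts_fasta, cfg$regions)
  transcripts <- transcripts[transcripts$transcript_id %in% rownames(mrna_counts), ,
                             drop = FALSE]
  mrna_counts <- mrna_counts[transcripts$transcript_id, , drop = FALSE]
  .stage("sequences", nrow(transcripts), " transcripts with sequence and expression")

  lens <- stats::setNames(transcripts$length, transcripts$transcript_id)
  mrna_fpkm <- normalize_counts(mrna_counts, mode = "FPKM", lengths = lens,
                                log2 = TRUE)

  iso_seqs <- utils::read.delim(cfg$isomir_seqs, stringsAsFactors = FALSE)
  iso_seqs <- isomir_sequences(iso_seqs$isomir, iso_seqs$seq)
  iso_seqs <- iso_seqs[iso_seqs$isomir %in% selected, , drop = FALSE]

  tabs <- list()
  if (!is.null(cfg$rna22)) {
    tabs$rna22 <- read_rna22_table(cfg$rna22, transcripts, iso_seqs)
    .stage("predictions", nrow(tabs$rna22), " RNA22-like site rows")
  }
  if (!is.null(cfg$targetscan)) {
    tabs$targetscan <- read_targetscan_table(cfg$targetscan, transcripts, iso_seqs)
    .stage("predictions", nrow(tabs$targetscan), " TargetScan-like site rows")
  }
  interactions <- if (length(tabs) == 2L) {
    union_interactions(tabs[[1]], tabs[[2]])
  } else {
    tabs[[1]]
  }
  interactions <- interactions[interactions$isomir %in% iso_seqs$isomir, ,
                               drop = FALSE]
  .stage("union", nrow(interactions), " site rows; ",
         nrow(interaction_pairs(interactions)), " isomiR-transcript pairs")

  .stage("nontargets", "building 6-mer index over ", nrow(transcripts),
         " transcripts")
  index <- build_kmer_index(transcripts, k = 6L)
  nontargets <- lapply(
    stats::setNames(iso_seqs$seq, iso_seqs$isomir),
    compose_nontarget_set, index = index
  )
  .stage("nontargets", "median non-target set size: ",
         stats::median(lengths(nontargets)))

  .stage("ita", "correlations and ITA records (strata: ", cfg$strata, ")")
  profile <- compute_ita_profile(
    iso_fpm[selected, , drop = FALSE], mrna_fpkm,
    groups_df, interactions, nontargets,
    strata = cfg$strata, rho_max = cfg$rho_max, fdr_max = cfg$fdr_max,
    min_group_size = cfg$min_group_size, groups = cfg$groups
  )
  .stage("ita", nrow(profile$ita), " ITA records in ",
         length(unique(profile$ita$group)), " group(s)")

  files <- list(
    correlations = file.path(cfg$outdir, "correlations.tsv"),
    ita = file.path(cfg$outdir, "ita.tsv"),
    active = file.path(cfg$outdir, "active_sets.tsv"),
    overlap = file.path(cfg$outdir, "active_set_overlap.tsv")
  )
  wt <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(profile$correlations, files$correlations)
  wt(profile$ita, files$ita)

  act_tab <- profile$ita[profile$ita$stratum ==
                           (if (cfg$strata == "pooled") "pooled" else unique(profile$ita$stratum)[1]), ,
                         drop = FALSE]
  active_df <- data.frame(
    isomir = act_tab$isomir, group = act_tab$group,
    active = act_tab$fisher_fdr < cfg$active_fdr_max,
    stringsAsFactors = FALSE
  )
  wt(active_df, files$active)

  active <- NULL
  if (length(unique(profile$ita$group)) >= 2L && cfg$strata == "pooled") {
    active <- report_active_sets(profile$ita, fdr_max = cfg$active_fdr_max)
    wt(active$jaccard, files$overlap)
    .stage("report", "active isomiRs per group: ",
           paste(sprintf("%s=%d", names(active$active),
                         lengths(active$active)), collapse = ", "))
  }

  invisible(list(
    selected_isomirs = selected, interactions = interactions,
    nontargets = nontargets, profile = profile, active = active,
    files = files
  ))
}
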