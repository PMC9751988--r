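# Synthetic-data module: self-contained inputs with the statistical
# structure the analysis assumes. Transcript sequences carry planted seed
# sites for designated true targets; background transcripts are scrubbed
# (by local rejection sampling) of every wobble-admissible seed 6-mer of
# every isomiR, so they are guaranteed non-targets of all isomiRs.
# Expression is log-normal with additive log-scale regulation: a true
# target's log-expression follows its isomiR with slope beta (< 0 for
# repression); independent non-targets are pure noise; a configurable
# fraction of transcripts is driven by a latent confounder that also
# drives designated isomiRs, creating anti-correlation without targeting
# (the situation the background adjustment exists for).

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package: 20 isomiRs of which 10 are active with 30 planted targets
#' each, repression slope `beta = -1` on the natural-log scale,
#' 200 samples per group, and no confounding (`gamma = 0`).
#'
#' @param n_transcripts total transcripts (planted-target pool plus
#'   scrubbed background).
#' @param transcript_length inclusive length range (nt).
#' @param utr5_frac,cds_frac fractions of each transcript assigned to the
#'   5'-UTR and CDS (remainder is 3'-UTR).
#' @param n_isomirs number of isomiRs (distinct seeds enforced).
#' @param isomir_length isomiR length (nt).
#' @param n_active isomiRs with planted targets; the rest are nulls.
#' @param targets_per_isomir planted targets per active isomiR (disjoint
#'   across isomiRs).
#' @param planted_seed_type seed type of planted sites.
#' @param planted_region region in which sites are planted.
#' @param n_samples samples per group.
#' @param groups group labels.
#' @param group_active optional named list `group -> active isomiR
#'   indices` restricting where planted regulation operates (default: all
#'   groups).
#' @param beta log-scale slope of a true target on its isomiR (<= 0 for
#'   repression).
#' @param sigma residual log-scale noise sd of transcripts.
#' @param tau log-scale sd of isomiR expression across samples.
#' @param mu_iso_log_range range of isomiR mean log-expression (natural
#'   log of counts).
#' @param baseline_log_range range of background-transcript baseline
#'   log-expression (reaches low values so that zero counts occur and the
#'   transcript filter is exercised).
#' @param target_baseline_log_range baseline range for planted targets
#'   (kept away from zero counts).
#' @param gamma fraction of transcripts driven by the confounder.
#' @param confounder_slope log-scale slope of confounded transcripts on
#'   the confounder (negative yields anti-correlation with confounded
#'   isomiRs).
#' @param n_confounded_isomirs null isomiRs driven by the confounder when
#'   `gamma > 0`.
#' @param seed integer RNG seed; every draw is a pure function of the
#'   configuration including this seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_transcripts = 450L,
                              transcript_length = c(150L, 400L),
                              utr5_frac = 0.15, cds_frac = 0.55,
                              n_isomirs = 20L, isomir_length = 22L,
                              n_active = 10L, targets_per_isomir = 30L,
                              planted_seed_type = "8mer",
                              planted_region = "3UTR",
                              n_samples = 200L,
                              groups = c("tumor", "normal"),
                              group_active = NULL,
                              beta = -1, sigma = 0.5, tau = 1,
                              mu_iso_log_range = log(c(50, 500)),
                              baseline_log_range = log(c(0.5, 200)),
                              target_baseline_log_range = log(c(20, 200)),
                              gamma = 0, confounder_slope = -1,
                              n_confounded_isomirs = 2L,
                              seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    utr5_frac = utr5_frac, cds_frac = cds_frac,
    n_isomirs = as.integer(n_isomirs),
    isomir_length = as.integer(isomir_length),
    n_active = as.integer(n_active),
    targets_per_isomir = as.integer(targets_per_isomir),
    planted_seed_type = planted_seed_type,
    planted_region = planted_region,
    n_samples = as.integer(n_samples),
    groups = groups, group_active = group_active,
    beta = beta, sigma = sigma, tau = tau,
    mu_iso_log_range = mu_iso_log_range,
    baseline_log_range = baseline_log_range,
    target_baseline_log_range = target_baseline_log_range,
    gamma = gamma, confounder_slope = confounder_slope,
    n_confounded_isomirs = as.integer(n_confounded_isomirs),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_transcripts >= 1L, cfg$n_isomirs >= 1L,
    cfg$n_active >= 0L, cfg$n_active <= cfg$n_isomirs,
    cfg$targets_per_isomir >= 1L,
    cfg$n_active * cfg$targets_per_isomir < cfg$n_transcripts,
    cfg$isomir_length >= 16L, cfg$isomir_length <= 30L,
    cfg$beta <= 0, cfg$sigma > 0, cfg$tau > 0,
    cfg$gamma >= 0, cfg$gamma <= 1,
    cfg$planted_seed_type %in% .CLASSICAL_TYPES,
    cfg$planted_region %in% .REGIONS,
    length(cfg$groups) >= 1L, cfg$n_samples >= 3L
  )
  structure(cfg, class = "simulation_config")
}

.sample_rna <- function(n) {
  paste(sample(.RNA_BASES, n, replace = TRUE), collapse = "")
}

# Build the 8-nt mRNA window that classifies as the requested seed type
# for the given isomiR (window position 9 - j opposes seed position j).
.plant_window <- function(seq, seed_type) {
  s <- strsplit(substr(seq, 1L, 8L), "", fixed = TRUE)[[1]]
  rc <- function(jj) paste(.WC[s[rev(jj)]], collapse = "")
  non_wc8 <- setdiff(.RNA_BASES, c(.WC[[s[8]]]))
  switch(seed_type,
    "8mer" = paste0(rc(2:8), "A"),
    "7mer-m8" = paste0(rc(2:8), "C"),
    "7mer-A1" = paste0(non_wc8[1], rc(2:7), "A"),
    "6mer" = paste0(non_wc8[1], rc(2:7), "C"),
    .stop_invalid("can only plant classical seed types")
  )
}

# Remove every occurrence of a forbidden 6-mer from a sequence by
# redrawing the offending window positions; iterates until clean.
.scrub_sequence <- function(seq, forbidden, max_iter = 200L) {
  for (it in seq_len(max_iter)) {
    L <- nchar(seq)
    starts <- seq_len(L - 5L)
    hits <- starts[substring(seq, starts, starts + 5L) %in% forbidden]
    if (length(hits) == 0L) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    redo <- unique(unlist(lapply(hits, function(h) h:(h + 5L))))
    chars[redo] <- sample(.RNA_BASES, length(redo), replace = TRUE)
    seq <- paste(chars, collapse = "")
  }
  .stop_invalid(
    "could not scrub all admissible 6-mers after ", max_iter,
    " passes; use longer transcripts or fewer isomiRs"
  )
}

#' Generate a synthetic transcriptome with planted seed sites
#'
#' Draws isomiR sequences with distinct seeds and random transcripts with
#' uniform nucleotide composition. Each active isomiR receives a disjoint
#' block of target transcripts with one site of the requested seed type
#' planted at a random position inside the requested region; all remaining
#' (background) transcripts are scrubbed of every wobble-admissible seed
#' 6-mer of every isomiR, so [compose_nontarget_set()] is guaranteed to
#' return them for every isomiR. Deterministic under `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list with `transcripts` (see [make_transcripts()]), `iso_seqs`
#'   (data frame `isomir`, `seq`), `truth_sites` (planted sites:
#'   `isomir`, `transcript_id`, `window_start`, `seed_type`, `region`),
#'   `target_map` (named list isomiR -> planted transcript ids),
#'   `background_ids`, and `active_isomirs`.
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)

  # isomiRs: distinct seeds (positions 2-7)
  shifts <- sample(c(0L, 0L, 0L, 1L, -1L), cfg$n_isomirs, replace = TRUE)
  iso_seq <- character(cfg$n_isomirs)
  seen_seeds <- character(0)
  for (i in seq_len(cfg$n_isomirs)) {
    repeat {
      cand <- .sample_rna(cfg$isomir_length)
      sd6 <- substr(cand, 2L, 7L)
      if (!sd6 %in% seen_seeds) {
        iso_seq[i] <- cand
        seen_seeds <- c(seen_seeds, sd6)
        break
      }
    }
  }
  iso_ids <- format_isomir_id(sprintf("syn-miR-%03d-5p", seq_len(cfg$n_isomirs)),
                              shifts)
  iso_seqs <- isomir_sequences(iso_ids, iso_seq)
  active <- iso_ids[seq_len(cfg$n_active)]

  # transcript scaffolds
  lens <- sample(seq(cfg$transcript_length[1], cfg$transcript_length[2]),
                 cfg$n_transcripts, replace = TRUE)
  utr5 <- as.integer(round(lens * cfg$utr5_frac))
  cds <- as.integer(round(lens * (cfg$utr5_frac + cfg$cds_frac)))
  tids <- sprintf("TX%04d", seq_len(cfg$n_transcripts))
  seqs <- vapply(lens, .sample_rna, character(1))

  # role assignment: disjoint planted-target blocks, remainder background
  n_planted <- cfg$n_active * cfg$targets_per_isomir
  planted_idx <- if (n_planted > 0L) {
    sample(cfg$n_transcripts, n_planted)
  } else {
    integer(0)
  }
  target_map <- split(
    tids[planted_idx],
    rep(active, each = cfg$targets_per_isomir)
  )[active]
  if (cfg$n_active == 0L) target_map <- stats::setNames(list(), character(0))
  background <- setdiff(tids, tids[planted_idx])

  # scrub the background of every admissible 6-mer of every isomiR
  forbidden <- unique(unlist(lapply(iso_seqs$seq, function(s) {
    seed_site_kmers(extract_seed(s), allow_wobble = TRUE)
  }), use.names = FALSE))
  bg <- match(background, tids)
  seqs[bg] <- vapply(seqs[bg], .scrub_sequence, character(1),
                     forbidden = forbidden)

  # plant one site per (active isomiR, target transcript)
  truth <- list()
  for (iso in active) {
    w <- .plant_window(iso_seqs$seq[match(iso, iso_seqs$isomir)],
                       cfg$planted_seed_type)
    for (tid in target_map[[iso]]) {
      j <- match(tid, tids)
      bounds <- switch(cfg$planted_region,
        "5UTR" = c(0L, utr5[j]),
        "CDS" = c(utr5[j], cds[j]),
        "3UTR" = c(cds[j], lens[j])
      )
      if (bounds[2] - bounds[1] < 8L) {
        .stop_invalid("planted region too short on ", tid)
      }
      ws <- bounds[1] + sample.int(bounds[2] - bounds[1] - 7L, 1L) - 1L
      substr(seqs[j], ws + 1L, ws + 8L) <- w
      truth[[length(truth) + 1L]] <- data.frame(
        isomir = iso, transcript_id = tid, window_start = ws,
        seed_type = cfg$planted_seed_type, region = cfg$planted_region,
        stringsAsFactors = FALSE
      )
    }
  }
  truth_sites <- if (length(truth) > 0L) {
    do.call(rbind, truth)
  } else {
    data.frame(isomir = character(0), transcript_id = character(0),
               window_start = integer(0), seed_type = character(0),
               region = character(0), stringsAsFactors = FALSE)
  }

  list(
    transcripts = make_transcripts(tids, seqs, utr5, cds),
    iso_seqs = iso_seqs,
    truth_sites = truth_sites,
    target_map = target_map,
    background_ids = background,
    active_isomirs = active
  )
}

#' Generate grouped expression matrices over a synthetic transcriptome
#'
#' IsomiR log-expression is Normal per sample; a true target's
#' log-expression is its baseline plus `beta` times the isomiR's log
#' deviation plus noise; independent transcripts are baseline plus noise;
#' confounded transcripts additionally follow the latent per-sample
#' confounder, which also drives the designated confounded isomiRs.
#' Values are exponentiated and rounded to non-negative integer counts.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param truth output of [generate_transcriptome()].
#' @return list with `iso_counts`, `mrna_counts` (integer matrices),
#'   `sample_groups` (data frame), `confounded_transcripts`,
#'   `confounded_isomirs`.
#' @export
generate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  iso_ids <- truth$iso_seqs$isomir
  tids <- truth$transcripts$transcript_id
  n_iso <- length(iso_ids)
  n_tx <- length(tids)

  mu_iso <- runif(n_iso, cfg$mu_iso_log_range[1], cfg$mu_iso_log_range[2])
  baseline <- runif(n_tx, cfg$baseline_log_range[1], cfg$baseline_log_range[2])
  planted_tx <- unique(unlist(truth$target_map, use.names = FALSE))
  baseline[match(planted_tx, tids)] <- runif(
    length(planted_tx),
    cfg$target_baseline_log_range[1], cfg$target_baseline_log_range[2]
  )

  confounded_tx <- character(0)
  confounded_iso <- character(0)
  if (cfg$gamma > 0) {
    confounded_tx <- sort(sample(tids, round(cfg$gamma * n_tx)))
    nulls <- setdiff(iso_ids, truth$active_isomirs)
    confounded_iso <- sort(sample(nulls, min(cfg$n_confounded_isomirs,
                                             length(nulls))))
  }

  # planted regulation map: rows of (iso index, tx index), per group mask
  reg <- do.call(rbind, lapply(names(truth$target_map), function(iso) {
    cbind(match(iso, iso_ids), match(truth$target_map[[iso]], tids))
  }))
  active_in <- function(g) {
    if (is.null(cfg$group_active)) return(truth$active_isomirs)
    iso_ids[cfg$group_active[[g]]]
  }

  sample_ids <- character(0)
  group_lab <- character(0)
  iso_cols <- list()
  tx_cols <- list()
  for (g in cfg$groups) {
    ids <- sprintf("%s_S%03d", g, seq_len(cfg$n_samples))
    sample_ids <- c(sample_ids, ids)
    group_lab <- c(group_lab, rep(g, cfg$n_samples))
    z_conf <- rnorm(cfg$n_samples)
    iso_log <- matrix(mu_iso, n_iso, cfg$n_samples) +
      matrix(rnorm(n_iso * cfg$n_samples, sd = cfg$tau), n_iso)
    if (length(confounded_iso) > 0L) {
      ci <- match(confounded_iso, iso_ids)
      iso_log[ci, ] <- matrix(mu_iso[ci], length(ci), cfg$n_samples) +
        rep(z_conf, each = length(ci)) +
        matrix(rnorm(length(ci) * cfg$n_samples, sd = 0.5), length(ci))
    }
    tx_log <- matrix(baseline, n_tx, cfg$n_samples) +
      matrix(rnorm(n_tx * cfg$n_samples, sd = cfg$sigma), n_tx)
    if (!is.null(reg)) {
      iso_on <- active_in(g)
      for (r in seq_len(nrow(reg))) {
        if (!iso_ids[reg[r, 1]] %in% iso_on) next
        dev <- iso_log[reg[r, 1], ] - mu_iso[reg[r, 1]]
        tx_log[reg[r, 2], ] <- tx_log[reg[r, 2], ] + cfg$beta * dev
      }
    }
    if (length(confounded_tx) > 0L) {
      ct <- match(confounded_tx, tids)
      tx_log[ct, ] <- tx_log[ct, ] +
        cfg$confounder_slope * rep(z_conf, each = length(ct))
    }
    iso_cols[[g]] <- iso_log
    tx_cols[[g]] <- tx_log
  }

  iso_counts <- round(exp(do.call(cbind, iso_cols)))
  mrna_counts <- round(exp(do.call(cbind, tx_cols)))
  dimnames(iso_counts) <- list(iso_ids, sample_ids)
  dimnames(mrna_counts) <- list(tids, sample_ids)
  list(
    iso_counts = iso_counts,
    mrna_counts = mrna_counts,
    sample_groups = data.frame(sample_id = sample_ids, group = group_lab,
                               stringsAsFactors = FALSE),
    confounded_transcripts = confounded_tx,
    confounded_isomirs = confounded_iso
  )
}

#' Simulate a complete dataset
#'
#' Runs [generate_transcriptome()] and [generate_expression()], scans all
#' isomiRs against all transcripts with the internal predictor
#' ([scan_target_sites()]), composes every non-target set, and assembles
#' the pair-level ground truth (`true_target`, `independent_nontarget`,
#' `confounded_nontarget`; pairs that are neither planted targets nor
#' guaranteed non-targets — e.g. chance seed-site carriers — are outside
#' the truth table).
#'
#' @param cfg a [simulation_config()].
#' @return list with everything from both generators plus `interactions`
#'   (internal predictor site table), `nontargets` (named list) and
#'   `truth_pairs` (data frame `isomir`, `transcript_id`, `role`).
#' @export
simulate_dataset <- function(cfg) {
  tx <- generate_transcriptome(cfg)
  ex <- generate_expression(cfg, tx)
  index <- build_kmer_index(tx$transcripts, k = 6L)
  interactions <- do.call(rbind, lapply(seq_len(nrow(tx$iso_seqs)), function(i) {
    scan_target_sites(tx$iso_seqs$isomir[i], tx$iso_seqs$seq[i],
                      tx$transcripts, index)
  }))
  nontargets <- lapply(
    stats::setNames(tx$iso_seqs$seq, tx$iso_seqs$isomir),
    compose_nontarget_set, index = index
  )
  truth_pairs <- do.call(rbind, lapply(tx$iso_seqs$isomir, function(iso) {
    planted <- tx$target_map[[iso]]
    non <- nontargets[[iso]]
    data.frame(
      isomir = iso,
      transcript_id = c(planted, non),
      role = c(
        rep("true_target", length(planted)),
        ifelse(non %in% ex$confounded_transcripts,
               "confounded_nontarget", "independent_nontarget")
      ),
      stringsAsFactors = FALSE
    )
  }))
  c(tx, ex, list(interactions = interactions, nontargets = nontargets,
                 truth_pairs = truth_pairs, config = cfg))
}

#' Write a fixture bundle to disk
#'
#' Emits every input file the pipeline reads — transcript FASTA, region
#' TSV, isomiR and transcript count TSVs (isomiR counts are split into two
#' 3'-variant rows per isomiR, preserving the totals, so aggregation is
#' exercised), isomiR sequence TSV, sample-group TSV, and the internal
#' predictor output reformatted as both an RNA22-like and a
#' TargetScan-like table — plus the ground-truth TSVs (`ground_truth.tsv`,
#' `planted_sites.tsv`), which the pipeline never reads.
#'
#' @param cfg a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @param sim optional pre-computed [simulate_dataset()] result for `cfg`.
#' @return invisibly, a named list of file paths (also see
#'   [bundle_paths()]).
#' @export
write_fixture_bundle <- function(cfg, outdir, sim = NULL) {
  if (is.null(sim)) sim <- simulate_dataset(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- bundle_paths(outdir)

  fa <- sprintf(">%s\n%s", sim$transcripts$transcript_id, sim$transcripts$seq)
  writeLines(fa, paths$transcripts_fasta)
  utils::write.table(
    sim$transcripts[c("transcript_id", "utr5_end", "cds_end")],
    paths$regions, sep = "\t", quote = FALSE, row.names = FALSE
  )

  # split each 5'-isomiR into two 3'-variants (counts preserved exactly)
  v1 <- floor(sim$iso_counts * 0.6)
  v2 <- sim$iso_counts - v1
  raw <- rbind(v1, v2)
  rownames(raw) <- c(paste0(rownames(sim$iso_counts), "|3p0"),
                     paste0(rownames(sim$iso_counts), "|3p1"))
  raw <- raw[order(rownames(raw)), , drop = FALSE]
  write_count_matrix(raw, paths$isomir_counts)
  write_count_matrix(sim$mrna_counts, paths$mrna_counts)

  utils::write.table(sim$iso_seqs, paths$isomir_seqs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$sample_groups, paths$sample_groups, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_rna22_table(sim$interactions, paths$rna22)
  ts <- sim$interactions[sim$interactions$seed_type %in% .CLASSICAL_TYPES &
                           sim$interactions$region == "3UTR", , drop = FALSE]
  write_targetscan_table(ts, paths$targetscan)

  utils::write.table(sim$truth_pairs, paths$ground_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_sites, paths$planted_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Standard file layout of a fixture bundle
#'
#' @param dir bundle directory.
#' @return named list of file paths.
#' @export
bundle_paths <- function(dir) {
  list(
    transcripts_fasta = file.path(dir, "transcripts.fasta"),
    regions = file.path(dir, "regions.tsv"),
    isomir_counts = file.path(dir, "isomir_counts.tsv"),
    mrna_counts = file.path(dir, "mrna_counts.tsv"),
    isomir_seqs = file.path(dir, "isomir_seqs.tsv"),
    sample_groups = file.path(dir, "sample_groups.tsv"),
    rna22 = file.path(dir, "rna22_like.tsv"),
    targetscan = file.path(dir, "targetscan_like.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    planted_sites = file.path(dir, "planted_sites.tsv")
  )
}
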