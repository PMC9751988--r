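# small configuration used across these tests (unit scale; the reference
# study conditions are the defaults and are exercised in the acceptance
# suite)
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_transcripts = 100, transcript_length = c(120, 250),
         n_isomirs = 6, n_active = 2, targets_per_isomir = 8,
         n_samples = 50, groups = "g1", seed = 101),
    list(...)
  )
  do.call(simulation_config, args)
}

test_that("generators are pure functions of the configuration", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(cfg, d1)
  write_fixture_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the sequences
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(small_cfg(seed = 102))
  expect_false(identical(tx1$transcripts$seq, tx2$transcripts$seq))
})

test_that("planted sites classify as the requested type, in the requested region", {
  for (st in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    tx <- generate_transcriptome(small_cfg(planted_seed_type = st,
                                           planted_region = "CDS"))
    expect_gt(nrow(tx$truth_sites), 0)
    got <- mapply(function(iso, tid, ws) {
      seq <- tx$transcripts$seq[match(tid, tx$transcripts$transcript_id)]
      classify_site(tx$iso_seqs$seq[match(iso, tx$iso_seqs$isomir)],
                    substr(seq, ws + 1, ws + 8))
    }, tx$truth_sites$isomir, tx$truth_sites$transcript_id,
       tx$truth_sites$window_start)
    expect_true(all(got == st))
    tr <- tx$transcripts[match(tx$truth_sites$transcript_id,
                               tx$transcripts$transcript_id), ]
    expect_true(all(tx$truth_sites$window_start >= tr$utr5_end &
                      tx$truth_sites$window_start < tr$cds_end))
  }
})

test_that("scrubbed background transcripts are non-targets of every isomiR", {
  tx <- generate_transcriptome(small_cfg())
  idx <- build_kmer_index(tx$transcripts)
  for (i in seq_len(nrow(tx$iso_seqs))) {
    non <- compose_nontarget_set(tx$iso_seqs$seq[i], idx)
    expect_true(all(tx$background_ids %in% non))
  }
})

test_that("expression counts are non-negative integers with sane structure", {
  cfg <- small_cfg()
  tx <- generate_transcriptome(cfg)
  ex <- generate_expression(cfg, tx)
  for (m in list(ex$iso_counts, ex$mrna_counts)) {
    expect_true(all(m >= 0))
    expect_true(all(m == round(m)))
  }
  expect_identical(ncol(ex$iso_counts), 50L)
  expect_identical(sort(unique(ex$sample_groups$group)), "g1")
  # low baselines produce genuine zeros, so the transcript filter has work
  expect_gt(sum(ex$mrna_counts == 0), 0)
})

test_that("independent pairs have near-zero Spearman correlation when beta = 0", {
  cfg <- small_cfg(beta = 0, n_samples = 80)
  sim <- simulate_dataset(cfg)
  lg_iso <- log2(sim$iso_counts + 1)
  lg_tx <- log2(sim$mrna_counts + 1)
  bg <- sim$background_ids
  rho <- spearman_matrix(lg_iso, lg_tx[bg, , drop = FALSE])$rho
  rho <- rho[!is.na(rho)]
  expect_gt(length(rho), 400)
  expect_lt(abs(mean(rho)), 0.05)
})

test_that("planted repression is detectable: rho < -0.3 for almost all planted pairs", {
  cfg <- simulation_config(n_transcripts = 80, n_isomirs = 4, n_active = 2,
                           targets_per_isomir = 15, n_samples = 200,
                           groups = "g1", beta = -1, seed = 202)
  sim <- simulate_dataset(cfg)
  lg_iso <- log2(sim$iso_counts + 1)
  lg_tx <- log2(sim$mrna_counts + 1)
  hits <- mapply(function(iso, tid) {
    spearman(lg_iso[iso, ], lg_tx[tid, ])$rho < -0.3
  }, sim$truth_pairs$isomir[sim$truth_pairs$role == "true_target"],
     sim$truth_pairs$transcript_id[sim$truth_pairs$role == "true_target"])
  expect_gt(mean(hits), 0.95)
})

test_that("confounding inflates the background ITA", {
  run_bg <- function(gamma, seed) {
    cfg <- small_cfg(gamma = gamma, n_samples = 100, seed = seed)
    sim <- simulate_dataset(cfg)
    prof <- compute_ita_profile(
      log2(sim$iso_counts + 1), log2(sim$mrna_counts + 1),
      sim$sample_groups, sim$interactions, sim$nontargets
    )
    conf <- sim$confounded_isomirs
    if (length(conf) > 0) {
      mean(prof$ita$background_ita[prof$ita$isomir %in% conf])
    } else {
      mean(prof$ita$background_ita)
    }
  }
  bg_conf <- vapply(301:303, function(s) run_bg(0.3, s), numeric(1))
  bg_null <- vapply(301:303, function(s) run_bg(0, s), numeric(1))
  expect_gt(mean(bg_conf), mean(bg_null))
  expect_gt(mean(bg_conf), 0)
})

test_that("fixture bundles round-trip through the pipeline deterministically", {
  cfg <- small_cfg()
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg)
  write_fixture_bundle(cfg, d, sim = sim)
  out1 <- file.path(d, "o1")
  out2 <- file.path(d, "o2")
  suppressMessages({
    res1 <- run_pipeline(bundle_config(d, outdir = out1))
    res2 <- run_pipeline(bundle_config(d, outdir = out2))
  })
  expect_identical(readLines(res1$files$ita), readLines(res2$files$ita))
  # the ground-truth file is test-only: removing it changes nothing
  unlink(file.path(d, "ground_truth.tsv"))
  out3 <- file.path(d, "o3")
  suppressMessages(res3 <- run_pipeline(bundle_config(d, outdir = out3)))
  expect_identical(readLines(res1$files$ita), readLines(res3$files$ita))
})
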