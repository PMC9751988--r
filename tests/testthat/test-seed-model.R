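test_that("isomiR identifiers round-trip through parse and format", {
  ids <- c("hsa-miR-192-5p|+1", "hsa-miR-192-5p|0", "hsa-let-7a-5p|-2")
  p <- parse_isomir_id(ids)
  expect_identical(p$shift, c(1L, 0L, -2L))
  expect_identical(format_isomir_id(p$mirna_name, p$shift), ids)
  # 3'-variant suffix is tolerated and stripped
  expect_identical(parse_isomir_id("hsa-miR-21-5p|+3|3p-ACA")$isomir,
                   "hsa-miR-21-5p|+3")
  expect_error(parse_isomir_id("hsa-miR-21-5p"), "malformed")
  expect_error(format_isomir_id("bad|name", 0), "must not contain")
})

test_that("seed extraction takes positions 2-7 (2-8 extended) of the shifted 5' end", {
  expect_identical(extract_seed("UAGCUUAUCAGACUGAUGUUGA"), "AGCUUA")
  expect_identical(extract_seed("UAGCUUAUCAGACUGAUGUUGA", extended = TRUE),
                   "AGCUUAU")
  # DNA input is transcribed at parse time
  expect_identical(extract_seed("TAGCTTATCAGACTGATGTTGA"), "AGCUUA")
  expect_error(extract_seed("UAGCUUA"), "shorter than 8")
  expect_error(extract_seed("UAGCNUAUCA"), "non-RNA")
})

test_that("seed-site k-mers follow antiparallel pairing with optional wobbles", {
  expect_identical(seed_site_kmers("AGCUUA"), "UAAGCU")
  # miRNA A admits only U: no wobble variants for a poly-A seed
  expect_identical(seed_site_kmers("AAAAAA", allow_wobble = TRUE), "UUUUUU")

  # brute force over all 4^6 mRNA 6-mers using the integer-coded oracle
  pool <- all_kmers(6)
  brute <- function(seed, wobble) {
    sd <- rna_codes(seed)
    keep <- vapply(pool, function(m) {
      mc <- rna_codes(m)
      all(vapply(1:6, function(k) {
        sm <- mc[k] + sd[7 - k]
        sm == 5L || (wobble && sm == 7L)
      }, logical(1)))
    }, logical(1))
    sort(pool[keep])
  }
  wob <- seed_site_kmers("AGCUUA", allow_wobble = TRUE)
  expect_length(wob, 8L)
  expect_true("UAAGCU" %in% wob)
  expect_identical(wob, brute("AGCUUA", TRUE))

  set.seed(11)
  for (i in 1:8) {
    seed <- rand_rna(6)
    got <- seed_site_kmers(seed, allow_wobble = TRUE)
    expect_identical(got, brute(seed, TRUE))
    n_gu <- sum(strsplit(seed, "")[[1]] %in% c("G", "U"))
    expect_length(got, 2^n_gu)
    expect_identical(seed_site_kmers(seed), brute(seed, FALSE))
  }
  expect_error(seed_site_kmers("AGCUU"), "6-mer")
  expect_error(seed_site_kmers("AGCUUN"), "non-RNA")
})

test_that("site classification honours the motif definitions and precedence", {
  iso <- "UAGCUUAUCAGACUGAUGUUGA" # seed 2-8 = AGCUUAU
  rc28 <- "AUAAGCU"               # reverse WC complement of positions 2-8
  expect_identical(classify_site(iso, paste0(rc28, "A")), "8mer")
  expect_identical(classify_site(iso, paste0(rc28, "C")), "7mer-m8")
  rc27 <- "UAAGCU"                # reverse WC complement of positions 2-7
  expect_identical(classify_site(iso, paste0("C", rc27, "A")), "7mer-A1")
  expect_identical(classify_site(iso, paste0("C", rc27, "G")), "6mer")
  # one G:U wobble in the core, position 8 unpaired, non-A opposite 1
  wob <- "UAGGCU"                 # A at seed position 3 replaced by G wobble partner... core pairs with one wobble
  expect_identical(classify_site(iso, paste0("C", wob, "G")), "other")
  # mRNA-side bulge: 9-nt window whose centre carries one extra nucleotide
  expect_identical(classify_site(iso, paste0("C", "UAA", "C", "GCU", "G")), "other")
  expect_identical(classify_site(iso, "GGGGGGGG"), "none")
  expect_error(classify_site(iso, "UAAGCU"), "8 nt")
})

test_that("classifier agrees with the direct-definition oracle on random windows", {
  set.seed(21)
  for (r in 1:3) {
    iso <- rand_rna(22)
    wins <- vapply(1:400, function(i) rand_rna(8), character(1))
    got <- classify_sites(iso, wins)
    want <- vapply(wins, oracle_classify, character(1), iso_seq = iso)
    expect_identical(got, unname(want))
  }
})

test_that("k-mer index records every window with 0-based positions", {
  tx <- make_transcripts(c("t1", "t2"), c("AAAAA", "AUGCAU"), c(0, 0), c(0, 0))
  idx <- build_kmer_index(tx, k = 6)
  expect_identical(nrow(idx$positions), 1L)
  expect_identical(idx$positions$kmer, "AUGCAU")
  expect_identical(idx$positions$start, 0L)
  expect_identical(idx$transcript_ids, c("t1", "t2"))

  set.seed(5)
  lens <- sample(50:200, 30, replace = TRUE)
  tx <- make_transcripts(sprintf("t%02d", 1:30),
                         vapply(lens, rand_rna, character(1)),
                         rep(0, 30), rep(0, 30))
  idx <- build_kmer_index(tx, k = 6)
  expect_identical(nrow(idx$positions), sum(lens - 5L))
  expect_error(build_kmer_index(tx, k = 0), "k must be")
})

test_that("non-target sets equal the brute-force sliding-window scan", {
  # a transcript that is the WC site padded with C runs is excluded;
  # a poly-C transcript can never carry a site
  seed6 <- "AGCUUA"
  iso <- paste0("U", seed6, "UCAGACUGAUGUUGA")
  tx <- make_transcripts(
    c("hit", "cfree"),
    c(paste0(strrep("C", 20), "UAAGCU", strrep("C", 20)), strrep("C", 50)),
    c(0, 0), c(0, 0)
  )
  idx <- build_kmer_index(tx)
  expect_identical(compose_nontarget_set(iso, idx), "cfree")

  set.seed(33)
  lens <- sample(80:160, 40, replace = TRUE)
  tx <- make_transcripts(sprintf("t%02d", 1:40),
                         vapply(lens, rand_rna, character(1)),
                         rep(0, 40), rep(0, 40))
  idx <- build_kmer_index(tx)
  for (i in 1:6) {
    iso <- rand_rna(22)
    want <- tx$transcript_id[vapply(tx$seq, oracle_is_nontarget,
                                    logical(1), iso_seq = iso)]
    expect_identical(compose_nontarget_set(iso, idx), sort(want))
  }
})

test_that("classical-site carriers are never members of the non-target set", {
  set.seed(44)
  lens <- sample(100:250, 60, replace = TRUE)
  tx <- make_transcripts(sprintf("t%02d", 1:60),
                         vapply(lens, rand_rna, character(1)),
                         round(lens * 0.2), round(lens * 0.7))
  idx <- build_kmer_index(tx)
  for (i in 1:10) {
    iso <- rand_rna(22)
    sites <- scan_target_sites("x|0", iso, tx, idx)
    carriers <- unique(sites$transcript_id[sites$seed_type %in%
                                             c("8mer", "7mer-m8", "7mer-A1", "6mer")])
    expect_length(intersect(carriers, compose_nontarget_set(iso, idx)), 0L)
  }
})

test_that("region assignment is half-open and keyed by the start position", {
  t <- list(utr5_end = 10L, cds_end = 100L, length = 150L)
  expect_identical(assign_region(t, 5), "5UTR")
  expect_identical(assign_region(t, 10), "CDS")   # boundary goes right
  expect_identical(assign_region(t, 99), "CDS")   # spanning site keeps start region
  expect_identical(assign_region(t, 100), "3UTR")
  expect_error(assign_region(t, 150), "out of range")
  expect_error(assign_region(t, -1), "out of range")
})

test_that("transcript construction validates the region partition", {
  expect_error(make_transcripts("t", "ACGU", 3, 2), "invalid region")
  expect_error(make_transcripts("t", "ACGU", 0, 5), "invalid region")
  tx <- make_transcripts("t", "acgu", 1, 3)
  expect_identical(tx$seq, "ACGU")
  expect_identical(tx$length, 4L)
})
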