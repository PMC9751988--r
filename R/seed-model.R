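# Seed model: seed extraction, wobble-aware seed-site k-mers, site
# classification, k-mer indexing and non-target set composition.
#
# Conventions: all coordinates are 0-based, half-open. An 8-nt mRNA site
# window is read 5'->3'; its 3'-most nucleotide opposes miRNA position 1,
# so window position 9 - j (1-based) opposes miRNA seed position j.

#' Extract the seed of an isomiR sequence
#'
#' The seed is nucleotides 2-7 of the isomiR's own 5' end (positions are
#' counted after any 5'-shift); the extended seed adds position 8.
#'
#' @param seq isomiR RNA sequence, 5'->3', at least 8 nt.
#' @param extended if `TRUE`, return positions 2-8 (7 nt) instead of 2-7.
#' @return seed string.
#' @examples
#' extract_seed("UAGCUUAUCAGACUGAUGUUGA")          # "AGCUUA"
#' extract_seed("UAGCUUAUCAGACUGAUGUUGA", TRUE)    # "AGCUUAU"
#' @export
extract_seed <- function(seq, extended = FALSE) {
  seq <- canonicalize_rna(seq, "isomiR sequence")
  if (any(nchar(seq) < 8L)) {
    .stop_invalid("isomiR sequence shorter than 8 nt: seed positions 1-8 must exist")
  }
  substr(seq, 2L, if (extended) 8L else 7L)
}

#' Enumerate mRNA 6-mers that bind a seed
#'
#' Returns every mRNA 6-mer (read 5'->3') that pairs antiparallel with the
#' 6-nt seed at all six positions. With `allow_wobble = FALSE` only
#' Watson-Crick pairs are admitted and the result is the single reverse
#' complement of the seed. With `allow_wobble = TRUE`, G:U wobble pairs are
#' admitted in both orientations (miRNA G opposite mRNA U, miRNA U opposite
#' mRNA G), so the set has size `2^(#G + #U)` over the seed.
#'
#' @param seed 6-nt RNA seed (isomiR positions 2-7).
#' @param allow_wobble admit G:U wobble pairs.
#' @return sorted character vector of 6-mers.
#' @examples
#' seed_site_kmers("AGCUUA")               # "UAAGCU"
#' length(seed_site_kmers("AGCUUA", TRUE)) # 8
#' @export
seed_site_kmers <- function(seed, allow_wobble = FALSE) {
  seed <- canonicalize_rna(seed, "seed")
  if (length(seed) != 1L || nchar(seed) != 6L) {
    .stop_invalid("seed must be a single 6-mer")
  }
  s <- strsplit(seed, "", fixed = TRUE)[[1]]
  # mRNA 6-mer position k (5'->3') opposes seed position 7 - k (1-based in
  # the seed string, i.e. isomiR position 8 - k).
  sets <- lapply(6:1, function(j) {
    if (allow_wobble) .ADMISSIBLE[[s[j]]] else .WC[[s[j]]]
  })
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # rev() so that column k of the grid is mRNA position k
  kmers <- do.call(paste0, rev(grid))
  sort(unique(kmers))
}

# TRUE where mRNA base m Watson-Crick pairs the miRNA base mi (scalars mi).
.pairs_wc <- function(mi, m) m == .WC[[mi]]

# TRUE where m pairs mi under WC or G:U wobble.
.pairs_relaxed <- function(mi, m) {
  ok <- m == .WC[[mi]]
  if (mi %in% names(.WOBBLE)) ok <- ok | m == .WOBBLE[[mi]]
  ok
}

#' Classify a seed-site window
#'
#' Classifies an mRNA site window against an isomiR's seed into one of the
#' four classical seed-site types, the relaxed non-classical type
#' (`"other"`), or `"none"`. The window is read 5'->3' and its 3'-most
#' nucleotide opposes isomiR position 1 (which is never required to pair;
#' only its identity as A matters).
#'
#' Classical types (checked in precedence order 8mer > 7mer-m8 > 7mer-A1 >
#' 6mer): 8mer = WC pairing of positions 2-8 plus target A opposite
#' position 1; 7mer-m8 = WC 2-8, non-A opposite 1; 7mer-A1 = WC 2-7 with
#' position 8 unpaired and A opposite 1; 6mer = WC 2-7 only. `"other"` =
#' positions 2-7 pair completely under the relaxed rule: any number of G:U
#' wobbles plus at most one of a mismatch or a single unpaired (bulged)
#' nucleotide on either strand. A miRNA-side bulge is evaluated by looping
#' out one seed position against the 5-nt mRNA core (window positions 3-7);
#' an mRNA-side bulge requires a 9-nt window, in which one of the seven
#' central nucleotides is looped out.
#'
#' @param seq isomiR RNA sequence (>= 8 nt); only positions 2-8 are used.
#' @param window 8-nt mRNA window (or 9-nt for the mRNA-bulge variant).
#' @return one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`, `"other"`,
#'   `"none"`.
#' @seealso [classify_sites()] for the vectorized form over many windows.
#' @export
classify_site <- function(seq, window) {
  window <- canonicalize_rna(window, "site window")
  if (length(window) != 1L) .stop_invalid("window must be a single string")
  if (nchar(window) == 9L) {
    return(.classify_mrna_bulge(seq, window))
  }
  if (nchar(window) != 8L) {
    .stop_invalid("site window must be 8 nt (9 nt for the mRNA-bulge variant)")
  }
  classify_sites(seq, window)
}

#' @param windows character vector of 8-nt windows.
#' @rdname classify_site
#' @export
classify_sites <- function(seq, windows) {
  seq <- canonicalize_rna(seq, "isomiR sequence")
  if (nchar(seq) < 8L) .stop_invalid("isomiR sequence shorter than 8 nt")
  windows <- canonicalize_rna(windows, "site window")
  if (any(nchar(windows) != 8L)) {
    .stop_invalid("all site windows must be 8 nt")
  }
  n <- length(windows)
  if (n == 0L) return(character(0))
  s <- strsplit(substr(seq, 1L, 8L), "", fixed = TRUE)[[1]]
  W <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
              ncol = 8L, byrow = TRUE)

  # WC pairing flags for seed positions 2..8 (window column 9 - j).
  wc <- vapply(2:8, function(j) .pairs_wc(s[j], W[, 9L - j]), logical(n))
  wc <- matrix(wc, nrow = n)          # columns: j = 2..8
  rel <- vapply(2:7, function(j) .pairs_relaxed(s[j], W[, 9L - j]), logical(n))
  rel <- matrix(rel, nrow = n)        # columns: j = 2..7

  wc27 <- rowSums(wc[, 1:6, drop = FALSE]) == 6L
  wc28 <- wc27 & wc[, 7]
  a1 <- W[, 8] == "A"

  type <- rep("none", n)
  type[wc28 & a1] <- "8mer"
  type[wc28 & !a1] <- "7mer-m8"
  idx7 <- !wc28 & wc27
  type[idx7 & a1] <- "7mer-A1"
  type[idx7 & !a1] <- "6mer"

  open <- type == "none"
  if (any(open)) {
    # wobbles plus at most one mismatch across positions 2-7
    n_fail <- 6L - rowSums(rel)
    ok <- n_fail <= 1L
    # miRNA-side bulge: loop out seed position j, pair the remaining five
    # seed nucleotides against the 5-nt mRNA core (window positions 3-7).
    bulge <- rep(FALSE, n)
    for (j in 2:7) {
      pp <- setdiff(2:7, j)
      okj <- rep(TRUE, n)
      for (k in 1:5) {
        okj <- okj & .pairs_relaxed(s[pp[k]], W[, 8L - k])
      }
      bulge <- bulge | okj
    }
    type[open & (ok | bulge)] <- "other"
  }
  type
}

# mRNA-side bulge on a 9-nt window: one of the seven central nucleotides
# (window positions 2-8) is looped out; the remaining six must pair the
# seed 2-7 under the relaxed (WC + wobble) rule.
.classify_mrna_bulge <- function(seq, window9) {
  seq <- canonicalize_rna(seq, "isomiR sequence")
  if (nchar(seq) < 8L) .stop_invalid("isomiR sequence shorter than 8 nt")
  s <- strsplit(substr(seq, 1L, 8L), "", fixed = TRUE)[[1]]
  w <- strsplit(window9, "", fixed = TRUE)[[1]]
  m7 <- w[2:8]
  for (k in 1:7) {
    m6 <- m7[-k]
    ok <- TRUE
    for (j in 2:7) {
      if (!.pairs_relaxed(s[j], m6[8L - j])) {
        ok <- FALSE
        break
      }
    }
    if (ok) return("other")
  }
  "none"
}

#' Build a k-mer position index over transcript sequences
#'
#' Maps every k-mer occurring in any transcript to its (transcript, 0-based
#' start) occurrences, the hash-table device used to compose non-target
#' sets efficiently.
#'
#' @param transcripts data frame with columns `transcript_id` and `seq`
#'   (RNA, 5'->3'), e.g. from [make_transcripts()].
#' @param k k-mer length (default 6, the seed-site length).
#' @return an object of class `kmer_index` with elements `k`, `positions`
#'   (data frame `kmer`, `transcript_id`, `start`), `by_kmer` (named list of
#'   row indices into `positions`) and `transcript_ids` (all indexed ids,
#'   including transcripts shorter than `k`).
#' @export
build_kmer_index <- function(transcripts, k = 6L) {
  k <- as.integer(k)
  if (k < 1L) .stop_invalid("k must be >= 1")
  if (nrow(transcripts) == 0L) .stop_invalid("transcripts must be non-empty")
  seqs <- canonicalize_rna(transcripts$seq, "transcript sequence")
  ids <- transcripts$transcript_id
  if (anyDuplicated(ids)) .stop_invalid("duplicated transcript ids")
  lens <- nchar(seqs)
  per <- lapply(seq_along(ids), function(i) {
    L <- lens[i]
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.frame(
      kmer = substring(seqs[i], starts, starts + k - 1L),
      transcript_id = ids[i],
      start = starts - 1L,
      stringsAsFactors = FALSE
    )
  })
  positions <- do.call(rbind, per)
  if (is.null(positions)) {
    positions <- data.frame(kmer = character(0), transcript_id = character(0),
                            start = integer(0), stringsAsFactors = FALSE)
  }
  structure(
    list(
      k = k,
      positions = positions,
      by_kmer = split(seq_len(nrow(positions)), positions$kmer),
      transcript_ids = ids
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "kmer_index: k = %d, %d transcripts, %d indexed positions, %d distinct k-mers\n",
    x$k, length(x$transcript_ids), nrow(x$positions), length(x$by_kmer)
  ))
  invisible(x)
}

#' Compose the non-target transcript set of an isomiR
#'
#' Non-targets are the negative-control transcripts that contain no
#' wobble-tolerant 6-mer seed-binding site anywhere in their sequence: a
#' transcript is a non-target of an isomiR iff none of
#' `seed_site_kmers(extract_seed(seq), allow_wobble = TRUE)` occurs in it.
#' The scan covers the full transcript (all regions).
#'
#' @param seq isomiR RNA sequence (>= 8 nt); the 6-nt seed is taken from
#'   positions 2-7 of the isomiR itself.
#' @param index a [build_kmer_index()] object with `k = 6` over full
#'   transcript sequences.
#' @return sorted character vector of non-target transcript ids.
#' @export
compose_nontarget_set <- function(seq, index) {
  if (!inherits(index, "kmer_index") || index$k != 6L) {
    .stop_invalid("index must be a kmer_index with k = 6")
  }
  if (nrow(index$positions) == 0L) {
    warning("empty k-mer index: non-target set is empty", call. = FALSE)
    return(character(0))
  }
  kmers <- seed_site_kmers(extract_seed(seq), allow_wobble = TRUE)
  rows <- unlist(index$by_kmer[kmers], use.names = FALSE)
  hit <- unique(index$positions$transcript_id[rows])
  sort(setdiff(index$transcript_ids, hit))
}

#' Construct a validated transcript table
#'
#' A transcript is its id, RNA sequence (5'->3') and the half-open region
#' boundaries: 5'-UTR = `[0, utr5_end)`, CDS = `[utr5_end, cds_end)`,
#' 3'-UTR = `[cds_end, length)`. The three regions partition the sequence.
#'
#' @param transcript_id character vector of unique ids.
#' @param seq RNA sequences (DNA `T` transcribed to `U`).
#' @param utr5_end,cds_end 0-based half-open boundaries with
#'   `0 <= utr5_end <= cds_end <= nchar(seq)`.
#' @return data frame with columns `transcript_id`, `seq`, `utr5_end`,
#'   `cds_end`, `length`.
#' @export
make_transcripts <- function(transcript_id, seq, utr5_end, cds_end) {
  seq <- canonicalize_rna(seq, "transcript sequence")
  utr5_end <- as.integer(utr5_end)
  cds_end <- as.integer(cds_end)
  len <- nchar(seq)
  if (anyDuplicated(transcript_id)) .stop_invalid("duplicated transcript ids")
  bad <- utr5_end < 0L | utr5_end > cds_end | cds_end > len
  if (any(bad)) {
    .stop_invalid(
      "invalid region boundaries for transcript(s): ",
      paste(utils::head(transcript_id[bad], 5L), collapse = ", ")
    )
  }
  data.frame(
    transcript_id = transcript_id, seq = seq,
    utr5_end = utr5_end, cds_end = cds_end, length = len,
    stringsAsFactors = FALSE
  )
}

#' Read transcript sequences and region boundaries
#'
#' `read_transcripts_fasta()` reads a FASTA file (id = first
#' whitespace-delimited token of the header); `read_region_table()` reads a
#' TSV with columns `transcript_id`, `utr5_end`, `cds_end` (0-based,
#' half-open). `read_transcripts()` joins the two into a validated
#' transcript table; transcripts missing from the region table get
#' `utr5_end = cds_end = 0` (entire sequence treated as 3'-UTR) with a
#' message.
#'
#' @param fasta,path file paths.
#' @return see [make_transcripts()].
#' @export
read_transcripts_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- NULL
  data.frame(transcript_id = ids, seq = canonicalize_rna(seqs, "transcript sequence"),
             stringsAsFactors = FALSE)
}

#' @rdname read_transcripts_fasta
#' @export
read_region_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "utr5_end", "cds_end")
  if (!all(need %in% names(df))) {
    .stop_invalid("region table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' @param regions region table (data frame), or a path to one.
#' @rdname read_transcripts_fasta
#' @export
read_transcripts <- function(fasta, regions) {
  seqs <- read_transcripts_fasta(fasta)
  if (is.character(regions)) regions <- read_region_table(regions)
  i <- match(seqs$transcript_id, regions$transcript_id)
  if (anyNA(i)) {
    message(sum(is.na(i)), " transcript(s) missing from the region table; ",
            "treating the full sequence as 3'-UTR")
  }
  utr5 <- ifelse(is.na(i), 0L, regions$utr5_end[i])
  cds <- ifelse(is.na(i), 0L, regions$cds_end[i])
  make_transcripts(seqs$transcript_id, seqs$seq, utr5, cds)
}

#' Assign the mRNA region of a site position
#'
#' A site is keyed by its window's 5'-most (0-based) position; a site that
#' spans a region boundary takes the region of its start position, which
#' makes the assignment deterministic.
#'
#' @param transcript one row of a transcript table (list or data frame row)
#'   with `utr5_end`, `cds_end`, `length`.
#' @param window_start integer vector of 0-based window starts.
#' @return character vector over `"5UTR"`, `"CDS"`, `"3UTR"`.
#' @export
assign_region <- function(transcript, window_start) {
  window_start <- as.integer(window_start)
  len <- if (!is.null(transcript$length)) transcript$length else nchar(transcript$seq)
  if (any(window_start < 0L | window_start >= len)) {
    .stop_invalid("window_start out of range [0, transcript length)")
  }
  ifelse(window_start < transcript$utr5_end, "5UTR",
         ifelse(window_start < transcript$cds_end, "CDS", "3UTR"))
}

#' Scan transcripts for seed sites of an isomiR
#'
#' The package's internal sequence-based predictor: candidate positions are
#' taken from the wobble-admissible 6-mer occurrences in the k-mer index
#' (the 6-mer occupies window positions 2-7, opposite seed positions 7-2),
#' the surrounding 8-nt window is classified with [classify_sites()], and
#' sites classified `"none"` are dropped. It therefore reports all classical
#' sites and the wobble-bearing subset of `"other"` sites (mismatch- or
#' bulge-only sites have no admissible 6-mer core and are not scanned for).
#'
#' @param isomir isomiR identifier to record in the output.
#' @param seq isomiR RNA sequence.
#' @param transcripts transcript table ([make_transcripts()]).
#' @param index [build_kmer_index()] over `transcripts` with `k = 6`.
#' @return interaction table: data frame with columns `isomir`,
#'   `transcript_id`, `window_start`, `seed_type`, `region`, `source`
#'   (`"internal"`).
#' @export
scan_target_sites <- function(isomir, seq, transcripts, index) {
  if (!inherits(index, "kmer_index") || index$k != 6L) {
    .stop_invalid("index must be a kmer_index with k = 6")
  }
  kmers <- seed_site_kmers(extract_seed(seq), allow_wobble = TRUE)
  rows <- unlist(index$by_kmer[kmers], use.names = FALSE)
  empty <- data.frame(
    isomir = character(0), transcript_id = character(0),
    window_start = integer(0), seed_type = character(0),
    region = character(0), source = character(0), stringsAsFactors = FALSE
  )
  if (length(rows) == 0L) return(empty)
  hits <- index$positions[rows, , drop = FALSE]
  ti <- match(hits$transcript_id, transcripts$transcript_id)
  if (anyNA(ti)) .stop_invalid("index refers to transcripts absent from the table")
  len <- transcripts$length[ti]
  # the 6-mer core sits at window positions 2-7: window_start = core - 1
  ws <- hits$start - 1L
  keep <- ws >= 0L & ws + 8L <= len
  if (!any(keep)) return(empty)
  hits <- hits[keep, , drop = FALSE]
  ti <- ti[keep]
  ws <- ws[keep]
  windows <- substring(transcripts$seq[ti], ws + 1L, ws + 8L)
  type <- classify_sites(seq, windows)
  keep2 <- type != "none"
  if (!any(keep2)) return(empty)
  out <- data.frame(
    isomir = isomir,
    transcript_id = hits$transcript_id[keep2],
    window_start = ws[keep2],
    seed_type = type[keep2],
    region = ifelse(ws[keep2] < transcripts$utr5_end[ti[keep2]], "5UTR",
                    ifelse(ws[keep2] < transcripts$cds_end[ti[keep2]], "CDS", "3UTR")),
    source = "internal",
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(out[c("isomir", "transcript_id", "window_start")]), , drop = FALSE]
  out[order(out$transcript_id, out$window_start), , drop = FALSE]
}
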