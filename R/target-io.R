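# Reading, unifying and comparing predicted-interaction tables in the
# RNA22-like and TargetScan-like TSV dialects.
#
# Default dialect schemas (overridable through col_map):
#   RNA22-like:      isomir  transcript_id  window_start  seed_type  region
#                    (window_start 0-based; seed_type may be any of the five
#                    categories; region any of 5UTR/CDS/3UTR)
#   TargetScan-like: isomir  transcript_id  site_start  seed_type
#                    (site_start 1-based inclusive; classical seed types
#                    only; region is always 3UTR)

.SEED_PRECEDENCE <- c("8mer" = 1L, "7mer-m8" = 2L, "7mer-A1" = 3L,
                      "6mer" = 4L, "other" = 5L)

.validate_interactions <- function(tbl) {
  stopifnot(all(c("isomir", "transcript_id", "window_start", "seed_type",
                  "region", "source") %in% names(tbl)))
  bad <- !tbl$seed_type %in% .SEED_TYPES
  if (any(bad)) .stop_invalid("unknown seed_type: ", unique(tbl$seed_type[bad])[1])
  bad <- !tbl$region %in% .REGIONS
  if (any(bad)) .stop_invalid("unknown region: ", unique(tbl$region[bad])[1])
  tbl
}

# Shared reader core: rename mapped columns, drop transcripts without a
# sequence, optionally re-classify sites against the sequences.
.read_prediction_table <- function(path, col_map, source,
                                   transcripts = NULL, iso_seqs = NULL,
                                   one_based = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(unlist(col_map)), names(df))
  if (length(missing) > 0L) {
    .stop_invalid(
      source, " table ", path, " lacks column(s) ",
      paste(missing, collapse = ", "),
      "; expected schema: ", paste(unlist(col_map), collapse = ", ")
    )
  }
  out <- data.frame(
    isomir = parse_isomir_id(as.character(df[[col_map$isomir]]))$isomir,
    transcript_id = as.character(df[[col_map$transcript_id]]),
    window_start = as.integer(df[[col_map$window_start]]),
    seed_type = as.character(df[[col_map$seed_type]]),
    stringsAsFactors = FALSE
  )
  if (one_based) out$window_start <- out$window_start - 1L
  out$region <- if (!is.null(col_map$region)) {
    as.character(df[[col_map$region]])
  } else {
    rep("3UTR", nrow(out))
  }
  out$source <- rep(source, nrow(out))
  if (!is.null(transcripts)) {
    known <- out$transcript_id %in% transcripts$transcript_id
    if (any(!known)) {
      message(sum(!known), " ", source,
              " row(s) refer to transcripts absent from the sequence set; dropped")
      out <- out[known, , drop = FALSE]
    }
    if (!is.null(iso_seqs) && nrow(out) > 0L) {
      out <- .reclassify_sites(out, transcripts, iso_seqs, source)
    }
  }
  out <- out[!duplicated(out[c("isomir", "transcript_id", "window_start", "source")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  .validate_interactions(out)
}

# Re-derive seed_type (and region) from sequence when both the transcript
# and isomiR sequences are on hand; sites that classify as "none" are
# dropped with a message.
.reclassify_sites <- function(out, transcripts, iso_seqs, source) {
  ti <- match(out$transcript_id, transcripts$transcript_id)
  ii <- match(out$isomir, iso_seqs$isomir)
  if (anyNA(ii)) {
    message(sum(is.na(ii)), " ", source,
            " row(s) refer to isomiRs without a sequence; dropped")
    keep <- !is.na(ii)
    out <- out[keep, , drop = FALSE]
    ti <- ti[keep]
    ii <- ii[keep]
  }
  if (nrow(out) == 0L) return(out)
  len <- transcripts$length[ti]
  ok <- out$window_start >= 0L & out$window_start + 8L <= len
  if (any(!ok)) {
    message(sum(!ok), " ", source, " site(s) out of transcript bounds; dropped")
    out <- out[ok, , drop = FALSE]
    ti <- ti[ok]
    ii <- ii[ok]
  }
  if (nrow(out) == 0L) return(out)
  windows <- substring(transcripts$seq[ti], out$window_start + 1L,
                       out$window_start + 8L)
  type <- character(nrow(out))
  for (iso in unique(out$isomir)) {
    sel <- out$isomir == iso
    type[sel] <- classify_sites(iso_seqs$seq[match(iso, iso_seqs$isomir)],
                                windows[sel])
  }
  drop <- type == "none"
  if (any(drop)) {
    message(sum(drop), " ", source,
            " site(s) did not classify against the sequences; dropped")
  }
  out$seed_type <- type
  out$region <- assign_region_rows(transcripts, ti, out$window_start)
  out[!drop, , drop = FALSE]
}

# vectorized region lookup given row indices into the transcript table
assign_region_rows <- function(transcripts, ti, window_start) {
  ifelse(window_start < transcripts$utr5_end[ti], "5UTR",
         ifelse(window_start < transcripts$cds_end[ti], "CDS", "3UTR"))
}

#' Read an RNA22-like prediction table
#'
#' @param path TSV path.
#' @param transcripts optional transcript table ([make_transcripts()]);
#'   rows for transcripts absent from it are dropped with a logged count.
#' @param iso_seqs optional isomiR sequence table ([isomir_sequences()]);
#'   when both sequence sets are given, every site is re-classified with
#'   [classify_sites()] and its region re-derived.
#' @param col_map named list mapping the canonical fields (`isomir`,
#'   `transcript_id`, `window_start`, `seed_type`, and for RNA22 `region`)
#'   to the file's column names.
#' @return interaction table (data frame) with columns `isomir`,
#'   `transcript_id`, `window_start`, `seed_type`, `region`, `source`.
#' @export
read_rna22_table <- function(path, transcripts = NULL, iso_seqs = NULL,
                             col_map = list(isomir = "isomir",
                                            transcript_id = "transcript_id",
                                            window_start = "window_start",
                                            seed_type = "seed_type",
                                            region = "region")) {
  .read_prediction_table(path, col_map, "RNA22", transcripts, iso_seqs)
}

#' Read a TargetScan-like prediction table
#'
#' The TargetScan dialect carries classical seed types only (a row claiming
#' `"other"` is an error), 1-based site coordinates (converted to 0-based
#' half-open on read), and 3'-UTR sites only (region is forced to
#' `"3UTR"`).
#'
#' @inheritParams read_rna22_table
#' @export
read_targetscan_table <- function(path, transcripts = NULL, iso_seqs = NULL,
                                  col_map = list(isomir = "isomir",
                                                 transcript_id = "transcript_id",
                                                 window_start = "site_start",
                                                 seed_type = "seed_type")) {
  col_map$region <- NULL
  out <- .read_prediction_table(path, col_map, "TargetScan",
                                transcripts = NULL, one_based = TRUE)
  if (any(!out$seed_type %in% .CLASSICAL_TYPES)) {
    .stop_invalid("TargetScan dialect admits classical seed types only")
  }
  out$region <- rep("3UTR", nrow(out))
  if (!is.null(transcripts)) {
    known <- out$transcript_id %in% transcripts$transcript_id
    if (any(!known)) {
      message(sum(!known),
              " TargetScan row(s) refer to transcripts absent from the sequence set; dropped")
      out <- out[known, , drop = FALSE]
    }
    if (!is.null(iso_seqs) && nrow(out) > 0L) {
      out <- .reclassify_sites(out, transcripts, iso_seqs, "TargetScan")
    }
  }
  rownames(out) <- NULL
  .validate_interactions(out)
}

#' Write interaction tables in either dialect
#'
#' `write_rna22_table()` writes 0-based coordinates with a region column;
#' `write_targetscan_table()` writes 1-based coordinates without one.
#' Both round-trip losslessly through the corresponding reader.
#'
#' @param tbl interaction table.
#' @param path output TSV path.
#' @export
write_rna22_table <- function(tbl, path) {
  utils::write.table(
    tbl[c("isomir", "transcript_id", "window_start", "seed_type", "region")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_rna22_table
#' @export
write_targetscan_table <- function(tbl, path) {
  out <- data.frame(
    isomir = tbl$isomir, transcript_id = tbl$transcript_id,
    site_start = tbl$window_start + 1L, seed_type = tbl$seed_type,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Union of interaction tables
#'
#' Site-level union: all site rows from both tables are retained (for
#' stratified analyses), with exact duplicates on the key (`isomir`,
#' `transcript_id`, `window_start`, `source`) removed. Pair-level views are
#' obtained with [interaction_pairs()].
#'
#' @param a,b interaction tables over the same transcript universe.
#' @return interaction table.
#' @export
union_interactions <- function(a, b) {
  out <- rbind(.validate_interactions(a), .validate_interactions(b))
  out <- out[!duplicated(out[c("isomir", "transcript_id", "window_start", "source")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair-level view of an interaction table
#'
#' Collapses site rows to unique (isomiR, transcript) pairs. Each pair is
#' labelled with its maximum-precedence seed type (8mer > 7mer-m8 >
#' 7mer-A1 > 6mer > other) for pair-level summaries.
#'
#' @param tbl interaction table.
#' @return data frame `isomir`, `transcript_id`, `seed_type`.
#' @export
interaction_pairs <- function(tbl) {
  if (nrow(tbl) == 0L) {
    return(data.frame(isomir = character(0), transcript_id = character(0),
                      seed_type = character(0), stringsAsFactors = FALSE))
  }
  prec <- .SEED_PRECEDENCE[tbl$seed_type]
  ord <- order(tbl$isomir, tbl$transcript_id, prec)
  tbl <- tbl[ord, , drop = FALSE]
  keep <- !duplicated(tbl[c("isomir", "transcript_id")])
  out <- tbl[keep, c("isomir", "transcript_id", "seed_type"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare sets: intersections and Jaccard indices
#'
#' For up to four named sets, reports every exclusive intersection-region
#' size (Venn-style) and all pairwise Jaccard indices
#' `|A intersect B| / |A union B|`. A pair of empty sets has Jaccard 0 (with
#' a warning).
#'
#' @param sets named list of 2-4 character vectors (de-duplicated).
#' @return list with `jaccard` (data frame `set_a`, `set_b`,
#'   `intersection`, `union`, `jaccard`) and `regions` (data frame
#'   `membership`, `size`, one row per non-empty combination of sets).
#' @examples
#' compare_sets(list(a = letters[1:10], b = letters[6:12]))
#' @export
compare_sets <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    .stop_invalid("sets must be named")
  }
  if (length(sets) < 2L || length(sets) > 4L) {
    .stop_invalid("compare_sets handles 2 to 4 sets")
  }
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2L)
  jac <- apply(pairs, 2L, function(p) {
    a <- sets[[p[1]]]
    b <- sets[[p[2]]]
    ni <- length(intersect(a, b))
    nu <- length(union(a, b))
    if (nu == 0L) {
      warning("Jaccard of two empty sets defined as 0", call. = FALSE)
      j <- 0
    } else {
      j <- ni / nu
    }
    c(intersection = ni, union = nu, jaccard = j)
  })
  jaccard <- data.frame(
    set_a = pairs[1, ], set_b = pairs[2, ],
    intersection = as.integer(jac["intersection", ]),
    union = as.integer(jac["union", ]),
    jaccard = jac["jaccard", ], stringsAsFactors = FALSE
  )
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  regions <- data.frame(
    membership = apply(combos, 1L, function(z) paste(nm[unlist(z)], collapse = "&")),
    size = apply(combos, 1L, function(z) {
      z <- unlist(z)
      if (length(universe) == 0L) return(0L)
      sum(rowSums(member[, z, drop = FALSE]) == sum(z) &
            rowSums(member[, !z, drop = FALSE]) == 0L)
    }),
    stringsAsFactors = FALSE
  )
  rownames(regions) <- NULL
  list(jaccard = jaccard, regions = regions)
}
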