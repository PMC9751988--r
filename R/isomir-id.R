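#' Parse and format 5'-isomiR identifiers
#'
#' A 5'-isomiR is identified as `"<mirna_name>|<shift>"`, where the shift is
#' the offset of the isomiR's 5' end from the canonical 5' end in the 5'->3'
#' direction: positive shifts trim canonical 5' nucleotides (rendered with an
#' explicit `+`, e.g. `"hsa-miR-192-5p|+1"`), negative shifts add templated
#' nucleotides, and the canonical form carries `"|0"`. Identifiers may carry
#' a trailing 3'-variant token (`"name|shift|<variant>"`), which is ignored
#' by the parser and used only by [aggregate_5prime_isomirs()].
#'
#' @param x character vector of identifiers.
#' @return `parse_isomir_id()` returns a data frame with columns
#'   `mirna_name`, `shift` (integer) and `isomir` (the canonical rendered
#'   id). `format_isomir_id()` returns a character vector.
#' @examples
#' parse_isomir_id("hsa-miR-192-5p|+1")
#' format_isomir_id("hsa-miR-192-5p", c(-2, 0, 1))
#' @export
parse_isomir_id <- function(x) {
  m <- regmatches(x, regexec("^([^|]+)\\|([+-]?[0-9]+)(\\|.*)?$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    .stop_invalid(
      "malformed isomiR identifier(s): ",
      paste(utils::head(x[bad], 5L), collapse = ", "),
      " (expected \"<mirna_name>|<signed shift>\")"
    )
  }
  name <- vapply(m, `[`, character(1), 2L)
  shift <- as.integer(vapply(m, `[`, character(1), 3L))
  data.frame(
    mirna_name = name,
    shift = shift,
    isomir = format_isomir_id(name, shift),
    stringsAsFactors = FALSE
  )
}

#' @param mirna_name character vector of miRNA names (no `|` characters).
#' @param shift integer vector of 5'-end shifts.
#' @rdname parse_isomir_id
#' @export
format_isomir_id <- function(mirna_name, shift) {
  if (any(grepl("|", mirna_name, fixed = TRUE))) {
    .stop_invalid("mirna_name must not contain '|'")
  }
  shift <- as.integer(shift)
  if (length(shift) == 0L || length(mirna_name) == 0L) return(character(0))
  tag <- ifelse(shift > 0L, paste0("+", shift), as.character(shift))
  paste0(mirna_name, "|", tag)
}

# Upper-case, transcribe DNA (T) to RNA (U), and validate the alphabet.
canonicalize_rna <- function(x, what = "sequence") {
  x <- chartr("t", "u", x)
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    .stop_invalid(
      "non-RNA character(s) in ", what, ": ",
      paste(utils::head(x[bad], 3L), collapse = ", ")
    )
  }
  x
}

#' Construct an isomiR sequence table
#'
#' Binds isomiR identifiers to their 5'->3' RNA sequences (after any 5'
#' shift, so position 1 of `seq` is the isomiR's own first nucleotide).
#' Sequences are canonicalized to upper-case RNA; each must be at least
#' 8 nt so that seed positions 2-8 exist.
#'
#' @param isomir character vector of `"name|shift"` identifiers.
#' @param seq character vector of RNA sequences (DNA `T` is transcribed).
#' @return data frame with columns `isomir`, `seq`.
#' @export
isomir_sequences <- function(isomir, seq) {
  ids <- parse_isomir_id(isomir)
  seq <- canonicalize_rna(seq, "isomiR sequence")
  if (any(nchar(seq) < 8L)) {
    .stop_invalid("isomiR sequences must be at least 8 nt (seed positions 1-8)")
  }
  if (anyDuplicated(ids$isomir)) {
    .stop_invalid("duplicated isomiR identifiers")
  }
  data.frame(isomir = ids$isomir, seq = seq, stringsAsFactors = FALSE)
}
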