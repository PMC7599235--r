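#' Pair of equal-length protein sequences
#'
#' @param id_a,id_b Sequence identifiers.
#' @param seq_a,seq_b One-letter amino-acid strings of equal length
#'   (case-insensitive; stored uppercase).
#' @return Object of class `sequence_pair`.
#' @export
sequence_pair <- function(id_a, seq_a, id_b, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("unequal lengths")
  structure(list(id_a = id_a, id_b = id_b, seq_a = seq_a, seq_b = seq_b),
            class = "sequence_pair")
}

#' Read a sequence pair from one or two FASTA files
#'
#' @param fasta_a Path to a FASTA file holding the first sequence.
#' @param fasta_b Path for the second sequence; if `NULL`, both records
#'   are taken from `fasta_a`.
#' @return A [sequence_pair()].
#' @export
read_sequence_pair <- function(fasta_a, fasta_b = NULL) {
  recs <- seqinr::read.fasta(fasta_a, seqtype = "AA", as.string = TRUE)
  if (is.null(fasta_b)) {
    if (length(recs) < 2) stop("need two FASTA records")
    a <- recs[[1]]; b <- recs[[2]]
    ids <- names(recs)[1:2]
  } else {
    recs_b <- seqinr::read.fasta(fasta_b, seqtype = "AA", as.string = TRUE)
    a <- recs[[1]]; b <- recs_b[[1]]
    ids <- c(names(recs)[1], names(recs_b)[1])
  }
  sequence_pair(ids[1], as.character(a), ids[2], as.character(b))
}

#' Identify variable positions between two equal-length sequences
#'
#' Position-by-position comparison (no alignment); 'X' counts as a
#' difference from any other letter and is reported with a message.
#'
#' @param pair A [sequence_pair()].
#' @return Object of class `variant_report`: a data.frame with columns
#'   `position` (1-based, ascending), `aa_a`, `aa_b`.
#' @examples
#' p <- sequence_pair("s1", "ACDEF", "s2", "ACDKF")
#' variable_positions(p)  # position 4, E -> K
#' @export
variable_positions <- function(pair) {
  stopifnot(inherits(pair, "sequence_pair"))
  a <- strsplit(pair$seq_a, "")[[1]]
  b <- strsplit(pair$seq_b, "")[[1]]
  if (length(a) != length(b)) stop("unequal lengths")
  diff <- which(a != b)
  n_x <- sum(a[diff] == "X" | b[diff] == "X")
  if (n_x > 0) message(n_x, " variable positions involve 'X'")
  variant_report(data.frame(position = diff, aa_a = a[diff], aa_b = b[diff],
                            stringsAsFactors = FALSE))
}

#' Construct a variant report
#' @param df data.frame with `position`, `aa_a`, `aa_b`.
#' @return `variant_report` object.
#' @export
variant_report <- function(df) {
  stopifnot(all(c("position", "aa_a", "aa_b") %in% names(df)))
  df <- df[order(df$position), , drop = FALSE]
  if (any(duplicated(df$position))) stop("duplicate positions")
  if (any(df$aa_a == df$aa_b)) stop("listed positions must differ")
  rownames(df) <- NULL
  class(df) <- c("variant_report", "data.frame")
  df
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("<variant_report> %d variable position(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Trim a sequence to an inclusive 1-based segment
#'
#' Original numbering is retained as metadata so that downstream position
#' reports stay on full-length coordinates.
#'
#' @param seq Character scalar (sequence) or `sequence_pair`.
#' @param start,end 1-based inclusive bounds.
#' @return For a string: a string of length `end - start + 1` with
#'   attribute `positions` (original numbering). For a pair: a trimmed
#'   `sequence_pair` whose sequences carry the same attribute.
#' @export
trim_segment <- function(seq, start, end) {
  if (inherits(seq, "sequence_pair")) {
    a <- trim_segment(seq$seq_a, start, end)
    b <- trim_segment(seq$seq_b, start, end)
    out <- sequence_pair(seq$id_a, a, seq$id_b, b)
    attr(out, "positions") <- attr(a, "positions")
    return(out)
  }
  n <- nchar(seq)
  if (!(start >= 1 && start <= end && end <= n)) stop("bounds out of range")
  out <- substr(seq, start, end)
  attr(out, "positions") <- start:end
  out
}

#' Restrict a variant report to interface positions
#'
#' @param report A [variant_report()].
#' @param interface_positions Integer set of 1-based positions (typically
#'   from [interface_positions()] on a reference structure).
#' @return The sub-report restricted to those positions.
#' @export
near_interface_subset <- function(report, interface_positions) {
  stopifnot(inherits(report, "variant_report"))
  sub <- report[report$position %in% interface_positions, , drop = FALSE]
  rownames(sub) <- NULL
  class(sub) <- c("variant_report", "data.frame")
  sub
}

#' Write a variant report as TSV and/or JSON
#'
#' @param report A [variant_report()].
#' @param tsv,json Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_variant_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    write.table(as.data.frame(report), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(n = nrow(report), positions = report$position,
           substitutions = as.data.frame(report)),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
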