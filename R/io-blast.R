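#' Read 12-column blast-tabular alignments ("blast8" / outfmt 6)
#'
#' The tab-separated columns are: query id, subject id, percent identity,
#' alignment length, mismatches, gap openings, query start, query end,
#' subject start, subject end, e-value, bit score. Query coordinates are
#' 1-based inclusive with start <= end; subject start > subject end denotes
#' an antisense (reverse-strand) match, flagged in the `sense` column.
#'
#' @param path tab-separated alignment file.
#' @return `alignment_hits` data.table, one row per hit, in file order, with
#'   columns `query_id, subject_id, pct_identity, aln_len, mismatches,
#'   gap_openings, q_start, q_end, s_start, s_end, evalue, bit_score, sense`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop(sprintf("blast tabular line %d: expected 12 columns, found %d",
                 bad[1], lengths(fields)[bad[1]]))
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop(sprintf("blast tabular line %d: non-numeric %s '%s'",
                   which(is.na(v))[1], what, m[which(is.na(v))[1], j]))
    v
  }
  hits <- data.table(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3, "identity"),
    aln_len = as.integer(num(4, "length")),
    mismatches = as.integer(num(5, "mismatches")),
    gap_openings = as.integer(num(6, "gap openings")),
    q_start = as.integer(num(7, "coordinate")),
    q_end = as.integer(num(8, "coordinate")),
    s_start = as.integer(num(9, "coordinate")),
    s_end = as.integer(num(10, "coordinate")),
    evalue = num(11, "e-value"),
    bit_score = num(12, "bit score"))
  validate_hits(hits)
}

#' @rdname read_blast_tab
#' @export
parse_blast_tab <- read_blast_tab

#' Write alignments in 12-column blast-tabular format
#' @param hits `alignment_hits` table.
#' @param path output path.
#' @export
write_blast_tab <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_len, hits$mismatches, hits$gap_openings,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   fmt_num(hits$evalue), fmt_num(hits$bit_score))
  writeLines(lines, path)
  invisible(path)
}

empty_hits <- function() {
  h <- data.table(query_id = character(), subject_id = character(),
                  pct_identity = numeric(), aln_len = integer(),
                  mismatches = integer(), gap_openings = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), bit_score = numeric(), sense = logical())
  setattr(h, "class", c("alignment_hits", class(h)))
  h[]
}

validate_hits <- function(hits) {
  if (any(hits$q_start > hits$q_end))
    stop("invalid hit: q_start > q_end at row ",
         which(hits$q_start > hits$q_end)[1])
  if (any(hits$q_start < 1))
    stop("invalid hit: q_start < 1 at row ", which(hits$q_start < 1)[1])
  if (any(hits$evalue < 0))
    stop("invalid hit: negative e-value at row ", which(hits$evalue < 0)[1])
  hits[, sense := s_start <= s_end]
  if (!inherits(hits, "alignment_hits"))
    setattr(hits, "class", c("alignment_hits", class(hits)))
  hits[]
}
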