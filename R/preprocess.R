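#' Trim 3' adapter (linker) sequences
#'
#' Removes the longest read suffix that matches a prefix of the adapter, with
#' a tolerance of one mismatch per 10 matched nucleotides (floor), provided
#' the match is at least `min_match` nt long. A full internal occurrence of
#' the adapter removes the adapter and everything 3' of it. `min_match = 0`
#' disables trimming (the "no linker trimming" mode). Qualities are trimmed
#' in step; the output is always a prefix of the input read.
#'
#' @param reads a [clash_reads] table.
#' @param adapter 3' adapter DNA sequence.
#' @param min_match minimum linker match length (default 4).
#' @return trimmed [clash_reads].
#' @export
trim_adapter_3p <- function(reads, adapter, min_match = 4L) {
  stopifnot(nzchar(adapter), min_match >= 0)
  if (nrow(reads) == 0 || min_match == 0) return(reads)
  keep <- cpp_trim_adapter(reads$seq, toupper(adapter), as.integer(min_match))
  out <- copy(reads)
  out[, seq := substr(seq, 1L, keep)]
  out[, qual := ifelse(is.na(qual), qual, substr(qual, 1L, keep))]
  out[]
}

#' Trim low-quality 3' ends
#'
#' BWA-style quality trimming: starting from the 3' end, the read is cut at
#' the position maximising the running sum of `(threshold - quality)`; with
#' `q_threshold = 0` the read is unchanged. Requires Phred+33 qualities.
#'
#' @param reads a [clash_reads] table with qualities.
#' @param q_threshold Phred quality threshold (default 30).
#' @return trimmed [clash_reads].
#' @export
quality_trim <- function(reads, q_threshold = 30L) {
  if (q_threshold == 0 || nrow(reads) == 0) return(reads)
  if (anyNA(reads$qual))
    stop("quality trimming requested but some reads have no qualities")
  keep <- vapply(reads$qual, function(q) {
    phred <- utf8ToInt(q) - 33L
    if (any(phred < 0 | phred > 60))
      stop("qualities outside the Phred+33 range; other encodings are not supported")
    s <- cumsum(q_threshold - rev(phred))
    if (max(s) <= 0) length(phred) else length(phred) - which.max(s)
  }, integer(1), USE.NAMES = FALSE)
  out <- copy(reads)
  out[, seq := substr(seq, 1L, keep)]
  out[, qual := substr(qual, 1L, keep)]
  out[]
}

#' Filter reads by minimum length
#' @param reads a [clash_reads] table.
#' @param min_len minimum insert length in nt (default 17).
#' @return the reads with `nchar(seq) >= min_len`.
#' @export
filter_length <- function(reads, min_len = 17L) {
  stopifnot(min_len >= 1)
  reads[nchar(seq) >= min_len]
}

#' Filter reads by minimum mean base quality
#'
#' Off by default in the standard pipeline (`min_mean_qual = 0`).
#' @param reads a [clash_reads] table.
#' @param min_mean_qual minimum mean Phred quality.
#' @export
filter_quality <- function(reads, min_mean_qual = 0) {
  if (min_mean_qual == 0 || nrow(reads) == 0) return(reads)
  if (anyNA(reads$qual)) stop("quality filtering requires qualities")
  mq <- vapply(reads$qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
               USE.NAMES = FALSE)
  reads[mq >= min_mean_qual]
}

#' Collapse identical reads (PCR-duplicate removal)
#'
#' Identical sequences are collapsed to a single record. Each collapsed
#' record keeps: `count` = number of reads collapsed, `n_barcodes` = number
#' of distinct random barcodes among them (absent when no reads carry
#' random tags), and `rank` = 1-based position after sorting by count
#' descending (ties broken lexicographically by sequence). Identifiers are
#' rewritten as `"K-L_M"` (with barcodes) or `"K_M"`.
#'
#' @param reads a [clash_reads] table.
#' @return collapsed [clash_reads] (FASTA-style: no qualities), ordered by rank.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0) return(clash_reads())
  # re-collapsing already-collapsed input: honour existing counts from ids
  w <- read_weight(reads$id)
  nb_id <- parse_collapsed_id(reads$id)$n_barcodes
  has_tags <- !all(is.na(reads$random_tag))
  agg <- reads[, .(count = sum(w[.I]),
                   n_barcodes = if (has_tags) uniqueN(random_tag[!is.na(random_tag)])
                                else if (!anyNA(nb_id[.I])) sum(nb_id[.I])
                                else NA_integer_),
               by = seq]
  # guard: rows that had no tag at all in a tagged library still get >= 1
  if (has_tags) agg[n_barcodes == 0L, n_barcodes := 1L]
  setorder(agg, -count, seq)
  agg[, rank := .I]
  out <- clash_reads(
    id = collapsed_id(agg$rank, agg$count, agg$n_barcodes),
    seq = agg$seq)
  out[, count := agg$count]
  out[, n_barcodes := agg$n_barcodes]
  out[, rank := agg$rank]
  out[]
}

#' Length-distribution report for raw vs collapsed reads
#'
#' The "check" task: tabulates read lengths before and after collapsing
#' (collapsed reads counted once per unique sequence).
#'
#' @param reads_raw,reads_collapsed [clash_reads] tables.
#' @return data.table with columns `length`, `n_raw`, `n_collapsed`.
#' @export
check_lengths <- function(reads_raw, reads_collapsed = collapse_reads(reads_raw)) {
  lens <- sort(unique(c(nchar(reads_raw$seq), nchar(reads_collapsed$seq))))
  data.table(
    length = as.integer(lens),
    n_raw = as.integer(tabulate2(nchar(reads_raw$seq), lens)),
    n_collapsed = as.integer(tabulate2(nchar(reads_collapsed$seq), lens)))
}

tabulate2 <- function(x, levels) {
  t <- table(factor(x, levels = levels))
  as.vector(t)
}

#' Run the full preprocessing stage
#'
#' Adapter trimming, optional quality trimming and filtering, length
#' filtering, and collapsing, with the standard defaults (`trim=30`,
#' `len=17`, `min=4`).
#'
#' @param reads a [clash_reads] table.
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @param trim Phred threshold for 3' quality trimming (0 disables; ignored
#'   for FASTA input).
#' @param len minimum read length.
#' @param min minimum linker match length (0 disables linker trimming).
#' @param filt minimum mean base quality (0 disables, the default).
#' @return list with elements `reads` (preprocessed, uncollapsed) and
#'   `collapsed`.
#' @export
preprocess_reads <- function(reads, adapter = NULL, trim = 30L, len = 17L,
                             min = 4L, filt = 0) {
  out <- reads
  if (!is.null(adapter) && min > 0)
    out <- trim_adapter_3p(out, adapter, min_match = min)
  if (trim > 0 && nrow(out) > 0 && !anyNA(out$qual))
    out <- quality_trim(out, q_threshold = trim)
  if (filt > 0) out <- filter_quality(out, filt)
  out <- filter_length(out, min_len = len)
  list(reads = out, collapsed = collapse_reads(out))
}
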