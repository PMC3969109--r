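#' Merge overlapping chimeras into interactions
#'
#' Chimeras of the same (ordered) transcript pair whose fragment-1 intervals
#' overlap by at least one nucleotide AND whose fragment-2 intervals overlap
#' by at least one nucleotide are merged transitively (similar to a bedtools
#' merge, but requiring the overlap in both fragments). Each resulting
#' interaction reports the merged (envelope) spans, the number of merged
#' chimeras, the total read support (sum of the collapse counts M parsed
#' from the read ids), the mean folding energy over folded members, and the
#' sorted supporting read ids. The result is independent of the input
#' order.
#'
#' @param calls a `hyb_calls` table (folded or not).
#' @return a `clash_interactions` data.table with columns `tx1, tx2,
#'   s1_start, s1_end, s2_start, s2_end, n_chimeras, n_reads, mean_dG,
#'   supporting_ids`.
#' @export
merge_interactions <- function(calls) {
  empty <- data.table(tx1 = character(), tx2 = character(),
                      s1_start = integer(), s1_end = integer(),
                      s2_start = integer(), s2_end = integer(),
                      n_chimeras = integer(), n_reads = integer(),
                      mean_dG = numeric(), supporting_ids = character())
  setattr(empty, "class", c("clash_interactions", class(empty)))
  x <- as.data.table(calls)
  if (nrow(x) == 0) return(empty[])
  # canonical order first so the merge is permutation-invariant
  setorder(x, tx1, tx2, s1_start, s1_end, s2_start, s2_end, read_id)
  x[, w := read_weight(read_id)]
  out <- x[, merge_one_pair(.SD), by = .(tx1, tx2)]
  setorder(out, tx1, tx2, s1_start, s2_start)
  setattr(out, "class", c("clash_interactions", class(out)))
  out[]
}

# single transcript pair: union-find over the both-fragment overlap relation
merge_one_pair <- function(d) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ov1 <- min(d$s1_end[i], d$s1_end[j]) - max(d$s1_start[i], d$s1_start[j]) + 1L
      ov2 <- min(d$s2_end[i], d$s2_end[j]) - max(d$s2_start[i], d$s2_start[j]) + 1L
      if (ov1 >= 1L && ov2 >= 1L) union_(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  d[, .(s1_start = min(s1_start), s1_end = max(s1_end),
        s2_start = min(s2_start), s2_end = max(s2_end),
        n_chimeras = .N, n_reads = sum(w),
        mean_dG = if (all(is.na(dG))) NA_real_ else mean(dG, na.rm = TRUE),
        supporting_ids = paste(sort(read_id), collapse = ",")),
    by = .(.comp = comp)][, .comp := NULL][]
}

#' Write merged interactions to a TSV file
#' @param interactions from [merge_interactions()].
#' @param path output path.
#' @export
write_interactions <- function(interactions, path) {
  fwrite(interactions, path, sep = "\t", na = ".")
  invisible(path)
}

#' miRNA seed match
#'
#' TRUE iff the reverse complement of miRNA positions 2-7 (the canonical
#' 6-mer seed) occurs in the target sequence.
#'
#' @param mirna_seq mature miRNA sequence (5'->3', DNA or RNA alphabet).
#' @param target_seq target (mRNA fragment) sequence.
#' @return logical.
#' @export
seed_match <- function(mirna_seq, target_seq) {
  mirna_seq <- chartr("Uu", "Tt", mirna_seq)
  target_seq <- chartr("Uu", "Tt", target_seq)
  if (nchar(mirna_seq) < 7) return(FALSE)
  site <- revcomp(substr(toupper(mirna_seq), 2, 7))
  grepl(site, toupper(target_seq), fixed = TRUE)
}

#' Quality-control statistics of a chimera set
#'
#' The three intrinsic indicators of call quality: (1) mean predicted
#' folding energy (more negative in true interactions), (2) fraction of
#' miRNA-mRNA chimeras whose target fragment carries a seed match for the
#' miRNA, (3) fraction of chimeras with zero gap/overlap between the two
#' fragments (exactly adjacent in the read).
#'
#' @param calls a `hyb_calls` table (folded for the energy statistic).
#' @param db the `transcript_db` (needed for the seed statistic).
#' @return one-row data.table: `n_chimeras, mean_dG, zero_gap_fraction,
#'   n_mim, seed_match_fraction`.
#' @export
interaction_qc <- function(calls, db = NULL) {
  x <- as.data.table(calls)
  if (nrow(x) == 0)
    return(data.table(n_chimeras = 0L, mean_dG = NA_real_,
                      zero_gap_fraction = NA_real_, n_mim = 0L,
                      seed_match_fraction = NA_real_))
  gap <- gap_or_overlap(x$q1_end, x$q2_start)
  mean_dG <- if (all(is.na(x$dG))) NA_real_ else mean(x$dG, na.rm = TRUE)
  n_mim <- 0L; smf <- NA_real_
  if (!is.null(db)) {
    bt1 <- db_biotype(db, x$tx1); bt2 <- db_biotype(db, x$tx2)
    mim <- which(!is.na(bt1) & !is.na(bt2) & is_mim_pair(bt1, bt2))
    n_mim <- length(mim)
    if (n_mim > 0) {
      hit <- vapply(mim, function(i) {
        mir_first <- bt1[i] == "microRNA"
        mir <- if (mir_first) db$seq[[x$tx1[i]]] else db$seq[[x$tx2[i]]]
        tgt <- if (mir_first)
          db_subseq(db, x$tx2[i], x$s2_start[i], x$s2_end[i])
        else db_subseq(db, x$tx1[i], x$s1_start[i], x$s1_end[i])
        seed_match(mir, tgt)
      }, logical(1))
      smf <- mean(hit)
    }
  }
  data.table(n_chimeras = nrow(x), mean_dG = mean_dG,
             zero_gap_fraction = mean(gap == 0L),
             n_mim = n_mim, seed_match_fraction = smf)
}
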