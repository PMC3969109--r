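#' Chimera-calling parameters
#'
#' @param hval e-value threshold for hybrid fragments (default 0.1).
#' @param hmax maximum number of mapped locations per fragment (default 10).
#' @param gmax maximum gap/overlap between the two fragments, nt (default 4).
#' @param pref `"none"` or `"mim"`: prioritise miRNA-mRNA chimeras among
#'   equal-score candidates.
#' @param type `"all"` or `"mim"`: restrict calls to miRNA-mRNA chimeras and
#'   enable bioinformatic extension of the fragments.
#' @param anti accept antisense fragments (set for genomic databases).
#' @return a `call_params` list.
#' @export
call_params <- function(hval = 0.1, hmax = 10L, gmax = 4L,
                        pref = c("none", "mim"), type = c("all", "mim"),
                        anti = FALSE) {
  pref <- match.arg(pref); type <- match.arg(type)
  stopifnot(hval > 0, hmax >= 1, gmax >= 0)
  structure(list(hval = hval, hmax = as.integer(hmax), gmax = as.integer(gmax),
                 pref = pref, type = type, anti = isTRUE(anti) || identical(anti, 1)),
            class = "call_params")
}

#' Signed gap/overlap between two fragments of a read
#'
#' For fragments in read order (A starting at or before B), returns
#' `B.q_start - A.q_end - 1`: positive = gap, negative = overlap, zero =
#' exactly adjacent.
#'
#' @param a_q_end q_end of the first fragment.
#' @param b_q_start q_start of the second fragment.
#' @return signed distance in nt.
#' @examples
#' gap_or_overlap(21, 22)  # 0: adjacent
#' gap_or_overlap(22, 22)  # -1: one shared nucleotide
#' gap_or_overlap(22, 20)  # -3
#' @export
gap_or_overlap <- function(a_q_end, b_q_start) {
  b_q_start - a_q_end - 1L
}

#' Record the matches of one read considered for chimera calling
#'
#' Processing hits in descending score order, records: the top-scoring
#' match, all matches tying the top score, every further match whose gap
#' or overlap with the union of the already-recorded read intervals is at
#' most `gmax` nt, and alternative equal-score placements of an
#' already-recorded fragment (same read interval, same score), so that
#' multi-mapping can be counted. Hits with e-value above `hval` are never
#' recorded. Fragments (recorded hits sharing a read interval) mapping to
#' more than `hmax` distinct locations are then excluded wholesale.
#'
#' @param hits `alignment_hits` for a single read, any order.
#' @param params a [call_params()] list.
#' @param read_len read length (needed only for bookkeeping; defaults to max
#'   q_end seen).
#' @return the recorded subset of `hits`.
#' @export
record_matches <- function(hits, params = call_params(), read_len = NULL) {
  hits <- hits[hits$evalue <= params$hval]
  if (nrow(hits) == 0) return(hits)
  o <- order(-hits$bit_score, hits$subject_id, pmin(hits$s_start, hits$s_end))
  hits <- hits[o]
  read_len <- read_len %||% max(hits$q_end)
  covered <- logical(read_len)
  top <- hits$bit_score[1]
  rec <- logical(nrow(hits))
  frag_key <- paste(hits$q_start, hits$q_end, hits$bit_score)
  rec_keys <- character(0)
  for (i in seq_len(nrow(hits))) {
    qs <- hits$q_start[i]; qe <- hits$q_end[i]
    ov <- sum(covered[qs:qe])
    take <- if (!any(covered)) TRUE
    else if (hits$bit_score[i] == top) TRUE
    else if (frag_key[i] %in% rec_keys) TRUE  # alternative placement
    else if (ov > 0) ov <= params$gmax
    else {
      # distance to the nearest covered position
      left <- if (any(covered[seq_len(max(qs - 1, 0))]))
        qs - max(which(covered[seq_len(qs - 1)])) - 1L else NA_integer_
      right <- if (qe < read_len && any(covered[(qe + 1):read_len]))
        min(which(covered[(qe + 1):read_len])) - 1L else NA_integer_
      gap <- min(left, right, na.rm = TRUE)
      gap <= params$gmax
    }
    if (take) {
      rec[i] <- TRUE
      covered[qs:qe] <- TRUE
      rec_keys <- c(rec_keys, frag_key[i])
    }
  }
  hits <- hits[rec]
  # hmax: a fragment = the recorded hits sharing a read interval; count its
  # distinct (subject, strand, s-interval) locations
  frag <- paste(hits$q_start, hits$q_end)
  loc <- paste(hits$subject_id, hits$sense, hits$s_start, hits$s_end)
  nloc <- vapply(split(loc, frag), function(x) length(unique(x)), integer(1))
  keep_frag <- names(nloc)[nloc <= params$hmax]
  hits[frag %in% keep_frag]
}

#' Enumerate candidate fragment pairs of a read
#'
#' All pairs of recorded matches, in read order, with gap/overlap of at most
#' `gmax`, excluding self-pairs and pairs where one fragment's read interval
#' contains the other's. Reads whose best recorded match covers at least
#' `read_len - gmax` nucleotides are non-chimeric (contiguous full-length
#' match) and yield no candidates.
#'
#' @param recorded output of [record_matches()] (score-ordered).
#' @param read_len length of the read in nt.
#' @param params a [call_params()] list.
#' @return data.table with columns `i`, `j` (row indices into `recorded`)
#'   and `gap`; zero rows when the read is non-chimeric.
#' @export
enumerate_candidates <- function(recorded, read_len, params = call_params()) {
  none <- data.table(i = integer(), j = integer(), gap = integer())
  n <- nrow(recorded)
  if (n < 2) return(none)
  span <- recorded$q_end - recorded$q_start + 1L
  best <- which.max(recorded$bit_score)
  if (span[best] >= read_len - params$gmax) return(none)
  pairs <- CJ(a = seq_len(n), b = seq_len(n))[a != b]
  # orient in read order; keep each unordered pair once
  pairs <- pairs[recorded$q_start[a] < recorded$q_start[b] |
                   (recorded$q_start[a] == recorded$q_start[b] & a < b)]
  qs <- recorded$q_start; qe <- recorded$q_end
  contained <- (qs[pairs$a] <= qs[pairs$b] & qe[pairs$a] >= qe[pairs$b]) |
    (qs[pairs$b] <= qs[pairs$a] & qe[pairs$b] >= qe[pairs$a])
  pairs <- pairs[!contained]
  if (nrow(pairs) == 0) return(none)
  gap <- gap_or_overlap(qe[pairs$a], qs[pairs$b])
  keep <- abs(gap) <= params$gmax
  data.table(i = pairs$a[keep], j = pairs$b[keep], gap = gap[keep])
}

#' Rank transcripts by total mapped reads (alignment reference)
#'
#' Counts, for every transcript, the total number of reads mapped to it
#' (each distinct read counted once per transcript, weighted by its collapse
#' count M), and ranks transcripts by that total; rank 1 = most reads, ties
#' broken lexicographically by transcript id. The ranking can be saved and
#' reused across samples so that related experiments share one alignment
#' reference.
#'
#' @param hits one `alignment_hits` table, or a list of them (several
#'   samples).
#' @return data.table with `subject_id`, `reads`, `rank`.
#' @export
rank_transcripts <- function(hits) {
  if (is.data.frame(hits)) hits <- list(hits)
  tab <- rbindlist(lapply(hits, function(h)
    as.data.table(h)[, .(query_id, subject_id)]))
  if (nrow(tab) == 0)
    return(data.table(subject_id = character(), reads = numeric(), rank = integer()))
  tab <- unique(tab)
  tab[, w := read_weight(query_id)]
  counts <- tab[, .(reads = sum(w)), by = subject_id]
  setorder(counts, -reads, subject_id)
  counts[, rank := .I]
  counts[]
}

#' @param ranking a ranking table from [rank_transcripts()].
#' @param path TSV file.
#' @rdname rank_transcripts
#' @export
save_reference <- function(ranking, path) {
  fwrite(ranking, path, sep = "\t")
  invisible(path)
}

#' @rdname rank_transcripts
#' @export
load_reference <- function(path) {
  r <- fread(path, sep = "\t", colClasses = list(character = "subject_id"))
  setorder(r, rank)
  r[]
}

# classify a candidate pair as miRNA-mRNA (in either order)
is_mim_pair <- function(bt1, bt2) {
  (bt1 == "microRNA" & bt2 == "mRNA") | (bt1 == "mRNA" & bt2 == "microRNA")
}

#' Select the unique chimera call for one read
#'
#' Applies the selection cascade to the candidate pairs: (1) maximum sum of
#' the two fragments' mapping scores; (2) with `pref="mim"`, miRNA-mRNA
#' pairs outrank others among score ties; (3) best transcript ranks from the
#' alignment reference (the better rank of the pair compared first, then the
#' worse); (4) a final lexicographic tie-break on the transcript id pair.
#' With `type="mim"` only miRNA-mRNA pairs are eligible at all. Antisense
#' fragments disqualify a pair unless `anti` is set.
#'
#' @param recorded recorded hits of the read ([record_matches()]).
#' @param candidates pair table from [enumerate_candidates()].
#' @param params a [call_params()] list.
#' @param ranking optional transcript ranking ([rank_transcripts()]).
#' @param db the `transcript_db` (for biotypes).
#' @return a one-row `hyb_calls` table, or `NULL` when no eligible candidate.
#' @export
select_call <- function(recorded, candidates, params = call_params(),
                        ranking = NULL, db = NULL) {
  if (nrow(candidates) == 0) return(NULL)
  a <- candidates$i; b <- candidates$j
  ok <- rep(TRUE, nrow(candidates))
  if (!params$anti)
    ok <- ok & recorded$sense[a] & recorded$sense[b]
  bt_a <- bt_b <- rep(NA_character_, nrow(candidates))
  if (!is.null(db)) {
    bt_a <- db_biotype(db, recorded$subject_id[a])
    bt_b <- db_biotype(db, recorded$subject_id[b])
  }
  mim <- !is.na(bt_a) & !is.na(bt_b) & is_mim_pair(bt_a, bt_b)
  if (params$type == "mim") ok <- ok & mim
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  score_sum <- recorded$bit_score[a] + recorded$bit_score[b]
  # (1) maximum score sum
  cand <- cand[score_sum[cand] == max(score_sum[cand])]
  # (2) optional preference for miRNA-mRNA pairs
  if (params$pref == "mim" && any(mim[cand]) && !all(mim[cand]))
    cand <- cand[mim[cand]]
  # (3) transcript ranks: compare (better, worse) rank pairs
  if (length(cand) > 1 && !is.null(ranking) && nrow(ranking) > 0) {
    rk <- function(id) {
      r <- ranking$rank[match(id, ranking$subject_id)]
      ifelse(is.na(r), .Machine$integer.max, r)
    }
    r1 <- rk(recorded$subject_id[a[cand]])
    r2 <- rk(recorded$subject_id[b[cand]])
    better <- pmin(r1, r2); worse <- pmax(r1, r2)
    o <- order(better, worse)
    keep <- better == better[o[1]] & worse == worse[o[1]]
    cand <- cand[keep]
  }
  # (4) deterministic lexicographic tie-break
  if (length(cand) > 1) {
    o <- order(recorded$subject_id[a[cand]], recorded$subject_id[b[cand]],
               recorded$s_start[a[cand]], recorded$s_start[b[cand]])
    cand <- cand[o[1]]
  }
  ai <- a[cand[1]]; bi <- b[cand[1]]
  frag <- function(i) {
    list(tx = recorded$subject_id[i],
         q_start = recorded$q_start[i], q_end = recorded$q_end[i],
         s_start = min(recorded$s_start[i], recorded$s_end[i]),
         s_end = max(recorded$s_start[i], recorded$s_end[i]),
         e = recorded$evalue[i])
  }
  f1 <- frag(ai); f2 <- frag(bi)
  as_hyb_calls(data.table(
    read_id = recorded$query_id[ai], read_seq = NA_character_, dG = NA_real_,
    tx1 = f1$tx, q1_start = f1$q_start, q1_end = f1$q_end,
    s1_start = f1$s_start, s1_end = f1$s_end, e1 = f1$e,
    tx2 = f2$tx, q2_start = f2$q_start, q2_end = f2$q_end,
    s2_start = f2$s_start, s2_end = f2$s_end, e2 = f2$e,
    annotation = NA_character_))
}

#' Bioinformatically extend a miRNA-mRNA chimera call
#'
#' For miRNA-target chimeras (one microRNA fragment, one mRNA fragment), the
#' miRNA fragment's transcript coordinates are extended to cover the entire
#' mature miRNA, and the target coordinates are widened by 25 nt on both
#' sides (clamped to the transcript), so that the whole interaction site is
#' included even when the read does not cover it. Read coordinates are
#' unchanged. Calls that are not miRNA-mRNA are returned unmodified.
#'
#' @param calls a `hyb_calls` table.
#' @param db the `transcript_db`.
#' @param flank target extension in nt (default 25).
#' @return the extended calls.
#' @export
extend_call <- function(calls, db, flank = 25L) {
  if (nrow(calls) == 0) return(calls)
  out <- copy(calls)
  bt1 <- db_biotype(db, out$tx1); bt2 <- db_biotype(db, out$tx2)
  len1 <- db_length(db, out$tx1); len2 <- db_length(db, out$tx2)
  mim <- !is.na(bt1) & !is.na(bt2) & is_mim_pair(bt1, bt2)
  mir1 <- mim & bt1 == "microRNA"
  mir2 <- mim & bt2 == "microRNA"
  out[mir1, `:=`(s1_start = 1L, s1_end = len1[mir1])]
  out[mir1, `:=`(s2_start = pmax(1L, s2_start - flank),
                 s2_end = pmin(len2[mir1], s2_end + flank))]
  out[mir2, `:=`(s2_start = 1L, s2_end = len2[mir2])]
  out[mir2, `:=`(s1_start = pmax(1L, s1_start - flank),
                 s1_end = pmin(len1[mir2], s1_end + flank))]
  out[]
}

#' Call chimeras from a stream of alignments
#'
#' Runs [record_matches()], [enumerate_candidates()] and [select_call()] for
#' every read group in the hit table (one pass, constant memory per read
#' group), producing at most one chimera per read, in input read order. With
#' `type="mim"` the surviving calls are bioinformatically extended
#' ([extend_call()]).
#'
#' @param hits an `alignment_hits` table (built-in aligner or imported
#'   blast tabular; both feed the identical contract).
#' @param params a [call_params()] list.
#' @param ranking optional transcript ranking ([rank_transcripts()]); when
#'   `NULL`, computed from `hits`.
#' @param db the `transcript_db` (biotypes, extension, folding).
#' @param reads optional [clash_reads] supplying read sequences and lengths.
#' @return a `hyb_calls` data.table.
#' @export
call_chimeras <- function(hits, params = call_params(), ranking = NULL,
                          db = NULL, reads = NULL) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0) return(empty_calls())
  if (is.null(ranking)) ranking <- rank_transcripts(hits)
  read_len <- NULL
  if (!is.null(reads))
    read_len <- setNames(nchar(reads$seq), reads$id)
  groups <- split(seq_len(nrow(hits)), factor(hits$query_id, levels = unique(hits$query_id)))
  out <- vector("list", length(groups))
  k <- 0L
  for (g in groups) {
    h <- hits[g]
    rl <- read_len[h$query_id[1]]
    if (is.null(rl) || is.na(rl)) rl <- max(h$q_end)
    rec <- record_matches(h, params, read_len = rl)
    if (nrow(rec) < 2) next
    cands <- enumerate_candidates(rec, rl, params)
    call <- select_call(rec, cands, params, ranking, db)
    if (!is.null(call)) { k <- k + 1L; out[[k]] <- call }
  }
  if (k == 0L) return(empty_calls())
  calls <- as_hyb_calls(rbindlist(out[seq_len(k)]))
  if (!is.null(reads))
    calls[, read_seq := reads$seq[match(read_id, reads$id)]]
  if (params$type == "mim" && !is.null(db))
    calls <- extend_call(calls, db)
  validate_calls(calls)
  calls
}
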