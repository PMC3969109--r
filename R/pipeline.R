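#' Detect chimeras in a set of reads
#'
#' The "detect" task: maps reads against the transcript database with the
#' built-in aligner (or takes pre-computed alignments), ranks transcripts,
#' and calls at most one chimera per read.
#'
#' @param reads a [clash_reads] table (may be `NULL` when `hits` are
#'   supplied and read sequences are not needed).
#' @param db a `transcript_db` or an already-built `hyb_index`.
#' @param params a [call_params()] list.
#' @param align_params an [align_params()] list for the built-in aligner.
#' @param hits optional pre-computed `alignment_hits` (e.g. from
#'   [read_blast_tab()]); when given, no alignment is performed
#'   (`align=none` mode).
#' @param ranking optional transcript ranking to reuse as a common
#'   alignment reference across samples.
#' @return list with `calls` (a `hyb_calls` table), `hits`, and `ranking`.
#' @export
hyb_detect <- function(reads, db, params = call_params(),
                       align_params = clashr::align_params(),
                       hits = NULL, ranking = NULL) {
  index <- NULL
  if (inherits(db, "hyb_index")) {
    index <- db; db <- index$db
  }
  if (is.null(hits)) {
    if (is.null(index)) index <- build_index(db, align_params$word)
    hits <- local_align(reads, index, align_params)
  }
  if (is.null(ranking)) ranking <- rank_transcripts(hits)
  calls <- call_chimeras(hits, params, ranking, db, reads)
  list(calls = calls, hits = hits, ranking = ranking)
}

#' Fold and merge chimera calls
#'
#' The "analyse" task: folds every call as an intermolecular duplex, merges
#' overlapping chimeras into interactions, and computes the QC statistics.
#'
#' @param calls a `hyb_calls` table.
#' @param db the `transcript_db`.
#' @param fold `"builtin"` or `"viennad-import"`.
#' @param viennad viennad file when importing external foldings.
#' @return list with `calls` (folded), `interactions`, and `qc`.
#' @export
hyb_analyse <- function(calls, db, fold = c("builtin", "viennad-import"),
                        viennad = NULL) {
  fold <- match.arg(fold)
  folded <- fold_chimeras(calls, db, backend = fold, viennad = viennad)
  list(calls = folded,
       interactions = merge_interactions(folded),
       qc = interaction_qc(folded, db))
}

#' Score chimera recovery against a generator truth table
#'
#' A planted fusion read counts as recovered when its called transcript
#' pair matches the truth (by transcript id, in either fragment order; for
#' redundant isoforms, matching the gene's display name counts).
#'
#' @param calls a `hyb_calls` table.
#' @param truth truth table from [make_fusion_reads()].
#' @param db the `transcript_db` (to resolve isoform display names).
#' @return list: `recovered_fraction`, `n_recovered`, `n_truth`, and the
#'   per-read logical vector `recovered`.
#' @export
score_recovery <- function(calls, truth, db = NULL) {
  x <- as.data.table(calls)
  m <- match(truth$read_id, x$read_id)
  called1 <- x$tx1[m]; called2 <- x$tx2[m]
  gene <- function(ids) {
    if (is.null(db)) return(ids)
    g <- db$info$display_name[match(ids, db$info$full_id)]
    ifelse(is.na(g), ids, g)
  }
  ok <- !is.na(m) &
    ((gene(called1) == gene(truth$mirna_id) & gene(called2) == gene(truth$mrna_id)) |
     (gene(called1) == gene(truth$mrna_id) & gene(called2) == gene(truth$mirna_id)))
  ok[is.na(ok)] <- FALSE
  list(recovered_fraction = mean(ok), n_recovered = sum(ok),
       n_truth = nrow(truth), recovered = ok)
}
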