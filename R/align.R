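#' Alignment parameters
#'
#' Scoring follows local-aligner conventions for short reads: match +1,
#' mismatch -2, affine gaps (a gap of length L costs
#' `|gap_open| + L * |gap_extend|`), seeds of `word` nt, hits reported when
#' the local alignment score reaches `min_score`, capped at
#' `max_hits_reported` per read.
#'
#' @param word seed length in nt (>= 4; default 11).
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open,gap_extend gap penalties (negative).
#' @param min_score minimum reported local alignment score.
#' @param max_hits_reported cap on hits per read.
#' @return an `align_params` list.
#' @export
align_params <- function(word = 11L, match = 1L, mismatch = -2L,
                         gap_open = -5L, gap_extend = -1L,
                         min_score = 15L, max_hits_reported = 20L) {
  stopifnot(word >= 4, match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_score > 0, max_hits_reported >= 1)
  structure(list(word = as.integer(word), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score),
                 max_hits_reported = as.integer(max_hits_reported)),
            class = "align_params")
}

#' Build a k-mer seed index over a transcript database
#'
#' Every exact `word`-length substring of every transcript is hashed for O(1)
#' expected lookup. The returned object is an ordinary R list (serializable
#' with `saveRDS()`); the compiled hash table is rebuilt lazily after a
#' round-trip.
#'
#' @param db a `transcript_db`.
#' @param word seed length (default 11).
#' @return a `hyb_index` object.
#' @export
build_index <- function(db, word = 11L) {
  stopifnot(inherits(db, "transcript_db"))
  if (length(db$seq) == 0) stop("cannot index an empty database")
  short <- db$info$length < word
  if (any(short))
    warning(sum(short), " transcript(s) shorter than the word size carry no seeds")
  obj <- structure(list(word = as.integer(word), db = db,
                        ptr_env = new.env(parent = emptyenv())),
                   class = "hyb_index")
  index_ptr(obj)  # build eagerly
  obj
}

# compiled index handle, rebuilt after serialization round-trips
index_ptr <- function(index) {
  env <- index$ptr_env
  p <- env$ptr
  ok <- !is.null(p) &&
    !isTRUE(tryCatch(cpp_index_word(p) != index$word, error = function(e) TRUE))
  if (!ok) {
    env$ptr <- cpp_build_index(unname(index$db$seq), index$word)
    p <- env$ptr
  }
  p
}

#' Local alignment of reads against an indexed database
#'
#' Seed-and-extend local alignment with blast-tabular semantics: for each
#' cluster of exact word seeds a full Smith-Waterman alignment of the read
#' against the seeded window is computed, so reported scores equal the
#' exhaustive local-alignment score in that region. Both strands are
#' searched; reverse-strand (antisense) hits carry `s_start > s_end`. Hits
#' are sorted by score descending with deterministic tie-breaking by
#' (subject id, s_start), at most `max_hits_reported` per read, and are
#' assigned Karlin-Altschul e-values (see [hit_evalue()]).
#'
#' @param reads a [clash_reads] table (or character vector of sequences).
#' @param index a `hyb_index` from [build_index()].
#' @param params an [align_params()] list.
#' @param both_strands search the reverse strand as well (default TRUE).
#' @return an `alignment_hits` data.table (blast-tabular columns plus
#'   `score` and `sense`).
#' @export
local_align <- function(reads, index, params = align_params(word = index$word),
                        both_strands = TRUE) {
  stopifnot(inherits(index, "hyb_index"))
  if (inherits(reads, "data.frame")) {
    ids <- reads$id; seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- names(seqs) %||% paste0("read", seq_along(seqs))
  }
  if (length(seqs) == 0) return(empty_hits())
  raw <- as.data.table(cpp_local_align(
    index_ptr(index), seqs,
    params$match, params$mismatch, -params$gap_open, -params$gap_extend,
    params$min_score, both_strands))
  if (nrow(raw) == 0) return(empty_hits())
  subject_names <- names(index$db$seq)
  hits <- data.table(
    query_id = ids[raw$query],
    subject_id = subject_names[raw$subject],
    pct_identity = round(raw$pct_identity, 2),
    aln_len = raw$aln_len, mismatches = raw$mismatches,
    gap_openings = raw$gap_openings,
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = raw$s_start, s_end = raw$s_end,
    score = raw$score,
    query_ord = raw$query)
  n <- sum(index$db$info$length)
  hits[, bit_score := round(bit_score(score, params), 1)]
  hits[, evalue := signif(hit_evalue(bit_score, nchar(seqs)[query_ord], n), 3)]
  setorder(hits, query_ord, -score, subject_id, s_start)
  hits <- hits[, head(.SD, params$max_hits_reported), by = query_ord]
  hits[, query_ord := NULL]
  setcolorder(hits, c("query_id", "subject_id", "pct_identity", "aln_len",
                      "mismatches", "gap_openings", "q_start", "q_end",
                      "s_start", "s_end", "evalue", "bit_score", "score"))
  validate_hits(hits)
}

# ---- Karlin-Altschul statistics ------------------------------------------

#' Karlin-Altschul lambda for an ungapped scoring scheme
#'
#' The unique positive root of `sum_ij p_i p_j exp(lambda * s(i,j)) = 1`
#' under uniform base composition, solved numerically.
#'
#' @param match,mismatch the match/mismatch scores.
#' @return lambda (nats per score unit).
#' @export
karlin_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

# standard published ungapped K for the +1/-2 nucleotide scheme
KA_K <- 0.621

#' Bit score and e-value for built-in alignments
#'
#' `bit_score()` converts a raw local alignment score S to bits,
#' `(lambda * S - ln K) / ln 2`; `hit_evalue()` is the Karlin-Altschul
#' expectation `E = m * n * 2^(-bits)` with m the read length and n the
#' total database length (no edge correction).
#'
#' @param score raw alignment score(s).
#' @param params an [align_params()] list (for the match/mismatch scheme).
#' @export
bit_score <- function(score, params = align_params()) {
  lambda <- karlin_lambda(params$match, params$mismatch)
  (lambda * score - log(KA_K)) / log(2)
}

#' @param bits bit score(s).
#' @param m query (read) length(s).
#' @param n total database length in nt.
#' @rdname bit_score
#' @export
hit_evalue <- function(bits, m, n) {
  m * n * 2^(-bits)
}
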