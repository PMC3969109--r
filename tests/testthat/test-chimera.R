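# a minimal hit table builder with the alignment_hits columns
mk_hits <- function(...) {
  rows <- list(...)
  h <- data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(
      query_id = r$q %||% "read1", subject_id = r$tx,
      pct_identity = 100, aln_len = r$qe - r$qs + 1L,
      mismatches = 0L, gap_openings = 0L,
      q_start = as.integer(r$qs), q_end = as.integer(r$qe),
      s_start = as.integer(r$ss %||% 1L),
      s_end = as.integer(r$se %||% ((r$ss %||% 1L) + (r$qe - r$qs))),
      evalue = r$e %||% 1e-5, bit_score = r$bit,
      score = as.integer(round(r$bit)))
  }))
  clashr:::validate_hits(h)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gap_or_overlap reproduces the worked coordinate examples", {
  # adjacent fragments: q [2,21] then [22,47]
  expect_equal(gap_or_overlap(21, 22), 0L)
  # one-nucleotide overlap: [1,22] then [22,44]
  expect_equal(gap_or_overlap(22, 22), -1L)
  # three-nucleotide overlap: [1,22] then [20,40]
  expect_equal(gap_or_overlap(22, 20), -3L)
  # gaps are positive
  expect_equal(gap_or_overlap(22, 28), 5L)
})

test_that("record_matches keeps top hits, ties, and gmax-compatible hits", {
  # top fragment recorded, equal-score ties recorded, and the second
  # fragment abutting the covered area recorded
  hits <- mk_hits(
    list(tx = "fragA", qs = 1, qe = 28, bit = 28),
    list(tx = "tieA", qs = 1, qe = 28, bit = 28, ss = 50),
    list(tx = "fragB", qs = 27, qe = 50, bit = 24))
  rec <- record_matches(hits, call_params(), read_len = 50)
  expect_setequal(rec$subject_id, c("fragA", "tieA", "fragB"))
  # a hit contained in the covered area (overlap > gmax) is not recorded
  hits0 <- mk_hits(
    list(tx = "full", qs = 1, qe = 40, bit = 40),
    list(tx = "half1", qs = 1, qe = 22, bit = 20),
    list(tx = "half2", qs = 21, qe = 40, bit = 22))
  rec0 <- record_matches(hits0, call_params(), read_len = 40)
  expect_setequal(rec0$subject_id, "full")
  # a hit overlapping the covered area by more than gmax is not recorded
  hits2 <- mk_hits(
    list(tx = "top", qs = 1, qe = 22, bit = 22),
    list(tx = "inside", qs = 3, qe = 20, bit = 18))
  rec2 <- record_matches(hits2, call_params(), read_len = 40)
  expect_equal(rec2$subject_id, "top")
  # hits beyond the e-value threshold are never recorded
  hits3 <- mk_hits(
    list(tx = "good", qs = 1, qe = 22, bit = 22),
    list(tx = "weak", qs = 23, qe = 40, bit = 17, e = 0.2))
  rec3 <- record_matches(hits3, call_params(hval = 0.1), read_len = 40)
  expect_equal(rec3$subject_id, "good")
})

test_that("fragments mapping to more than hmax locations are excluded", {
  # 11 equal-scoring locations for the same read interval at hmax=10
  many <- lapply(1:11, function(i)
    list(tx = sprintf("iso%02d", i), qs = 1, qe = 22, bit = 22, ss = 1))
  one <- list(list(tx = "target", qs = 23, qe = 50, bit = 28))
  rec <- do.call(mk_hits, c(many, one))
  out <- record_matches(rec, call_params(hmax = 10), read_len = 50)
  expect_equal(out$subject_id, "target")   # multi-mapping fragment dropped
  out11 <- record_matches(rec, call_params(hmax = 11), read_len = 50)
  expect_equal(nrow(out11), 12L)           # kept when the cap allows it
})

test_that("candidate enumeration enforces gmax and full-length rejection", {
  p <- call_params()
  # halves [1,22] + [23,49]: gap 0, one candidate
  rec <- mk_hits(list(tx = "a", qs = 1, qe = 22, bit = 22),
                 list(tx = "b", qs = 23, qe = 49, bit = 27))
  cands <- enumerate_candidates(rec, 49, p)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$gap, 0L)
  # gap 5 at gmax=4: no candidate
  rec2 <- mk_hits(list(tx = "a", qs = 1, qe = 22, bit = 22),
                  list(tx = "b", qs = 28, qe = 49, bit = 22))
  expect_equal(nrow(enumerate_candidates(rec2, 49, p)), 0L)
  # a read with a contiguous full-length best match yields no candidates
  rec3 <- mk_hits(list(tx = "full", qs = 1, qe = 50, bit = 50),
                  list(tx = "a", qs = 1, qe = 22, bit = 22),
                  list(tx = "b", qs = 23, qe = 50, bit = 28))
  expect_equal(nrow(enumerate_candidates(rec3, 50, p)), 0L)
  # containment excluded: [1,40] vs [5,35]
  rec4 <- mk_hits(list(tx = "a", qs = 1, qe = 40, bit = 40),
                  list(tx = "b", qs = 5, qe = 35, bit = 31))
  expect_equal(nrow(enumerate_candidates(rec4, 60, p)), 0L)
})

test_that("transcript ranking counts collapse-weighted reads with stable ties", {
  hits <- rbind(
    mk_hits(list(q = "1_10", tx = "tx1", qs = 1, qe = 20, bit = 20)),
    mk_hits(list(q = "2_3", tx = "tx2", qs = 1, qe = 20, bit = 20)),
    mk_hits(list(q = "3_1", tx = "tx2", qs = 1, qe = 20, bit = 20)))
  r <- rank_transcripts(hits)
  expect_equal(r$subject_id[r$rank == 1], "tx1")  # 10 reads beats 3+1
  expect_equal(r$reads, c(10, 4))
  # ties resolved lexicographically
  hits2 <- rbind(
    mk_hits(list(q = "a", tx = "zzz", qs = 1, qe = 20, bit = 20)),
    mk_hits(list(q = "b", tx = "aaa", qs = 1, qe = 20, bit = 20)))
  r2 <- rank_transcripts(hits2)
  expect_equal(r2$subject_id, c("aaa", "zzz"))
  # save / load reproduces identical rankings
  f <- tempfile()
  save_reference(r, f)
  expect_equal(load_reference(f)$subject_id, r$subject_id)
})

test_that("selection prefers score sum, then mim class, then transcript rank", {
  db <- transcript_db(c(m_mir1_microRNA = strrep("A", 22),
                        g1_t1_G1_mRNA = strrep("C", 100),
                        g2_t2_G2_mRNA = strrep("G", 100),
                        g3_t3_G3_mRNA = strrep("T", 100)))
  rec <- mk_hits(
    list(tx = "m_mir1_microRNA", qs = 1, qe = 22, bit = 20),
    list(tx = "g1_t1_G1_mRNA", qs = 1, qe = 22, bit = 20),
    list(tx = "g2_t2_G2_mRNA", qs = 23, qe = 50, bit = 20))
  cands <- enumerate_candidates(rec, 50, call_params())
  expect_equal(nrow(cands), 2L)
  # equal score sums: pref=mim picks the miRNA-mRNA pair
  call_mim <- select_call(rec, cands, call_params(pref = "mim"), db = db)
  expect_equal(call_mim$tx1, "m_mir1_microRNA")
  # pref=none: the transcript ranking decides
  ranking <- data.table::data.table(subject_id = c("g1_t1_G1_mRNA", "g2_t2_G2_mRNA",
                                                   "m_mir1_microRNA"),
                                    reads = c(100, 50, 10), rank = 1:3)
  call_rank <- select_call(rec, cands, call_params(pref = "none"),
                           ranking = ranking, db = db)
  expect_equal(call_rank$tx1, "g1_t1_G1_mRNA")
  # type=mim: non-mim candidates are ineligible entirely
  rec2 <- mk_hits(
    list(tx = "g1_t1_G1_mRNA", qs = 1, qe = 22, bit = 22),
    list(tx = "g2_t2_G2_mRNA", qs = 23, qe = 50, bit = 28))
  cands2 <- enumerate_candidates(rec2, 50, call_params(type = "mim"))
  expect_null(select_call(rec2, cands2, call_params(type = "mim"), db = db))
})

test_that("antisense fragments disqualify a pair unless anti is set", {
  rec <- mk_hits(
    list(tx = "a_x_A_mRNA", qs = 1, qe = 22, bit = 22, ss = 60, se = 39),
    list(tx = "b_y_B_mRNA", qs = 23, qe = 50, bit = 28))
  cands <- enumerate_candidates(rec, 50, call_params())
  expect_equal(nrow(cands), 1L)
  expect_null(select_call(rec, cands, call_params(anti = FALSE)))
  call <- select_call(rec, cands, call_params(anti = TRUE))
  expect_equal(call$tx1, "a_x_A_mRNA")
  expect_lte(call$s1_start, call$s1_end)  # .hyb stores ascending coordinates
})

test_that("mim extension covers the full miRNA and widens targets by 25 nt", {
  db <- transcript_db(c(m_mir1_microRNA = strrep("A", 22),
                        g1_t1_G1_mRNA = strrep("C", 3000),
                        g2_t2_G2_mRNA = strrep("G", 100)))
  call <- clashr:::as_hyb_calls(data.table::data.table(
    read_id = "r", read_seq = NA_character_, dG = NA_real_,
    tx1 = "m_mir1_microRNA", q1_start = 1L, q1_end = 20L,
    s1_start = 1L, s1_end = 20L, e1 = 1e-4,
    tx2 = "g1_t1_G1_mRNA", q2_start = 21L, q2_end = 43L,
    s2_start = 1614L, s2_end = 1636L, e2 = 1e-4,
    annotation = NA_character_))
  ext <- extend_call(call, db)
  expect_equal(c(ext$s1_start, ext$s1_end), c(1L, 22L))       # full miRNA
  expect_equal(c(ext$s2_start, ext$s2_end), c(1589L, 1661L))  # +/- 25
  expect_equal(c(ext$q1_start, ext$q2_end), c(1L, 43L))       # read coords untouched
  # clamping at the transcript ends
  call2 <- data.table::copy(call)
  call2[, `:=`(tx2 = "g2_t2_G2_mRNA", s2_start = 10L, s2_end = 40L)]
  ext2 <- extend_call(call2, db)
  expect_equal(c(ext2$s2_start, ext2$s2_end), c(1L, 65L))
  # non-mim calls are untouched
  call3 <- data.table::copy(call)
  call3[, tx1 := "g2_t2_G2_mRNA"]
  expect_equal(extend_call(call3, db)$s1_end, 20L)
})

test_that("end-to-end chimera calling recovers planted fusions, rejects contiguous reads", {
  db <- toy_db()
  fus <- make_fusion_reads(150, db, seed = 21, order = "mixed")
  det <- hyb_detect(fus$reads, db)
  sc <- score_recovery(det$calls, fus$truth, db)
  expect_gte(sc$recovered_fraction, 0.95)
  # breakpoints within gmax of truth
  m <- match(det$calls$read_id, fus$truth$read_id)
  expect_true(all(abs(det$calls$q1_end - fus$truth$breakpoint[m]) <= 4))
  # contiguous library: exactly zero calls
  ctg <- make_contiguous_reads(150, db, seed = 22)
  expect_equal(nrow(hyb_detect(ctg, db)$calls), 0L)
  # empty input: empty output
  expect_equal(nrow(call_chimeras(clashr:::empty_hits())), 0L)
})

test_that("identical inputs give identical calls regardless of hit order", {
  db <- toy_db()
  fus <- make_fusion_reads(40, db, seed = 31)
  det <- hyb_detect(fus$reads, db)
  hits <- det$hits
  set.seed(1)
  shuffled <- hits[sample(nrow(hits))]
  calls_a <- call_chimeras(hits, db = db, reads = fus$reads)
  calls_b <- call_chimeras(shuffled, db = db, reads = fus$reads)
  data.table::setkey(calls_a, read_id); data.table::setkey(calls_b, read_id)
  expect_equal(as.data.frame(calls_a), as.data.frame(calls_b))
})
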