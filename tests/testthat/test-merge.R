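mk_call <- function(read_id, tx1, s1, tx2, s2, dG = NA_real_) {
  clashr:::as_hyb_calls(data.table::data.table(
    read_id = read_id, read_seq = NA_character_, dG = dG,
    tx1 = tx1, q1_start = 1L, q1_end = 22L,
    s1_start = as.integer(s1[1]), s1_end = as.integer(s1[2]), e1 = 1e-4,
    tx2 = tx2, q2_start = 23L, q2_end = 44L,
    s2_start = as.integer(s2[1]), s2_end = as.integer(s2[2]), e2 = 1e-4,
    annotation = NA_character_))
}

test_that("chimeras overlapping in both fragments merge into one interaction", {
  # two calls of one transcript pair with overlapping target windows
  calls <- rbind(
    mk_call("77750_22", "EIF2C1", c(1882, 1908), "let-7a", c(1, 22), -21.2),
    mk_call("199610_8", "EIF2C1", c(1884, 1907), "let-7a", c(1, 22), -21.2))
  m <- merge_interactions(calls)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_chimeras, 2L)
  expect_equal(m$n_reads, 22L + 8L)           # collapse counts from the ids
  expect_equal(m$mean_dG, -21.2)
  expect_equal(c(m$s1_start, m$s1_end), c(1882L, 1908L))  # envelope
  expect_equal(m$supporting_ids, "199610_8,77750_22")
})

test_that("overlap in only one fragment does not merge (both-fragment rule)", {
  calls <- rbind(
    mk_call("1_1", "txA", c(100, 130), "txB", c(10, 30)),
    mk_call("2_1", "txA", c(100, 130), "txB", c(50, 70)))  # frag2 disjoint
  m <- merge_interactions(calls)
  expect_equal(nrow(m), 2L)
  # and a single call maps onto itself
  single <- mk_call("9_5", "txA", c(1, 20), "txB", c(5, 25), -10)
  ms <- merge_interactions(single)
  expect_equal(ms$n_chimeras, 1L)
  expect_equal(ms$n_reads, 5L)
  expect_equal(c(ms$s2_start, ms$s2_end), c(5L, 25L))
})

test_that("merging is transitive, idempotent and permutation-invariant", {
  # a overlaps b, b overlaps c, a disjoint from c: one chain
  calls <- rbind(
    mk_call("1_1", "txA", c(100, 120), "txB", c(10, 30), -5),
    mk_call("2_1", "txA", c(115, 135), "txB", c(25, 45), -7),
    mk_call("3_1", "txA", c(130, 150), "txB", c(40, 60), -9))
  m <- merge_interactions(calls)
  expect_equal(m$n_chimeras, 3L)
  expect_equal(c(m$s1_start, m$s1_end), c(100L, 150L))
  set.seed(2)
  for (i in 1:5) {
    perm <- calls[sample(nrow(calls))]
    expect_equal(as.data.frame(merge_interactions(perm)), as.data.frame(m))
  }
  # conservation: total read support equals the sum of collapse counts
  expect_equal(sum(m$n_reads), sum(clashr:::read_weight(calls$read_id)))
  # empty input
  expect_equal(nrow(merge_interactions(clashr:::empty_calls())), 0L)
})

test_that("read-support conservation holds on a full synthetic run", {
  db <- toy_db()
  fus <- make_fusion_reads(120, db, seed = 51, order = "mixed")
  det <- hyb_detect(fus$reads, db)
  m <- merge_interactions(det$calls)
  expect_equal(sum(m$n_reads), sum(clashr:::read_weight(det$calls$read_id)))
  expect_true(all(m$n_reads >= m$n_chimeras))
})

test_that("seed_match agrees with the exhaustive scan over all 6-mers", {
  # every 6-mer seed: miRNA = N + seed6 + padding; matching target carries
  # the reverse complement, control target does not
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  set.seed(10)
  for (i in seq_len(nrow(grid))) {
    seed6 <- paste0(grid$b1[i], grid$b2[i], grid$b3[i],
                    sample(bases, 1), sample(bases, 1), sample(bases, 1))
    mir <- paste0("T", seed6, "ACGTACGTACGTACA")
    site <- clashr:::revcomp(seed6)
    target_hit <- paste0(random_dna(10), site, random_dna(10))
    expect_equal(seed_match(mir, target_hit),
                 seed_match_oracle(mir, target_hit))
    target_rnd <- random_dna(26)
    expect_equal(seed_match(mir, target_rnd),
                 seed_match_oracle(mir, target_rnd))
    expect_true(seed_match(mir, target_hit))
  }
  # a target equal to the miRNA itself carries no complement
  expect_false(seed_match("TGAGGTAGTAGGTTGTATAGTT", "TGAGGTAGTAGGTTGTATAGTT"))
})

test_that("QC reports mean energy, seed fraction and zero-gap fraction", {
  db0 <- toy_db()
  fus <- make_fusion_reads(60, db0, seed = 61, plant_site = TRUE)
  db <- fus$db  # carries the planted sites
  det <- hyb_detect(fus$reads, db)
  folded <- fold_chimeras(det$calls, db)
  qc <- interaction_qc(folded, db)
  expect_equal(qc$n_chimeras, nrow(folded))
  expect_lt(qc$mean_dG, 0)
  expect_gte(qc$seed_match_fraction, 0.9)  # planted complementary sites
  expect_true(qc$zero_gap_fraction >= 0 && qc$zero_gap_fraction <= 1)
  # all-adjacent calls give zero-gap fraction 1
  adj <- rbind(mk_call("1_1", "a", c(1, 20), "b", c(1, 20)),
               mk_call("2_1", "a", c(5, 24), "b", c(3, 22)))
  expect_equal(interaction_qc(adj)$zero_gap_fraction, 1)
  # empty input yields an empty-style row
  expect_equal(interaction_qc(clashr:::empty_calls())$n_chimeras, 0L)
})

test_that("matched pairs fold more strongly than shuffled pairs", {
  db0 <- toy_db()
  fus <- make_fusion_reads(60, db0, seed = 71, plant_site = TRUE)
  db <- fus$db
  det <- hyb_detect(fus$reads, db)
  folded <- fold_chimeras(det$calls, db)
  matched <- mean(folded$dG)
  # shuffle the miRNA-target pairing and refold
  shuf <- data.table::copy(folded)
  set.seed(1)
  perm <- sample(nrow(shuf))
  shuf[, `:=`(tx2 = folded$tx2[perm], s2_start = folded$s2_start[perm],
              s2_end = folded$s2_end[perm])]
  refold <- fold_chimeras(shuf, db)
  expect_lt(matched, mean(refold$dG))  # more negative = stronger
})
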