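test_that("collapsed-read identifiers parse and serialize in the K-L_M scheme", {
  p <- parse_collapsed_id(c("44480_39", "1-2_3", "readA", "7_1"))
  expect_equal(p$rank, c(44480L, 1L, NA, 7L))
  expect_equal(p$n_barcodes, c(NA, 2L, NA, NA))
  expect_equal(p$count, c(39L, 3L, NA, 1L))
  expect_equal(collapsed_id(44480, 39), "44480_39")
  expect_equal(collapsed_id(1, 3, 2), "1-2_3")
  expect_error(collapsed_id(1, 2, 3), "n_barcodes")
  # round trip on random ids
  set.seed(1)
  k <- sample(1e5, 50); m <- sample(100, 50, replace = TRUE)
  l <- pmin(sample(10, 50, replace = TRUE), m)
  ids <- collapsed_id(k, m, ifelse(seq_len(50) %% 2 == 0, l, NA))
  q <- parse_collapsed_id(ids)
  expect_equal(q$rank, k)
  expect_equal(q$count, m)
})

test_that("FASTA and FASTQ reading preserves order, metadata and qualities", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">44480_39", "ACGTACGT", ">1-2_3", "GGGTTTAA"), fa)
  r <- read_sequences(fa)
  expect_equal(r$id, c("44480_39", "1-2_3"))
  expect_equal(r$rank, c(44480L, 1L))
  expect_equal(r$count, c(39L, 3L))
  expect_equal(r$n_barcodes, c(NA_integer_, 2L))
  expect_true(all(is.na(r$qual)))

  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "TTGGA", "+", "IIIII"), fq)
  r2 <- read_sequences(fq)
  expect_equal(r2$seq, c("ACGT", "TTGGA"))
  expect_equal(r2$qual, c("IIII", "IIIII"))

  # gzip round trip
  gz <- tempfile(fileext = ".fastq.gz")
  write_sequences(r2, gz, "fastq")
  expect_equal(read_sequences(gz), r2)

  # empty file: empty stream, no error
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_sequences(empty)), 0L)
})

test_that("malformed FASTQ is rejected with a line number", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)  # qual too short
  expect_error(read_sequences(fq), "line 2")
  fq2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "AAAA", "+", "IIII"), fq2)
  expect_error(read_sequences(fq2), "line 5")
})

test_that("blast tabular parsing follows outfmt-6 semantics", {
  f <- tempfile()
  writeLines(c(
    "r1\ttx1\t100.00\t22\t0\t0\t1\t22\t1\t22\t2e-04\t44.1",
    "r2\ttx2\t95.00\t20\t1\t0\t3\t22\t100\t80\t1e-03\t30.0"), f)
  h <- read_blast_tab(f)
  expect_equal(h$q_start[1], 1L); expect_equal(h$q_end[1], 22L)
  expect_equal(h$s_start[1], 1L); expect_equal(h$s_end[1], 22L)
  expect_equal(h$evalue[1], 2e-4)
  expect_true(h$sense[1])
  expect_false(h$sense[2])  # s_start > s_end denotes antisense

  f11 <- tempfile()
  writeLines("r1\ttx1\t100\t22\t0\t0\t1\t22\t1\t22\t2e-04", f11)
  expect_error(read_blast_tab(f11), "12 columns")
  fbad <- tempfile()
  writeLines("r1\ttx1\t100\t22\t0\t0\tX\t22\t1\t22\t2e-04\t44.1", fbad)
  expect_error(read_blast_tab(fbad), "non-numeric")
  fempty <- tempfile(); file.create(fempty)
  expect_equal(nrow(read_blast_tab(fempty)), 0L)
})

test_that("write_hyb reproduces the canonical 15-column layout and round-trips", {
  call <- data.table::data.table(
    read_id = "44480_39", read_seq = "TGAGGTAG", dG = -12.1,
    tx1 = "let-7b", q1_start = 1L, q1_end = 22L, s1_start = 1L, s1_end = 22L,
    e1 = 2e-4,
    tx2 = "ACTB", q2_start = 22L, q2_end = 44L, s2_start = 1614L,
    s2_end = 1636L, e2 = 4e-5, annotation = NA_character_)
  f <- tempfile(fileext = ".hyb")
  write_hyb(call, f)
  expect_equal(readLines(f),
    "44480_39\tTGAGGTAG\t-12.1\tlet-7b\t1\t22\t1\t22\t2e-04\tACTB\t22\t44\t1614\t1636\t4e-05")
  back <- read_hyb(f)
  expect_equal(back$dG, -12.1)
  expect_equal(back$e2, 4e-5)
  # byte-identical round trip write -> read -> write
  f2 <- tempfile(fileext = ".hyb")
  write_hyb(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("unfolded calls serialize dG as '.' and restore as NA", {
  call <- data.table::data.table(
    read_id = "r1", read_seq = "ACGT", dG = NA_real_,
    tx1 = "a", q1_start = 1L, q1_end = 2L, s1_start = 5L, s1_end = 6L, e1 = 1e-3,
    tx2 = "b", q2_start = 3L, q2_end = 4L, s2_start = 9L, s2_end = 10L, e2 = 1e-3,
    annotation = "biotype=mim;")
  f <- tempfile()
  write_hyb(call, f)
  line <- readLines(f)
  expect_equal(strsplit(line, "\t")[[1]][3], ".")
  expect_equal(length(strsplit(line, "\t")[[1]]), 16L)  # annotation column
  back <- read_hyb(f)
  expect_true(is.na(back$dG))
  expect_equal(back$annotation, "biotype=mim;")
})

test_that("invalid chimera calls are refused by the writer", {
  bad <- data.table::data.table(
    read_id = "r1", read_seq = "ACGT", dG = NA_real_,
    tx1 = "a", q1_start = 5L, q1_end = 6L, s1_start = 1L, s1_end = 2L, e1 = 1e-3,
    tx2 = "b", q2_start = 1L, q2_end = 2L, s2_start = 1L, s2_end = 2L, e2 = 1e-3,
    annotation = NA_character_)
  expect_error(write_hyb(bad, tempfile()), "read order")
})

test_that("viennad blocks have the fixed six-line layout and round-trip", {
  db <- toy_db()
  fus <- make_fusion_reads(5, db, seed = 2)
  det <- hyb_detect(fus$reads, db)
  folded <- fold_chimeras(det$calls, db)
  f <- tempfile(fileext = ".viennad")
  write_viennad(folded, f)
  lines <- readLines(f)
  expect_equal(length(lines), 6L * nrow(folded))
  # energy line equals the .hyb column-3 value for the same call
  hl <- clashr:::hyb_lines(folded)
  for (i in seq_len(nrow(folded))) {
    expect_equal(lines[(i - 1) * 6 + 6],
                 sprintf("dG = %s kcal/mol", strsplit(hl[i], "\t")[[1]][3]))
    expect_equal(lines[(i - 1) * 6 + 1], folded$read_id[i])
  }
  back <- read_viennad(f)
  expect_equal(back$read_id, folded$read_id)
  expect_equal(back$dG, folded$dG)
  expect_equal(back$structure, folded$structure)
  expect_equal(back$s1_start, folded$s1_start)
  # zero calls -> empty file
  f0 <- tempfile()
  write_viennad(folded[0], f0)
  expect_equal(length(readLines(f0)), 0L)
})

test_that("transcript databases expose biotype and display name from headers", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ENSG0_ENST0_ACTB_mRNA", "ACGTACGTAA",
               ">MIMAT0000062_hsa-let-7a_microRNA", "TGAGGTAGTAGGTTGTATAGTT"), fa)
  db <- read_transcript_db(fa)
  expect_equal(db$info$biotype, c("mRNA", "microRNA"))
  expect_equal(db$info$display_name, c("ACTB", "hsa-let-7a"))
  expect_equal(clashr:::db_subseq(db, "ENSG0_ENST0_ACTB_mRNA", 2, 4), "CGT")
  expect_error(clashr:::db_subseq(db, "ENSG0_ENST0_ACTB_mRNA", 5, 99), "out of range")
  expect_error(read_transcript_db(tempfile()), "")
})
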