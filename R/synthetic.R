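#' Synthetic CLASH fixtures
#'
#' Generators emulating the components of a CLASH sequencing library:
#' a transcript database with redundant isoforms, miRNA-mRNA fusion
#' (chimeric) reads with a ground-truth table, contiguous (non-chimeric)
#' background reads, and multiplexed FASTQ with 5' barcodes and PCR
#' duplicates. All generators are pure functions of their parameters and
#' `seed`: the same seed reproduces byte-identical output without touching
#' the caller's RNG state. Base composition is uniform i.i.d.; multi-mapping
#' is controlled explicitly through the isoform-redundancy knob.
#'
#' @name synthetic
NULL

rand_dna <- function(n, len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic transcript database
#'
#' Random-composition mRNAs (biotype `mRNA`) and 22-nt mature miRNAs
#' (biotype `microRNA`). A fraction of the mRNA genes additionally carry
#' `redundancy - 1` exact-duplicate isoforms (distinct transcript ids, same
#' sequence), emulating databases in which several transcripts of a gene
#' share their exons; fragments from such genes map to many database
#' entries and can exceed the chimera caller's `hmax` multi-mapping cap.
#'
#' @param n_mrna number of distinct mRNA genes.
#' @param n_mirna number of mature miRNAs.
#' @param mrna_len_range length range of the mRNAs, nt.
#' @param redundancy isoform copies per redundant gene (1 = no redundancy).
#' @param redundant_fraction fraction of mRNA genes that are redundant
#'   (default 0.1).
#' @param seed RNG seed.
#' @return a `transcript_db`.
#' @export
make_transcript_db <- function(n_mrna = 50, n_mirna = 10,
                               mrna_len_range = c(300L, 600L),
                               redundancy = 1L, redundant_fraction = 0.1,
                               seed = 1L) {
  stopifnot(n_mrna >= 1, n_mirna >= 0, redundancy >= 1)
  with_seed(seed, {
    lens <- sample(mrna_len_range[1]:mrna_len_range[2], n_mrna, replace = TRUE)
    mrna <- rand_dna(n_mrna, lens)
    ids <- sprintf("ENSG%06d_ENST%06d_GENE%03d_mRNA",
                   seq_len(n_mrna), seq_len(n_mrna), seq_len(n_mrna))
    seqs <- setNames(mrna, ids)
    if (redundancy > 1 && redundant_fraction > 0) {
      n_red <- floor(n_mrna * redundant_fraction)
      if (n_red > 0) {
        red_genes <- seq_len(n_red)  # deterministic: the first genes
        iso <- unlist(lapply(red_genes, function(g) {
          copies <- setNames(
            rep(mrna[g], redundancy - 1L),
            sprintf("ENSG%06d_ENST%06d_GENE%03d_mRNA",
                    g, n_mrna + (g - 1L) * (redundancy - 1L) + seq_len(redundancy - 1L), g))
          copies
        }))
        seqs <- c(seqs, iso)
      }
    }
    if (n_mirna > 0) {
      mir <- rand_dna(n_mirna, rep(22L, n_mirna))
      names(mir) <- sprintf("MIMAT%07d_syn-miR-%d_microRNA", seq_len(n_mirna),
                            seq_len(n_mirna))
      seqs <- c(seqs, mir)
    }
    transcript_db(seqs)
  })
}

#' Generate miRNA-mRNA fusion reads with ground truth
#'
#' Each read is the concatenation of one mature miRNA and one `frag_len`-nt
#' mRNA segment (order controlled by `order`; real chimeras occur in both
#' orders), optionally followed by a 3' linker remnant, optionally with a
#' planted seed-complementary site, emulating the ligated chimeric cDNAs of
#' a CLASH experiment.
#'
#' @param n number of fusion reads.
#' @param db a `transcript_db` containing microRNA and mRNA entries.
#' @param frag_len length of the mRNA segment (default 30).
#' @param order `"mirna_first"`, `"mrna_first"` or `"mixed"`.
#' @param linker optional 3' linker sequence appended to every read (`NULL`
#'   for none).
#' @param plant_site embed the reverse complement of miRNA nt 2-8 inside the
#'   mRNA fragment (planted seed positives for folding/QC statistics).
#' @param seed RNG seed.
#' @return list with `reads` (a [clash_reads], FASTA-style), `truth`
#'   (data.table: `read_id, mirna_id, mrna_id, mirna_first, breakpoint,
#'   mrna_s_start, mrna_s_end`; `breakpoint` is the read position of the
#'   last base of the 5' fragment), and `db` (the database the reads were
#'   drawn from -- with `plant_site` this is a modified copy whose target
#'   windows carry the planted sites, and downstream analysis should use it).
#' @export
make_fusion_reads <- function(n, db, frag_len = 30L,
                              order = c("mirna_first", "mrna_first", "mixed"),
                              linker = NULL, plant_site = FALSE, seed = 1L) {
  order <- match.arg(order)
  info <- db$info
  mirna_ids <- info$full_id[info$biotype == "microRNA"]
  # one segment source per gene (first transcript of each display name), so
  # database redundancy affects mapping, not the sampling of fragments
  mrna_info <- info[info$biotype == "mRNA"]
  mrna_ids <- mrna_info$full_id[!duplicated(mrna_info$display_name)]
  if (length(mirna_ids) == 0 || length(mrna_ids) == 0)
    stop("database must contain microRNA and mRNA entries")
  with_seed(seed, {
    mir <- sample(mirna_ids, n, replace = TRUE)
    mr <- sample(mrna_ids, n, replace = TRUE)
    mlen <- db_length(db, mr)
    if (plant_site) {
      # write the complement of miRNA nt 2-8 into the database mRNA at the
      # sampled window (targets then genuinely carry their miRNA's site, so
      # database-extracted foldings and seed statistics see it); reads
      # landing in an already-seeded window reuse that window's miRNA
      seqs_db <- db$seq
      slot_owner <- new.env(parent = emptyenv())
      pos <- integer(n)
      for (i in seq_len(n)) {
        nslot <- (mlen[i] %/% frag_len)
        slot <- sample.int(nslot, 1L)
        key <- paste(mr[i], slot)
        owner <- get0(key, envir = slot_owner)
        if (is.null(owner)) assign(key, mir[i], envir = slot_owner)
        else mir[i] <- owner
        pos[i] <- (slot - 1L) * frag_len + 1L
        site <- revcomp(substr(db$seq[[mir[i]]], 2L, 8L))
        at <- pos[i] + frag_len - 12L
        substr(seqs_db[[mr[i]]], at, at + 6L) <- site
      }
      db <- transcript_db(seqs_db)
    } else {
      pos <- vapply(mlen, function(L) sample.int(L - frag_len + 1L, 1L),
                    integer(1))
    }
    mir_first <- switch(order,
                        mirna_first = rep(TRUE, n),
                        mrna_first = rep(FALSE, n),
                        mixed = sample(c(TRUE, FALSE), n, replace = TRUE))
    mir_seq <- unname(db$seq[mir])
    frag <- substr(unname(db$seq[mr]), pos, pos + frag_len - 1L)
    seqs <- ifelse(mir_first, paste0(mir_seq, frag), paste0(frag, mir_seq))
    if (!is.null(linker)) seqs <- paste0(seqs, linker)
    ids <- sprintf("fusion_%05d", seq_len(n))
    truth <- data.table(
      read_id = ids, mirna_id = mir, mrna_id = mr, mirna_first = mir_first,
      breakpoint = ifelse(mir_first, nchar(mir_seq), frag_len),
      mrna_s_start = pos, mrna_s_end = pos + frag_len - 1L)
    list(reads = clash_reads(id = ids, seq = seqs), truth = truth, db = db)
  })
}

#' Generate contiguous (non-chimeric) background reads
#'
#' Each read is a contiguous `read_len`-nt segment of one mRNA; a correct
#' chimera caller must call no chimeras from such a library.
#'
#' @param n number of reads.
#' @param db a `transcript_db`.
#' @param read_len segment length (default 50).
#' @param seed RNG seed.
#' @return a [clash_reads] table.
#' @export
make_contiguous_reads <- function(n, db, read_len = 50L, seed = 1L) {
  mrna_ids <- db$info$full_id[db$info$biotype == "mRNA" &
                                db$info$length >= read_len]
  if (length(mrna_ids) == 0) stop("no mRNA long enough in database")
  with_seed(seed, {
    mr <- sample(mrna_ids, n, replace = TRUE)
    mlen <- db_length(db, mr)
    pos <- vapply(mlen, function(L) sample.int(L - read_len + 1L, 1L), integer(1))
    seqs <- substr(unname(db$seq[mr]), pos, pos + read_len - 1L)
    clash_reads(id = sprintf("contig_%05d", seq_len(n)), seq = seqs)
  })
}

#' Generate a multiplexed FASTQ with barcodes and PCR duplicates
#'
#' Draws `n_molecules` distinct cDNA molecules per sample, assigns each a
#' random barcode fill, prefixes the sample's barcode pattern, and emits
#' PCR duplicates (extra full copies of a molecule, same random barcode) at
#' the given rate.
#'
#' @param barcodes a barcode table from [barcode_specs()].
#' @param n_molecules molecules per sample.
#' @param insert_len insert length range, nt.
#' @param pcr_dup_rate expected number of extra PCR copies per molecule
#'   (Poisson; 0 = no duplication).
#' @param seed RNG seed.
#' @return list with `reads` (multiplexed [clash_reads] with qualities),
#'   `truth` (data.table: `sample, insert, molecule, n_copies, random_fill`).
#' @export
make_multiplexed_fastq <- function(barcodes, n_molecules = 100L,
                                   insert_len = c(20L, 40L),
                                   pcr_dup_rate = 0, seed = 1L) {
  with_seed(seed, {
    out <- list(); truth <- list()
    k <- 0L
    for (i in seq_len(nrow(barcodes))) {
      pat <- strsplit(barcodes$pattern[i], "")[[1]]
      ns <- which(pat == "N")
      lens <- sample(insert_len[1]:insert_len[2], n_molecules, replace = TRUE)
      inserts <- rand_dna(n_molecules, lens)
      fills <- rand_dna(n_molecules, rep(length(ns), n_molecules))
      copies <- 1L + stats::rpois(n_molecules, pcr_dup_rate)
      for (m in seq_len(n_molecules)) {
        bc <- pat
        if (length(ns)) bc[ns] <- strsplit(fills[m], "")[[1]]
        full <- paste0(paste(bc, collapse = ""), inserts[m])
        for (cp in seq_len(copies[m])) {
          k <- k + 1L
          out[[k]] <- data.table(
            id = sprintf("mol_%s_%04d_c%d", barcodes$sample[i], m, cp),
            seq = full, qual = strrep("I", nchar(full)))
        }
      }
      truth[[i]] <- data.table(sample = barcodes$sample[i],
                               molecule = seq_len(n_molecules),
                               insert = inserts, n_copies = copies,
                               random_fill = fills)
    }
    tab <- rbindlist(out)
    # interleave deterministically so samples are mixed as in a real run
    tab <- tab[order(rank(paste(seq, id)))]
    list(reads = clash_reads(id = tab$id, seq = tab$seq, qual = tab$qual),
         truth = rbindlist(truth))
  })
}
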