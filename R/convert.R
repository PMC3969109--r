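#' Convert chimera calls to GFF3
#'
#' Each chimera is split into two GFF3 records, one per fragment, with the
#' transcript as the seqid, 1-based inclusive coordinates identical to the
#' .hyb columns, and attributes carrying the read id, the partner
#' transcript, the fragment index and the folding energy.
#'
#' @param calls a `hyb_calls` table.
#' @param path optional output path; when given, the lines (with the
#'   `##gff-version 3` header) are written there.
#' @return character vector of GFF3 feature lines (2 per chimera), invisibly
#'   when `path` is given.
#' @export
hyb_to_gff <- function(calls, path = NULL) {
  x <- as.data.table(calls)
  gff_attr <- function(read_id, partner, frag, dG) {
    sprintf("ID=%s.%d;read_id=%s;partner=%s;dG=%s",
            read_id, frag, read_id, partner, fmt_num(dG))
  }
  lines <- character(0)
  if (nrow(x) > 0) {
    l1 <- sprintf("%s\tclashr\tchimera_fragment\t%d\t%d\t%s\t+\t.\t%s",
                  x$tx1, x$s1_start, x$s1_end, fmt_num(x$e1),
                  gff_attr(x$read_id, x$tx2, 1L, x$dG))
    l2 <- sprintf("%s\tclashr\tchimera_fragment\t%d\t%d\t%s\t+\t.\t%s",
                  x$tx2, x$s2_start, x$s2_end, fmt_num(x$e2),
                  gff_attr(x$read_id, x$tx1, 2L, x$dG))
    lines <- as.vector(rbind(l1, l2))
  }
  if (!is.null(path)) {
    writeLines(c("##gff-version 3", lines), path)
    return(invisible(lines))
  }
  lines
}

#' Read a transcript-to-genome exon map
#'
#' Accepts either GFF/GTF exon annotations or BED12 transcript models and
#' returns the internal exon table: one row per exon with 1-based inclusive
#' genomic coordinates, ordered 5'->3' along the transcript (for minus-strand
#' transcripts the first exon is the one with the largest genomic
#' coordinate).
#'
#' @param path a `.gff`/`.gff3`/`.gtf` or `.bed` file.
#' @return data.table with columns `tx_id, chrom, start, end, strand`.
#' @export
read_exon_map <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$blocks)) {                       # BED12: one range per tx
    tx <- as.character(md$name)
    blocks <- md$blocks
    rows <- lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]                              # block starts relative to tx start
      data.table(tx_id = tx[i],
                 chrom = as.character(GenomicRanges::seqnames(gr[i])),
                 start = GenomicRanges::start(gr[i]) + GenomicRanges::start(b) - 1L,
                 end = GenomicRanges::start(gr[i]) + GenomicRanges::end(b) - 1L,
                 strand = as.character(GenomicRanges::strand(gr[i])))
    })
    ex <- rbindlist(rows)
  } else {                                         # GFF/GTF exon records
    keep <- if (!is.null(md$type)) as.character(md$type) == "exon"
            else rep(TRUE, length(gr))
    gr <- gr[keep]; md <- S4Vectors::mcols(gr)
    tx <- if (!is.null(md$transcript_id)) as.character(md$transcript_id)
          else if (!is.null(md$Parent)) as.character(unlist(md$Parent))
          else stop("GFF exons need a transcript_id or Parent attribute")
    ex <- data.table(tx_id = tx,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)))
  }
  exon_map(ex)
}

#' @param exons data.frame with columns `tx_id, chrom, start, end, strand`
#'   (1-based inclusive genomic exon coordinates).
#' @rdname read_exon_map
#' @export
exon_map <- function(exons) {
  ex <- as.data.table(exons)[, .(tx_id, chrom, start = as.integer(start),
                                 end = as.integer(end), strand)]
  stopifnot(all(ex$strand %in% c("+", "-")), all(ex$start <= ex$end))
  # order exons 5'->3' in transcript coordinates
  ex <- ex[order(tx_id, ifelse(strand == "-", -start, start))]
  ex[]
}

#' Project transcript coordinates onto the genome
#'
#' Maps a 1-based inclusive transcript interval through the transcript's
#' ordered exon blocks. Intervals crossing splice junctions are split into
#' one genomic interval per exon; minus-strand transcripts reverse the
#' projection. The summed length of the projected intervals always equals
#' the query length.
#'
#' @param tx_id transcript identifier present in `map`.
#' @param s_start,s_end 1-based inclusive transcript interval.
#' @param map exon table from [read_exon_map()] / [exon_map()].
#' @return data.table of genomic intervals `chrom, start, end, strand`, in
#'   transcript (5'->3') order.
#' @export
transcript_to_genome <- function(tx_id, s_start, s_end, map) {
  qid <- tx_id
  ex <- as.data.table(map)[tx_id == qid]
  if (nrow(ex) == 0) stop("transcript not in exon map: ", tx_id)
  widths <- ex$end - ex$start + 1L
  tx_len <- sum(widths)
  if (s_start < 1 || s_end > tx_len || s_start > s_end)
    stop(sprintf("interval [%d,%d] outside transcript %s (length %d)",
                 s_start, s_end, tx_id, tx_len))
  offs <- cumsum(c(0L, widths))  # transcript offset at the start of each exon
  out <- list(); k <- 0L
  for (i in seq_len(nrow(ex))) {
    lo <- max(s_start, offs[i] + 1L)
    hi <- min(s_end, offs[i + 1L])
    if (lo > hi) next
    rel1 <- lo - offs[i]; rel2 <- hi - offs[i]  # 1-based within this exon
    if (ex$strand[i] == "+") {
      g1 <- ex$start[i] + rel1 - 1L; g2 <- ex$start[i] + rel2 - 1L
    } else {
      g1 <- ex$end[i] - rel2 + 1L; g2 <- ex$end[i] - rel1 + 1L
    }
    k <- k + 1L
    out[[k]] <- data.table(chrom = ex$chrom[i], start = g1, end = g2,
                           strand = ex$strand[i])
  }
  rbindlist(out)
}

#' Convert every fragment of a .hyb file to genomic coordinates
#'
#' @param calls a `hyb_calls` table whose transcript ids appear in `map`.
#' @param map exon table from [read_exon_map()].
#' @return data.table with one row per projected genomic block:
#'   `read_id, fragment, tx, chrom, start, end, strand`.
#' @export
hyb_to_genome <- function(calls, map) {
  x <- as.data.table(calls)
  out <- list(); k <- 0L
  for (i in seq_len(nrow(x))) {
    for (frag in 1:2) {
      tx <- if (frag == 1) x$tx1[i] else x$tx2[i]
      ss <- if (frag == 1) x$s1_start[i] else x$s2_start[i]
      se <- if (frag == 1) x$s1_end[i] else x$s2_end[i]
      g <- transcript_to_genome(tx, ss, se, map)
      g[, `:=`(read_id = x$read_id[i], fragment = frag, tx = tx)]
      k <- k + 1L; out[[k]] <- g
    }
  }
  if (k == 0)
    return(data.table(read_id = character(), fragment = integer(),
                      tx = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character()))
  rbindlist(out)[, .(read_id, fragment, tx, chrom, start, end, strand)]
}
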