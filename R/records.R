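#' Sequence read containers
#'
#' Reads are carried through the pipeline as a `clash_reads` object: a
#' [data.table::data.table] with one row per read and columns
#' \describe{
#'   \item{id}{read identifier (character)}
#'   \item{seq}{uppercase DNA sequence over \{A,C,G,T,N\}}
#'   \item{qual}{Phred+33 quality string, or `NA` for FASTA input}
#'   \item{random_tag}{random-barcode prefix recovered at demultiplexing, or `NA`}
#'   \item{rank, n_barcodes, count}{collapse metadata parsed from `K-L_M` /
#'     `K_M` style identifiers (`NA` when absent)}
#' }
#'
#' @param id,seq,qual,random_tag vectors of equal length (qual/random_tag
#'   optional).
#' @return a `clash_reads` data.table.
#' @export
clash_reads <- function(id = character(), seq = character(), qual = NA_character_,
                        random_tag = NA_character_) {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("invalid characters in sequence(s): ", paste(head(which(bad), 3), collapse = ", "))
  if (length(qual) > 1 || !all(is.na(qual))) {
    ql <- nchar(qual); sl <- nchar(seq)
    mism <- !is.na(qual) & ql != sl
    if (any(mism))
      stop("sequence/quality length mismatch for read(s): ",
           paste(head(id[mism], 3), collapse = ", "))
  }
  meta <- parse_collapsed_id(id)
  x <- data.table(id = as.character(id), seq = seq,
                  qual = as.character(qual), random_tag = as.character(random_tag),
                  rank = meta$rank, n_barcodes = meta$n_barcodes, count = meta$count)
  setattr(x, "class", c("clash_reads", class(x)))
  x[]
}

#' Parse collapsed-read identifiers
#'
#' Collapsed reads are named `K_M` (no random barcodes) or `K-L_M` (with
#' barcodes), where K is the frequency rank of the sequence, L the number of
#' distinct random barcodes observed for it, and M the number of reads
#' collapsed. Identifiers not matching either form yield `NA` metadata.
#'
#' @param id character vector of identifiers.
#' @return list with integer vectors `rank`, `n_barcodes`, `count`.
#' @examples
#' parse_collapsed_id("44480_39")  # rank 44480, 39 reads
#' parse_collapsed_id("1-2_3")     # rank 1, 2 barcodes, 3 reads
#' @export
parse_collapsed_id <- function(id) {
  rank <- n_bar <- count <- rep(NA_integer_, length(id))
  m <- regmatches(id, regexec("^([0-9]+)(?:-([0-9]+))?_([0-9]+)$", as.character(id)))
  ok <- lengths(m) == 4L
  if (any(ok)) {
    mm <- do.call(rbind, m[ok])
    rank[ok] <- as.integer(mm[, 2])
    n_bar[ok] <- ifelse(mm[, 3] == "", NA_integer_, suppressWarnings(as.integer(mm[, 3])))
    count[ok] <- as.integer(mm[, 4])
  }
  list(rank = rank, n_barcodes = n_bar, count = count)
}

#' Construct collapsed-read identifiers
#'
#' @param rank frequency rank K (1 = most frequent sequence).
#' @param count number of reads collapsed, M.
#' @param n_barcodes number of distinct random barcodes L, or `NA` to omit.
#' @return character vector `"K-L_M"` or `"K_M"`.
#' @examples
#' collapsed_id(44480, 39)    # "44480_39"
#' collapsed_id(1, 3, 2)      # "1-2_3"
#' @export
collapsed_id <- function(rank, count, n_barcodes = NA_integer_) {
  stopifnot(all(rank >= 1), all(count >= 1))
  if (any(!is.na(n_barcodes) & (n_barcodes < 1 | count < n_barcodes)))
    stop("need count >= n_barcodes >= 1")
  ifelse(is.na(n_barcodes),
         paste0(rank, "_", count),
         paste0(rank, "-", n_barcodes, "_", count))
}

# collapse count M of each read (1 for uncollapsed ids)
read_weight <- function(id) {
  cnt <- parse_collapsed_id(id)$count
  ifelse(is.na(cnt), 1L, cnt)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
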