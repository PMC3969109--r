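#' Read sequencing reads from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file into a
#' [clash_reads] table. Collapse metadata is parsed from identifiers of the
#' form `K_M` / `K-L_M`. Qualities are interpreted as Phred+33; IUPAC
#' ambiguity codes other than N are converted to N.
#'
#' @param path input file; `.gz` handled transparently.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension, default).
#' @return a [clash_reads] data.table, in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2)$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    validate_fastq(path)
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) stop(fastq_error(path, conditionMessage(e))))
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
    qual <- rep(NA_character_, length(x))
  }
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(chartr("RYSWKMBDHV", "NNNNNNNNNN", as.character(x)))
  clash_reads(id = ids, seq = seqs, qual = qual)
}

# structural check of a FASTQ file, reporting the first offending line
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  lines <- readLines(con)
  close(con)
  n <- length(lines)
  if (n == 0) return(invisible(TRUE))
  if (n %% 4 != 0)
    stop(sprintf("malformed FASTQ in %s: truncated record at line %d",
                 path, (n %/% 4) * 4 + 1L))
  heads <- seq(1L, n, by = 4L)
  bad <- which(!startsWith(lines[heads], "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ in %s at line %d: expected '@'",
                 path, heads[bad[1]]))
  bad <- which(!startsWith(lines[heads + 2L], "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ in %s at line %d: expected '+'",
                 path, heads[bad[1]] + 2L))
  bad <- which(nchar(lines[heads + 1L]) != nchar(lines[heads + 3L]))
  if (length(bad))
    stop(sprintf("malformed FASTQ in %s at line %d: sequence/quality length mismatch",
                 path, heads[bad[1]] + 1L))
  invisible(TRUE)
}

# locate the offending record to report a line number on FASTQ parse failure
fastq_error <- function(path, msg) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  n <- 0L
  repeat {
    block <- readLines(con, n = 4L)
    if (length(block) == 0L) break
    if (length(block) < 4L)
      return(sprintf("malformed FASTQ in %s: truncated record at line %d", path, n + 1L))
    if (!startsWith(block[1], "@"))
      return(sprintf("malformed FASTQ in %s at line %d: expected '@'", path, n + 1L))
    if (nchar(block[2]) != nchar(block[4]))
      return(sprintf("malformed FASTQ in %s at line %d: sequence/quality length mismatch",
                     path, n + 2L))
    n <- n + 4L
  }
  sprintf("malformed FASTQ in %s: %s", path, msg)
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads a [clash_reads] table.
#' @param path output file (`.gz` to compress).
#' @param format `"fasta"`, `"fastq"`, or `"auto"`: fastq when all reads carry
#'   qualities, fasta otherwise.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (nrow(reads) > 0 && !anyNA(reads$qual)) "fastq" else "fasta"
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  compress <- grepl("\\.gz$", path)
  if (format == "fastq") {
    if (anyNA(reads$qual)) stop("cannot write FASTQ: some reads lack qualities")
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual),
                                compress = compress)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 20000L,
                                compress = compress)
  }
  invisible(path)
}
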