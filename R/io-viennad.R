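#' The viennad annotated dot-bracket format
#'
#' One fixed-layout block of six lines per folded chimera:
#' \enumerate{
#'   \item read identifier
#'   \item fragment-1 sequence, then transcript id, start, end (tab-separated)
#'   \item fragment-2 sequence, then transcript id, start, end
#'   \item the two fragment sequences joined by `&`
#'   \item dot-bracket structure with `(` pairing fragment 1, `)` fragment 2,
#'     `&` separating the strands
#'   \item `dG = <value> kcal/mol`
#' }
#' Fragment sequences are the database-extracted transcript subsequences that
#' were folded (not the read sequence).
#'
#' @param folded a `hyb_calls` table with folding columns `seq1`, `seq2`,
#'   `structure` and `dG` (as produced by [fold_chimeras()]).
#' @param path output file.
#' @export
write_viennad <- function(folded, path) {
  need <- c("seq1", "seq2", "structure")
  if (nrow(folded) > 0 && !all(need %in% names(folded)))
    stop("calls lack folding results; run fold_chimeras() first")
  if (nrow(folded) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ok <- nchar(folded$structure) ==
    nchar(folded$seq1) + 1L + nchar(folded$seq2)
  if (!all(ok))
    stop("structure/sequence length mismatch at call ", which(!ok)[1])
  blocks <- vapply(seq_len(nrow(folded)), function(i) {
    x <- folded[i]
    paste(c(x$read_id,
            paste(x$seq1, x$tx1, x$s1_start, x$s1_end, sep = "\t"),
            paste(x$seq2, x$tx2, x$s2_start, x$s2_end, sep = "\t"),
            paste0(x$seq1, "&", x$seq2),
            x$structure,
            sprintf("dG = %s kcal/mol", fmt_num(x$dG))),
          collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' @rdname write_viennad
#' @return `read_viennad()` returns a data.table with columns `read_id, seq1,
#'   tx1, s1_start, s1_end, seq2, tx2, s2_start, s2_end, structure, dG`.
#' @export
read_viennad <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 6 != 0)
    stop("viennad file has ", length(lines), " non-empty lines; expected a multiple of 6")
  n <- length(lines) %/% 6
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b <- lines[(i - 1) * 6 + 1:6]
    f1 <- strsplit(b[2], "\t", fixed = TRUE)[[1]]
    f2 <- strsplit(b[3], "\t", fixed = TRUE)[[1]]
    if (length(f1) != 4 || length(f2) != 4)
      stop("malformed viennad fragment line in block ", i)
    dg <- sub("^dG = (.*) kcal/mol$", "\\1", b[6])
    out[[i]] <- data.table(
      read_id = b[1],
      seq1 = f1[1], tx1 = f1[2],
      s1_start = as.integer(f1[3]), s1_end = as.integer(f1[4]),
      seq2 = f2[1], tx2 = f2[2],
      s2_start = as.integer(f2[3]), s2_end = as.integer(f2[4]),
      structure = b[5],
      dG = suppressWarnings(as.numeric(ifelse(dg == ".", NA, dg))))
  }
  rbindlist(out)
}
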