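#' The .hyb chimera format
#'
#' One chimera per line, 15 tab-separated columns plus an optional 16th:
#' \enumerate{
#'   \item unique read identifier
#'   \item read sequence
#'   \item predicted duplex binding energy in kcal/mol (`.` when not folded)
#'   \item[4-9] first fragment: matched transcript, read start, read end,
#'     transcript start, transcript end, e-value
#'   \item[10-15] second fragment, same six columns
#'   \item[16] optional annotations `"feature1=value1; feature2=value2;"`
#' }
#' All coordinates are 1-based inclusive; fragments are stored in read order
#' (fragment 1 starts at or before fragment 2 in the read).
#'
#' In memory a set of calls is a `hyb_calls` data.table with columns
#' `read_id, read_seq, dG, tx1, q1_start, q1_end, s1_start, s1_end, e1,
#' tx2, q2_start, q2_end, s2_start, s2_end, e2, annotation`.
#'
#' @param path file to read or write.
#' @return `read_hyb()` returns a `hyb_calls` data.table in file order.
#' @name hyb_format
NULL

hyb_cols <- c("read_id", "read_seq", "dG",
              "tx1", "q1_start", "q1_end", "s1_start", "s1_end", "e1",
              "tx2", "q2_start", "q2_end", "s2_start", "s2_end", "e2",
              "annotation")

empty_calls <- function() {
  x <- data.table(read_id = character(), read_seq = character(), dG = numeric(),
                  tx1 = character(), q1_start = integer(), q1_end = integer(),
                  s1_start = integer(), s1_end = integer(), e1 = numeric(),
                  tx2 = character(), q2_start = integer(), q2_end = integer(),
                  s2_start = integer(), s2_end = integer(), e2 = numeric(),
                  annotation = character())
  setattr(x, "class", c("hyb_calls", class(x)))
  x[]
}

as_hyb_calls <- function(x) {
  setDT(x)
  for (col in setdiff(hyb_cols, names(x)))
    x[, (col) := if (col %in% c("dG", "e1", "e2")) NA_real_ else NA_character_]
  setcolorder(x, hyb_cols)
  if (!inherits(x, "hyb_calls"))
    setattr(x, "class", c("hyb_calls", class(x)))
  x[]
}

validate_calls <- function(calls) {
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(calls$q1_start > calls$q2_start))
    stop("invalid chimera call: fragments not in read order at row ",
         which(calls$q1_start > calls$q2_start)[1])
  coord_ok <- calls$q1_start >= 1 & calls$q1_start <= calls$q1_end &
    calls$q2_start >= 1 & calls$q2_start <= calls$q2_end &
    calls$s1_start >= 1 & calls$s1_start <= calls$s1_end &
    calls$s2_start >= 1 & calls$s2_start <= calls$s2_end
  if (!all(coord_ok))
    stop("invalid chimera call: bad coordinates at row ", which(!coord_ok)[1])
  invisible(calls)
}

#' @rdname hyb_format
#' @export
read_hyb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_calls())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(!lengths(fields) %in% c(15L, 16L))
  if (length(bad))
    stop(sprintf(".hyb line %d: expected 15 or 16 columns, found %d",
                 bad[1], lengths(fields)[bad[1]]))
  get <- function(j) vapply(fields, function(f) if (j <= length(f)) f[j] else NA_character_,
                            character(1))
  num <- function(j) {
    v <- get(j)
    out <- suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
    bad <- which(is.na(out) & v != ".")
    if (length(bad)) stop(sprintf(".hyb line %d: non-numeric value '%s'", bad[1], v[bad[1]]))
    out
  }
  calls <- data.table(
    read_id = get(1), read_seq = get(2), dG = num(3),
    tx1 = get(4), q1_start = as.integer(num(5)), q1_end = as.integer(num(6)),
    s1_start = as.integer(num(7)), s1_end = as.integer(num(8)), e1 = num(9),
    tx2 = get(10), q2_start = as.integer(num(11)), q2_end = as.integer(num(12)),
    s2_start = as.integer(num(13)), s2_end = as.integer(num(14)), e2 = num(15),
    annotation = get(16))
  calls <- as_hyb_calls(calls)
  validate_calls(calls)
  calls
}

#' @param calls a `hyb_calls` table satisfying the call invariants.
#' @rdname hyb_format
#' @export
write_hyb <- function(calls, path) {
  validate_calls(calls)
  lines <- hyb_lines(calls)
  writeLines(lines, path)
  invisible(path)
}

hyb_lines <- function(calls) {
  if (nrow(calls) == 0) return(character())
  base <- sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%s",
                  calls$read_id, ifelse(is.na(calls$read_seq), ".", calls$read_seq),
                  fmt_num(calls$dG),
                  calls$tx1, calls$q1_start, calls$q1_end,
                  calls$s1_start, calls$s1_end, fmt_num(calls$e1),
                  calls$tx2, calls$q2_start, calls$q2_end,
                  calls$s2_start, calls$s2_end, fmt_num(calls$e2))
  ann <- calls$annotation
  ifelse(is.na(ann), base, paste0(base, "\t", ann))
}
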