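# Genomic intervals are carried throughout the package as data frames with
# columns contig/start/end in 0-based half-open coordinates (BED convention).
# IRanges backs the set operations; the +-1 shift to 1-based closed coordinates
# is confined to the two internal converters below.

#' Construct a validated set of genomic intervals
#'
#' @param contig character vector of contig names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @return A `data.frame` with columns `contig`, `start`, `end`.
#' @export
genomic_intervals <- function(contig = character(), start = integer(),
                              end = integer()) {
  x <- data.frame(contig = as.character(contig),
                  start = as.integer(start),
                  end = as.integer(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("contig", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, ": non-integer coordinates", call. = FALSE)
  if (any(!nzchar(x$contig)))
    stop(what, ": empty contig name", call. = FALSE)
  if (any(x$start < 0L))
    stop(what, ": negative start", call. = FALSE)
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(what, ": start >= end at record ", bad[1L], call. = FALSE)
  invisible(x)
}

# 0-based half-open -> IRanges (1-based closed), one contig at a time
.as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

.from_iranges <- function(ir, contig) {
  data.frame(contig = rep(contig, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

#' Merge overlapping and book-ended intervals
#'
#' Coalesces a set of intervals into its union: overlapping and directly
#' adjacent (book-ended) intervals become a single interval. Output is sorted
#' by contig then start.
#'
#' @param x interval data.frame (contig, start, end; 0-based half-open).
#' @return merged interval data.frame.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) return(genomic_intervals())
  out <- lapply(split(x, x$contig), function(d)
    .from_iranges(IRanges::reduce(.as_iranges(d)), d$contig[1L]))
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect two interval sets
#'
#' Returns the merged intersection of the unions of `a` and `b`.
#'
#' @param a,b interval data.frames (0-based half-open).
#' @return interval data.frame of the intersection.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  contigs <- intersect(unique(a$contig), unique(b$contig))
  if (length(contigs) == 0L || nrow(a) == 0L || nrow(b) == 0L)
    return(genomic_intervals())
  out <- lapply(contigs, function(ct) {
    ia <- IRanges::reduce(.as_iranges(a[a$contig == ct, , drop = FALSE]))
    ib <- IRanges::reduce(.as_iranges(b[b$contig == ct, , drop = FALSE]))
    .from_iranges(IRanges::intersect(ia, ib), ct)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test which intervals in `a` overlap any interval in `b`
#'
#' Overlap means at least one shared base pair.
#'
#' @param a,b interval data.frames (0-based half-open).
#' @return logical vector, one entry per row of `a`.
#' @export
overlaps_any <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  hit <- rep(FALSE, nrow(a))
  for (ct in intersect(unique(a$contig), unique(b$contig))) {
    ai <- which(a$contig == ct)
    n <- IRanges::countOverlaps(.as_iranges(a[ai, , drop = FALSE]),
                                .as_iranges(b[b$contig == ct, , drop = FALSE]))
    hit[ai] <- n > 0L
  }
  hit
}

#' Read a BED3+ file as genomic intervals
#'
#' Strict reader for the first three BED columns (contig, start, end;
#' 0-based half-open). Extra columns are ignored; malformed records raise an
#' error naming the offending line.
#'
#' @param path file path.
#' @return interval data.frame in file order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(genomic_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3L))
    stop("BED: fewer than 3 columns at line ", lineno[which(n < 3L)[1L]],
         call. = FALSE)
  ct <- vapply(fields, `[[`, character(1), 1L)
  s_raw <- vapply(fields, `[[`, character(1), 2L)
  e_raw <- vapply(fields, `[[`, character(1), 3L)
  ok <- grepl("^[0-9]+$", s_raw) & grepl("^[0-9]+$", e_raw)
  s <- suppressWarnings(as.integer(s_raw))
  e <- suppressWarnings(as.integer(e_raw))
  bad <- which(!ok | is.na(s) | is.na(e))
  if (length(bad))
    stop("BED: non-integer coordinates at line ", lineno[bad[1L]], call. = FALSE)
  bad <- which(s >= e | s < 0L)
  if (length(bad))
    stop("BED: invalid interval (start >= end) at line ", lineno[bad[1L]],
         call. = FALSE)
  data.frame(contig = ct, start = s, end = e, stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED3
#'
#' @param x interval data.frame.
#' @param path output file path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  utils::write.table(x[, c("contig", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
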