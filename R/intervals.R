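#' Interval set over chromosomes
#'
#' Holds, per chromosome, a set of 1-based closed intervals (e.g. a repeat
#' mask). Intervals are stored sorted and merged where they touch or overlap,
#' so membership queries reduce to a binary search.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (1-based closed).
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(df = data.frame(chrom = character(), start = integer(),
                                         end = integer())) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$end < df$start)) stop("interval end < start")
  by_chrom <- split(df[c("start", "end")], df$chrom)
  ivs <- lapply(by_chrom, function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    cbind(start = IRanges::start(ir), end = IRanges::end(ir))
  })
  structure(list(intervals = ivs), class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  n <- sum(vapply(x$intervals, nrow, integer(1)))
  bp <- sum(vapply(x$intervals, function(m) sum(m[, "end"] - m[, "start"] + 1),
                   numeric(1)))
  cat("Interval set:", n, "interval(s) on", length(x$intervals),
      "chromosome(s),", format(bp, big.mark = ","), "bp\n")
  invisible(x)
}

#' Test positions for interval membership
#'
#' @param iset an [interval_set()].
#' @param chrom chromosome name, scalar or parallel to `pos`.
#' @param pos 1-based positions.
#' @return Logical vector: `TRUE` where the position falls inside an interval.
#' @export
interval_member <- function(iset, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    m <- iset$intervals[[ch]]
    i <- which(chrom == ch)
    if (is.null(m) || nrow(m) == 0L) next
    # merged+sorted, so pos is inside iff the interval whose start precedes it
    # also ends at or after it
    k <- findInterval(pos[i], m[, "start"])
    out[i] <- k >= 1L & pos[i] <= m[cbind(pmax(k, 1L), 2L)]
  }
  out
}

#' Total masked bases per chromosome
#' @param iset an [interval_set()].
#' @return Named numeric vector of covered base counts.
#' @export
interval_coverage <- function(iset) {
  vapply(iset$intervals, function(m) sum(m[, "end"] - m[, "start"] + 1),
         numeric(1))
}

#' Read a mask from BED
#'
#' BED uses 0-based half-open coordinates; they are converted to the package's
#' 1-based closed convention at this boundary.
#'
#' @param path BED file path.
#' @return An [interval_set()]; an empty file yields an empty set.
#' @export
read_mask_bed <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path)
  if (info$size == 0) return(interval_set())
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  interval_set(data.frame(
    chrom = as.character(gr$seqnames),
    start = gr$start,
    end = gr$end))
}

#' Write an interval set to BED
#' @param iset an [interval_set()].
#' @param path output path.
#' @export
write_mask_bed <- function(iset, path) {
  rows <- lapply(names(iset$intervals), function(ch) {
    m <- iset$intervals[[ch]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(chrom = ch, start = m[, "start"] - 1L, end = m[, "end"])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
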