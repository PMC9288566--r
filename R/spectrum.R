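SUB_CLASSES <- c("AC", "AG", "AT", "CA", "CG", "CT",
                 "GA", "GC", "GT", "TA", "TC", "TG")
TS_CLASSES <- c("AG", "GA", "CT", "TC")

#' Classify a single-base substitution
#'
#' @param ref,alt single reference/alternative bases (vectorized).
#' @return data.frame with columns `class` (e.g. `"GA"` for G->A) and
#'   `is_transition` (purine<->purine or pyrimidine<->pyrimidine).
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("classify_substitution expects single bases")
  if (any(ref == alt)) stop("REF equals ALT")
  cls <- paste0(ref, alt)
  if (any(!cls %in% SUB_CLASSES)) stop("non-ACGT substitution")
  data.frame(class = cls, is_transition = cls %in% TS_CLASSES)
}

#' 12-class substitution spectrum with Ts/Tv summary
#'
#' @param x either a data.frame of SNVs with `ref`/`alt` columns, or a named
#'   numeric vector of counts for the 12 classes (AC, AG, ..., TG).
#' @return Object of class `substitution_spectrum`: `counts`, `total`,
#'   `percentages` (2 decimals), `ts_count`, `tv_count`, `ts_tv_ratio`
#'   (2 decimals, `Inf` when there are no transversions) and `gc_to_at_pct`,
#'   the percentage of G->A plus C->T transitions.
#' @export
compute_spectrum <- function(x) {
  if (is.data.frame(x)) {
    snv <- nchar(x$ref) == 1L & nchar(x$alt) == 1L
    if (any(!snv)) stop("compute_spectrum expects SNVs only")
    counts <- table(factor(paste0(toupper(x$ref), toupper(x$alt)),
                           levels = SUB_CLASSES))
    counts <- stats::setNames(as.numeric(counts), SUB_CLASSES)
  } else {
    if (!all(SUB_CLASSES %in% names(x)))
      stop("counts vector must name all 12 substitution classes")
    counts <- as.numeric(x[SUB_CLASSES])
    names(counts) <- SUB_CLASSES
  }
  total <- sum(counts)
  ts <- sum(counts[TS_CLASSES])
  tv <- total - ts
  structure(list(
    counts = counts,
    total = total,
    percentages = if (total > 0) round_half_up(100 * counts / total, 2)
                  else counts * 0,
    ts_count = ts, tv_count = tv,
    ts_tv_ratio = if (tv > 0) round_half_up(ts / tv, 2) else Inf,
    gc_to_at_pct = if (total > 0)
      round_half_up(100 * (counts[["GA"]] + counts[["CT"]]) / total, 1)
      else NA_real_),
    class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("Substitution spectrum (", format(x$total, big.mark = ","),
      " SNVs)\n", sep = "")
  df <- data.frame(class = sub("^(.)(.)$", "\\1>\\2", names(x$counts)),
                   count = x$counts, pct = x$percentages)
  rownames(df) <- NULL
  print(df, row.names = FALSE)
  cat(sprintf("Ts/Tv: %s (%s/%s); G/C->A/T transitions: %s%%\n",
              format(x$ts_tv_ratio), format(x$ts_count, big.mark = ","),
              format(x$tv_count, big.mark = ","), format(x$gc_to_at_pct)))
  invisible(x)
}

#' @export
as.data.frame.substitution_spectrum <- function(x, ...) {
  data.frame(class = names(x$counts), count = as.numeric(x$counts),
             pct = as.numeric(x$percentages))
}

#' Per-plant mutation rate summary
#'
#' @param x either a curated variant data.frame with a `plant_id` column
#'   (SNVs are counted per plant) or a single numeric total SNV count.
#' @param n_plants number of plants in the cohort.
#' @param genome_size reference length in bases used for the per-Mb rate.
#' @return list with `n_plants`, `total_snvs`, `mean_per_plant`,
#'   `min_per_plant`, `max_per_plant`, `rate_per_mb`, `genome_size_bases`.
#' @export
per_plant_rates <- function(x, n_plants, genome_size) {
  if (is.data.frame(x)) {
    snvs <- x[x$variant_class == "SNV", , drop = FALSE]
    per_plant <- table(snvs$plant_id)
    total <- nrow(snvs)
    mn <- if (length(per_plant)) min(per_plant) else 0
    mx <- if (length(per_plant)) max(per_plant) else 0
  } else {
    total <- as.numeric(x)
    mn <- NA_real_; mx <- NA_real_
  }
  mean_pp <- if (n_plants > 0) total / n_plants else NA_real_
  list(n_plants = n_plants, total_snvs = total,
       mean_per_plant = round_half_up(mean_pp, 1),
       min_per_plant = mn, max_per_plant = mx,
       rate_per_mb = round_half_up(mean_pp / (genome_size / 1e6), 2),
       genome_size_bases = genome_size)
}

#' Fraction of variants that are InDels
#'
#' @param n_indels,n_total InDel count and total variant count (SNVs + InDels).
#' @return Percentage, 2 decimals.
#' @export
indel_fraction_pct <- function(n_indels, n_total) {
  if (n_total <= 0) return(NA_real_)
  round_half_up(100 * n_indels / n_total, 2)
}

#' SNV density in genomic windows
#'
#' Tiles each chromosome with fixed-width windows (default: non-overlapping
#' 100-kb tiles; set `step < window_size` for a true sliding window) and
#' counts SNVs whose position falls inside each window. The final window is
#' truncated at the chromosome end.
#'
#' @param snvs data.frame with `chrom` and `pos`.
#' @param genome a [genome_sequence()] (provides chromosome lengths).
#' @param window_size window width in bp.
#' @param step distance between window starts; defaults to `window_size`.
#' @return data.frame with `chrom`, `window_start`, `window_end`, `n_snvs`.
#' @export
window_density <- function(snvs, genome, window_size = 100000L,
                           step = window_size) {
  stopifnot(window_size > 0, step > 0)
  out <- lapply(genome$chrom_names, function(ch) {
    len <- genome$lengths[[ch]]
    starts <- seq.int(1L, len, by = step)
    ends <- pmin(starts + window_size - 1L, len)
    p <- snvs$pos[snvs$chrom == ch]
    n <- vapply(seq_along(starts), function(i)
      sum(p >= starts[i] & p <= ends[i]), numeric(1))
    data.frame(chrom = ch, window_start = starts, window_end = ends, n_snvs = n)
  })
  do.call(rbind, out)
}

#' InDel size distribution
#'
#' @param indels data.frame with `indel_length` (signed: insertions positive,
#'   deletions negative) or with `ref`/`alt` from which lengths are derived.
#' @return list with `histogram` (data.frame length/count), `n_insertions`,
#'   `n_deletions`, `short_fraction` (proportion with |length| < 3 bp).
#' @export
indel_size_histogram <- function(indels) {
  if (!nrow(indels))
    return(list(histogram = data.frame(indel_length = integer(),
                                       count = integer()),
                n_insertions = 0L, n_deletions = 0L,
                short_fraction = NA_real_))
  len <- if ("indel_length" %in% names(indels)) indels$indel_length
         else nchar(indels$alt) - nchar(indels$ref)
  if (any(len == 0L)) stop("zero-length InDel")
  tab <- table(len)
  list(histogram = data.frame(indel_length = as.integer(names(tab)),
                              count = as.integer(tab)),
       n_insertions = sum(len > 0L),
       n_deletions = sum(len < 0L),
       short_fraction = mean(abs(len) < 3L))
}

# round half away from zero, the convention used in the reported tables
# (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
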