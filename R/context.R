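#' Select mutated-guanine sites from a curated set
#'
#' All curated SNVs whose reference base is G (any ALT), in plus-strand
#' reference orientation; C>N variants are not reverse-complemented in,
#' matching a REF-based site definition.
#'
#' @param curated curated variant data.frame.
#' @return data.frame with `chrom`, `pos` of mutated G sites.
#' @export
select_mutated_g <- function(curated) {
  sel <- curated$variant_class == "SNV" & toupper(curated$ref) == "G"
  out <- curated[sel, c("chrom", "pos"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nucleotide frequency profile around a set of sites
#'
#' Computes, for each offset in `-halfwidth..+halfwidth`, the frequency of
#' A/C/G/T among the bases found at that offset from each site. Offsets that
#' fall off a chromosome end (or on an N base) are excluded per site, so each
#' offset has its own denominator.
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param genome a [genome_sequence()].
#' @param halfwidth number of flanking bases on each side.
#' @param label profile label, e.g. `"observed"` or `"null"`.
#' @return Object of class `context_profile`: `freq` (offsets x 4 matrix),
#'   `denominators` (valid site count per offset), `n_sites`, `offsets`,
#'   `label`.
#' @export
profile_context <- function(sites, genome, halfwidth = 20L,
                            label = "observed") {
  offs <- seq.int(-halfwidth, halfwidth)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = length(offs), ncol = 4,
                   dimnames = list(as.character(offs), bases))
  denom <- stats::setNames(integer(length(offs)), as.character(offs))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    len <- genome$lengths[[ch]]
    if (is.null(len)) stop("unknown chromosome: ", ch)
    if (any(p < 1L | p > len)) stop("site outside chromosome ", ch)
    sq <- genome$seq[[ch]]
    for (i in seq_along(offs)) {
      q <- p + offs[i]
      q <- q[q >= 1L & q <= len]
      if (!length(q)) next
      b <- substring(sq, q, q)
      b <- b[b %in% bases]
      if (!length(b)) next
      tab <- table(factor(b, levels = bases))
      counts[i, ] <- counts[i, ] + as.integer(tab)
      denom[i] <- denom[i] + length(b)
    }
  }
  freq <- counts / pmax(denom, 1L)
  freq[denom == 0L, ] <- NA_real_
  structure(list(freq = freq, denominators = denom, n_sites = nrow(sites),
                 offsets = offs, label = label),
            class = "context_profile")
}

#' @export
print.context_profile <- function(x, ...) {
  cat("Context profile (", x$label, "): ", x$n_sites, " site(s), offsets ",
      min(x$offsets), "..", max(x$offsets), "\n", sep = "")
  show <- x$offsets[abs(x$offsets) <= 2]
  print(round(x$freq[as.character(show), , drop = FALSE], 3))
  invisible(x)
}

#' Sample a randomized-G null site set
#'
#' Draws a uniform without-replacement sample of G positions from the
#' genome, the comparison baseline for the mutated-G context profile.
#'
#' @param genome a [genome_sequence()].
#' @param n number of sites to draw; must not exceed the genome's G count.
#' @param rng_seed integer seed recorded for reproducibility; `NULL` uses the
#'   current RNG state.
#' @return data.frame with `chrom`, `pos`.
#' @export
sample_null_g <- function(genome, n, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  g_pos <- lapply(genome$chrom_names, function(ch) {
    p <- gregexpr("G", genome$seq[[ch]], fixed = TRUE)[[1]]
    if (p[1] == -1L) return(NULL)
    data.frame(chrom = ch, pos = as.integer(p))
  })
  g_pos <- do.call(rbind, g_pos)
  if (is.null(g_pos) || nrow(g_pos) < n)
    stop("genome contains fewer than ", n, " G bases")
  out <- g_pos[sort(sample.int(nrow(g_pos), n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed-minus-null context bias report
#'
#' @param observed,null [profile_context()] objects on the same offsets.
#' @param flag_threshold absolute percentage-point difference above which an
#'   offset/base is flagged.
#' @return data.frame with `offset`, `base`, `observed_freq`, `null_freq`,
#'   `difference_pct_points`, `flagged`.
#' @export
bias_report <- function(observed, null, flag_threshold = 5) {
  stopifnot(identical(observed$offsets, null$offsets))
  bases <- colnames(observed$freq)
  out <- expand.grid(offset = observed$offsets, base = bases,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$base), ]
  o <- observed$freq[cbind(as.character(out$offset), out$base)]
  u <- null$freq[cbind(as.character(out$offset), out$base)]
  out$observed_freq <- o
  out$null_freq <- u
  out$difference_pct_points <- 100 * (o - u)
  out$flagged <- !is.na(out$difference_pct_points) &
    abs(out$difference_pct_points) > flag_threshold
  rownames(out) <- NULL
  out
}
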