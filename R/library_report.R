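#' Build an in silico TILLING index
#'
#' Indexes annotated mutations by gene so that reverse-genetic queries
#' ("which plants carry a damaging allele of my gene?") are a lookup rather
#' than a PCR screen.
#'
#' @param annotations output of [annotate_variants()].
#' @return Object of class `tilling_index`.
#' @export
build_tilling_index <- function(annotations) {
  with_gene <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
  structure(list(by_gene = split(with_gene, with_gene$gene_id)),
            class = "tilling_index")
}

#' @export
print.tilling_index <- function(x, ...) {
  cat("In silico TILLING index:", length(x$by_gene), "gene(s),",
      sum(vapply(x$by_gene, nrow, integer(1))), "entries\n")
  invisible(x)
}

#' Query the TILLING index
#'
#' @param index a [build_tilling_index()] result.
#' @param gene_id gene of interest; an unknown gene returns an empty table.
#' @param min_impact minimum impact tier (`MODIFIER` < `LOW` < `MODERATE` <
#'   `HIGH`).
#' @return data.frame of matching annotated mutations.
#' @export
query_tilling <- function(index, gene_id, min_impact = "MODERATE") {
  stopifnot(min_impact %in% names(IMPACT_RANK))
  d <- index$by_gene[[gene_id]]
  if (is.null(d))
    return(data.frame(plant_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene_id = character(), category = character(),
                      impact = character()))
  out <- d[IMPACT_RANK[d$impact] >= IMPACT_RANK[[min_impact]], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transmission summary from a validation table
#'
#' Restricted to confirmed (true-positive) variants, reports how many were
#' transmitted to selfed progeny, separately for SNVs and InDels.
#'
#' @param validation_rows data.frame with `variant_class`, `confirmed` and
#'   `transmitted` columns (logical or yes/no).
#' @return list with `n_tested_snv`, `n_transmitted_snv`, `pct_snv`,
#'   `n_tested_indel`, `n_transmitted_indel`, `pct_indel` (1 decimal;
#'   `NA` when a class has no tested rows).
#' @export
transmission_summary <- function(validation_rows) {
  as_flag <- function(x) {
    if (is.logical(x)) x else tolower(as.character(x)) %in%
      c("yes", "true", "1")
  }
  conf <- as_flag(validation_rows$confirmed)
  trans <- as_flag(validation_rows$transmitted)
  is_snv <- validation_rows$variant_class == "SNV"
  one <- function(sel) {
    n <- sum(sel & conf)
    nt <- sum(sel & conf & trans)
    list(n = n, nt = nt,
         pct = if (n > 0) round_half_up(100 * nt / n, 1) else NA_real_)
  }
  s <- one(is_snv); i <- one(!is_snv)
  list(n_tested_snv = s$n, n_transmitted_snv = s$nt, pct_snv = s$pct,
       n_tested_indel = i$n, n_transmitted_indel = i$nt, pct_indel = i$pct)
}

#' Correlation between mutation count and seed setting
#'
#' @param per_plant_counts named or plain numeric vector of SNV counts.
#' @param phenotypes seed-setting percentages, parallel to the counts.
#' @return list with `pearson_r`, `p_value` (two-sided, from the t
#'   transform with n-2 df) and `n`. A constant phenotype gives `NA`.
#' @export
correlate_seed_setting <- function(per_plant_counts, phenotypes) {
  stopifnot(length(per_plant_counts) == length(phenotypes))
  n <- length(per_plant_counts)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(phenotypes) == 0 || stats::sd(per_plant_counts) == 0)
    return(list(pearson_r = NA_real_, p_value = NA_real_, n = n))
  ct <- stats::cor.test(per_plant_counts, phenotypes, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Cohort-size extrapolation for gene coverage
#'
#' Estimates how many M1 plants are needed for a target fraction of
#' annotated genes to carry at least one qualifying (e.g. high-impact)
#' mutation. The linear model scales plant count proportionally with
#' coverage; the Poisson model treats per-gene hits as Poisson with rate
#' proportional to cohort size, so coverage saturates:
#' `lambda = -log(1 - observed)/observed_n`, `n = -log(1 - target)/lambda`.
#'
#' @param observed_fraction gene-coverage fraction seen in the cohort,
#'   in (0, 1].
#' @param observed_n cohort size that produced it.
#' @param target_fraction desired coverage fraction in (0, 1]; the Poisson
#'   model requires `target_fraction < 1`.
#' @param model `"linear"` or `"poisson"`.
#' @return list with `model`, `observed_coverage_fraction`, `observed_n`,
#'   `target_fraction`, `estimated_n`.
#' @export
saturation_estimate <- function(observed_fraction, observed_n,
                                target_fraction, model = c("linear",
                                                           "poisson")) {
  model <- match.arg(model)
  stopifnot(observed_fraction > 0, observed_fraction <= 1,
            target_fraction > 0, target_fraction <= 1, observed_n > 0)
  est <- if (model == "linear") {
    observed_n * target_fraction / observed_fraction
  } else {
    if (target_fraction >= 1)
      stop("poisson model requires target_fraction < 1")
    lambda <- -log(1 - observed_fraction) / observed_n
    -log(1 - target_fraction) / lambda
  }
  list(model = model, observed_coverage_fraction = observed_fraction,
       observed_n = observed_n, target_fraction = target_fraction,
       estimated_n = est)
}
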