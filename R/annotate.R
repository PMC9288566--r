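EFFECT_CATEGORIES <- c("intergenic", "upstream", "downstream", "intron",
                       "five_prime_utr", "three_prime_utr",
                       "splice_acceptor", "splice_donor",
                       "synonymous", "missense",
                       "stop_gained", "stop_lost", "start_lost",
                       "gene")  # positional-only class used for InDels in genes

IMPACT_OF <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  splice_acceptor = "HIGH", splice_donor = "HIGH",
  missense = "MODERATE",
  synonymous = "LOW",
  intergenic = "MODIFIER", upstream = "MODIFIER", downstream = "MODIFIER",
  intron = "MODIFIER", five_prime_utr = "MODIFIER",
  three_prime_utr = "MODIFIER", gene = "MODIFIER")

IMPACT_RANK <- c(HIGH = 4L, MODERATE = 3L, LOW = 2L, MODIFIER = 1L)

# Standard genetic code, written out so translation is self-contained.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate codons with the standard genetic code
#' @param codons character vector of 3-base codons; partial or N-containing
#'   codons translate to `"X"`.
#' @return Amino-acid characters (`"*"` for stop).
#' @export
translate_codon <- function(codons) {
  aa <- CODON_TABLE[toupper(codons)]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# CDS coordinate (1-based, transcript orientation) of a genomic position
# inside CDS interval k of a model; NA when outside all intervals.
.cds_coordinate <- function(model, pos) {
  cds <- model$cds
  k <- which(pos >= cds[, "start"] & pos <= cds[, "end"])
  if (!length(k)) return(NA_integer_)
  lens <- cds[, "end"] - cds[, "start"] + 1L
  if (model$strand == "+") {
    before <- if (k > 1L) sum(lens[seq_len(k - 1L)]) else 0L
    before + (pos - cds[k, "start"] + 1L)
  } else {
    after <- if (k < nrow(cds)) sum(lens[(k + 1L):nrow(cds)]) else 0L
    after + (cds[k, "end"] - pos + 1L)
  }
}

# Classify one variant against one gene model. Returns NULL when the variant
# lies outside the gene span and its upstream/downstream window.
.classify_against_gene <- function(chrom, pos, ref, alt, is_snv, model,
                                   cds_seq, upstream_window) {
  strand <- model$strand
  in_span <- pos >= model$gene_start && pos <= model$gene_end
  if (!in_span) {
    if (pos >= model$gene_start - upstream_window && pos < model$gene_start)
      return(list(category = if (strand == "+") "upstream" else "downstream"))
    if (pos > model$gene_end && pos <= model$gene_end + upstream_window)
      return(list(category = if (strand == "+") "downstream" else "upstream"))
    return(NULL)
  }
  if (!is_snv) return(list(category = "gene"))
  cds_pos <- .cds_coordinate(model, pos)
  if (!is.na(cds_pos)) {
    ci <- (cds_pos - 1L) %/% 3L + 1L
    off <- (cds_pos - 1L) %% 3L + 1L
    ref_codon <- substring(cds_seq, 3L * ci - 2L, 3L * ci)
    tx_ref <- if (strand == "+") ref else REV_COMP[[ref]]
    tx_alt <- if (strand == "+") alt else REV_COMP[[alt]]
    if (nchar(ref_codon) >= off && substring(ref_codon, off, off) != tx_ref)
      stop(sprintf("REF mismatch at %s:%d (genome %s, variant %s)",
                   chrom, pos, substring(ref_codon, off, off), tx_ref))
    alt_codon <- ref_codon
    substring(alt_codon, off, off) <- tx_alt
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    category <-
      if (ci == 1L && ref_codon == "ATG" && alt_codon != "ATG") "start_lost"
      else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
      else if (alt_aa == "*" && ref_aa != "*") "stop_gained"
      else if (ref_aa != alt_aa) "missense"
      else "synonymous"
    return(list(category = category, ref_aa = ref_aa, aa_pos = ci,
                alt_aa = alt_aa, flagged = !model$complete))
  }
  # splice sites: the two intronic bases flanking each exon junction
  ex <- model$exons
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      is_ <- ex[i, "end"] + 1L      # intron start (genomic)
      ie_ <- ex[i + 1L, "start"] - 1L
      if (ie_ - is_ + 1L < 1L) next
      five_side <- pos %in% c(is_, min(is_ + 1L, ie_))
      three_side <- pos %in% c(max(ie_ - 1L, is_), ie_)
      if (five_side || three_side) {
        donor_side <- if (strand == "+") five_side else three_side
        return(list(category = if (donor_side) "splice_donor"
                               else "splice_acceptor"))
      }
    }
  }
  in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
  if (in_exon) {
    cds_lo <- min(model$cds[, "start"]); cds_hi <- max(model$cds[, "end"])
    left_of_cds <- pos < cds_lo
    right_of_cds <- pos > cds_hi
    if (left_of_cds || right_of_cds) {
      five <- if (strand == "+") left_of_cds else right_of_cds
      return(list(category = if (five) "five_prime_utr" else "three_prime_utr"))
    }
    return(list(category = "intron"))  # exon gap inside CDS span; degenerate
  }
  list(category = "intron")
}

#' Annotate variants against longest-isoform gene models
#'
#' Reimplements variant-effect classification from first principles. SNVs in
#' coding sequence are classified by translating the reference and alternate
#' codons with the standard genetic code, strand-aware (minus-strand alleles
#' are complemented into transcript frame): a disrupted initial ATG is
#' `start_lost`, a destroyed stop is `stop_lost`, a created stop
#' `stop_gained`, other amino-acid changes `missense`, the rest `synonymous`.
#' The two canonical intronic bases at each exon junction are
#' `splice_donor`/`splice_acceptor`. Non-coding positions get
#' `five_prime_utr`/`three_prime_utr`/`intron`, and positions within
#' `upstream_window` of a gene span are `upstream`/`downstream`
#' (strand-aware); everything else is `intergenic`. InDels are annotated
#' positionally only: `gene` when inside a gene span, else
#' upstream/downstream/intergenic.
#'
#' One row is emitted per (variant, overlapping gene); a variant touching no
#' gene or window yields a single `intergenic` row with `gene_id = NA`.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `plant_id`, `variant_class`).
#' @param gset a [gene_model_set()].
#' @param genome a [genome_sequence()]; the REF allele must match it.
#' @param upstream_window bp flanking a gene span still reported as
#'   upstream/downstream (default 5000).
#' @return data.frame with columns `plant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `transcript_id`, `category`, `impact`, `ref_aa`, `aa_pos`,
#'   `alt_aa`, `flagged`.
#' @export
annotate_variants <- function(variants, gset, genome, upstream_window = 5000L) {
  n <- nrow(variants)
  empty <- data.frame(plant_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene_id = character(), transcript_id = character(),
                      category = character(), impact = character(),
                      ref_aa = character(), aa_pos = integer(),
                      alt_aa = character(), flagged = logical())
  if (!n) return(empty)
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  # REF consistency guard against the genome (first base for InDels)
  base1 <- genome_base(genome, variants$chrom, variants$pos)
  ref1 <- toupper(substring(variants$ref, 1L, 1L))
  if (any(base1 != ref1 & base1 != "N"))
    stop("REF allele does not match the genome at ",
         variants$chrom[base1 != ref1][1], ":",
         variants$pos[base1 != ref1][1])
  plant <- if ("plant_id" %in% names(variants)) variants$plant_id
           else rep(NA_character_, n)
  idx <- gset$index
  cds_cache <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  for (v in seq_len(n)) {
    ch <- variants$chrom[v]; p <- variants$pos[v]
    g_hit <- which(idx$chrom == ch &
                   p >= idx$start - upstream_window &
                   p <= idx$end + upstream_window)
    recs <- list()
    for (g in g_hit) {
      m <- gset$models[[g]]
      key <- m$transcript_id
      if (is.null(cds_cache[[key]]))
        cds_cache[[key]] <- cds_sequence(m, genome)
      cl <- .classify_against_gene(ch, p, toupper(variants$ref[v]),
                                   toupper(variants$alt[v]), is_snv[v],
                                   m, cds_cache[[key]], upstream_window)
      if (is.null(cl)) next
      recs[[length(recs) + 1L]] <- data.frame(
        plant_id = plant[v], chrom = ch, pos = p,
        ref = variants$ref[v], alt = variants$alt[v],
        gene_id = m$gene_id, transcript_id = m$transcript_id,
        category = cl$category, impact = IMPACT_OF[[cl$category]],
        ref_aa = if (is.null(cl$ref_aa)) NA_character_ else cl$ref_aa,
        aa_pos = if (is.null(cl$aa_pos)) NA_integer_ else cl$aa_pos,
        alt_aa = if (is.null(cl$alt_aa)) NA_character_ else cl$alt_aa,
        flagged = isTRUE(cl$flagged))
    }
    if (!length(recs))
      recs[[1L]] <- data.frame(
        plant_id = plant[v], chrom = ch, pos = p,
        ref = variants$ref[v], alt = variants$alt[v],
        gene_id = NA_character_, transcript_id = NA_character_,
        category = "intergenic", impact = "MODIFIER",
        ref_aa = NA_character_, aa_pos = NA_integer_,
        alt_aa = NA_character_, flagged = FALSE)
    rows[[v]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# severity ranking: impact first, then the fixed category order
.severity <- function(category) {
  IMPACT_RANK[IMPACT_OF[category]] * 100L -
    match(category, EFFECT_CATEGORIES)
}

#' Most-severe annotation per variant
#'
#' Collapses multi-gene annotations to a single row per variant, keeping the
#' highest-impact category (HIGH > MODERATE > LOW > MODIFIER, ties broken by
#' a fixed category order).
#'
#' @param annotations output of [annotate_variants()].
#' @return One row per distinct (chrom, pos, ref, alt, plant_id) variant.
#' @export
most_severe_per_variant <- function(annotations) {
  if (!nrow(annotations)) return(annotations)
  key <- paste(annotations$plant_id, annotations$chrom, annotations$pos,
               annotations$ref, annotations$alt, sep = "\r")
  sev <- .severity(annotations$category)
  o <- order(key, -sev)
  a <- annotations[o, , drop = FALSE]
  out <- a[!duplicated(key[o]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-category SNV distribution
#'
#' @param annotations output of [annotate_variants()]; collapsed to the
#'   most severe annotation per variant before counting.
#' @return data.frame with `category`, `n`, `pct` (1 decimal).
#' @export
category_distribution <- function(annotations) {
  if (!nrow(annotations))
    return(data.frame(category = character(), n = integer(), pct = numeric()))
  ms <- most_severe_per_variant(annotations)
  tab <- table(factor(ms$category, levels = EFFECT_CATEGORIES))
  tab <- tab[tab > 0]
  data.frame(category = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / sum(tab), 1))
}

#' Percentage of annotated genes covered
#' @param n_genes genes carrying at least one variant of the class.
#' @param n_annotated_genes total annotated genes.
#' @return Percentage, 1 decimal.
#' @export
gene_coverage_pct <- function(n_genes, n_annotated_genes) {
  stopifnot(n_genes <= n_annotated_genes)
  round_half_up(100 * n_genes / n_annotated_genes, 1)
}

#' Gene-coverage summary by effect category and impact
#'
#' For each category (and each impact tier), counts SNV annotations and the
#' number of distinct genes carrying at least one, as a proportion of all
#' annotated genes.
#'
#' @param annotations output of [annotate_variants()].
#' @param n_annotated_genes total number of annotated genes in the genome.
#' @return list with `by_category` and `by_impact` data.frames
#'   (`n_snvs`, `n_genes`, `pct_of_annotated_genes`) and `n_annotated_genes`.
#' @export
summarize_gene_coverage <- function(annotations, n_annotated_genes) {
  cats <- EFFECT_CATEGORIES
  with_gene <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    d <- with_gene[with_gene$category == cc, , drop = FALSE]
    ng <- length(unique(d$gene_id))
    data.frame(category = cc, n_snvs = nrow(d), n_genes = ng,
               pct_of_annotated_genes = gene_coverage_pct(ng, n_annotated_genes))
  }))
  by_imp <- do.call(rbind, lapply(names(IMPACT_RANK), function(im) {
    d <- with_gene[with_gene$impact == im, , drop = FALSE]
    ng <- length(unique(d$gene_id))
    data.frame(impact = im, n_snvs = nrow(d), n_genes = ng,
               pct_of_annotated_genes = gene_coverage_pct(ng, n_annotated_genes))
  }))
  list(by_category = by_cat[by_cat$n_snvs > 0 | by_cat$category %in%
                              c("missense", "stop_gained", "synonymous"), ],
       by_impact = by_imp, n_annotated_genes = n_annotated_genes)
}
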