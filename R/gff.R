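#' Single gene model (one representative transcript)
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds matrix/data.frame with columns `start`, `end` (1-based closed),
#'   sorted in genome order, non-overlapping.
#' @param exons exon intervals in the same layout; defaults to `cds`.
#' @param gene_start,gene_end gene span; defaults to the exon span.
#' @return Object of class `gene_model`. `complete` flags whether the summed
#'   CDS length is divisible by 3; incomplete models are kept but flagged.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, cds,
                       exons = cds, gene_start = NULL, gene_end = NULL) {
  stopifnot(strand %in% c("+", "-"))
  cds <- as.matrix(as.data.frame(cds)[c("start", "end")])
  exons <- as.matrix(as.data.frame(exons)[c("start", "end")])
  cds <- cds[order(cds[, "start"]), , drop = FALSE]
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(cds) > 1L && any(cds[-1L, "start"] <= cds[-nrow(cds), "end"]))
    stop("overlapping CDS intervals in ", transcript_id)
  cds_len <- sum(cds[, "end"] - cds[, "start"] + 1L)
  if (is.null(gene_start)) gene_start <- min(exons[, "start"])
  if (is.null(gene_end)) gene_end <- max(exons[, "end"])
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, cds = cds, exons = exons,
                 gene_start = gene_start, gene_end = gene_end,
                 cds_len = cds_len, complete = (cds_len %% 3L == 0L)),
            class = "gene_model")
}

#' Collection of gene models with a positional index
#' @param models list of [gene_model()] objects.
#' @return Object of class `gene_model_set` with a data.frame `index`.
#' @export
gene_model_set <- function(models) {
  idx <- if (length(models)) {
    data.frame(
      gene_id = vapply(models, `[[`, "", "gene_id"),
      transcript_id = vapply(models, `[[`, "", "transcript_id"),
      chrom = vapply(models, `[[`, "", "chrom"),
      strand = vapply(models, `[[`, "", "strand"),
      start = vapply(models, `[[`, 0, "gene_start"),
      end = vapply(models, `[[`, 0, "gene_end"),
      cds_len = vapply(models, `[[`, 0, "cds_len"),
      complete = vapply(models, `[[`, TRUE, "complete"))
  } else {
    data.frame(gene_id = character(), transcript_id = character(),
               chrom = character(), strand = character(), start = numeric(),
               end = numeric(), cds_len = numeric(), complete = logical())
  }
  structure(list(models = models, index = idx), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("Gene model set:", length(x$models), "gene(s)")
  if (length(x$models))
    cat(",", sum(!x$index$complete), "with CDS length not divisible by 3")
  cat("\n")
  invisible(x)
}

#' Read gene models from GFF3, keeping the longest isoform per gene
#'
#' For every gene the transcript with the greatest total CDS length is
#' retained as its single representative model; ties are broken by the
#' lexicographically smallest transcript id. Genes without any CDS are
#' dropped with a warning. A CDS feature without a parent transcript is an
#' error.
#'
#' @param path GFF3 path with gene/mRNA/CDS (and optionally exon) features
#'   linked by `Parent` attributes.
#' @return A [gene_model_set()].
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- df[df$type == "gene", ]
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  cds <- df[df$type == "CDS", ]
  exons <- df[df$type == "exon", ]
  if (nrow(cds) && anyNA(cds$Parent))
    stop("CDS feature without a parent transcript")
  tx2gene <- stats::setNames(mrna$Parent, mrna$ID)
  if (nrow(cds) && any(!cds$Parent %in% names(tx2gene)))
    stop("CDS feature without a parent transcript")
  models <- list()
  for (g in genes$ID) {
    tx_ids <- sort(mrna$ID[mrna$Parent == g])
    if (!length(tx_ids)) next
    cds_lens <- vapply(tx_ids, function(tx) {
      d <- cds[cds$Parent == tx, ]
      if (!nrow(d)) 0 else sum(d$end - d$start + 1)
    }, numeric(1))
    if (all(cds_lens == 0)) {
      warning("gene ", g, " has no CDS; excluded", call. = FALSE)
      next
    }
    best <- tx_ids[which.max(cds_lens)]  # which.max keeps the first (sorted) tie
    cd <- cds[cds$Parent == best, c("start", "end")]
    ex <- exons[exons$Parent == best, c("start", "end")]
    if (!nrow(ex)) ex <- cd
    grow <- genes[genes$ID == g, ][1, ]
    models[[length(models) + 1L]] <- gene_model(
      gene_id = g, transcript_id = best,
      chrom = as.character(grow$seqnames), strand = as.character(grow$strand),
      cds = cd, exons = ex,
      gene_start = grow$start, gene_end = grow$end)
  }
  gene_model_set(models)
}

#' Write gene models to GFF3
#' @param gset a [gene_model_set()].
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(gset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tmnutill\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, as.integer(start), as.integer(end), strand, attrs)
  for (m in gset$models) {
    writeLines(fmt(m$chrom, "gene", m$gene_start, m$gene_end, m$strand,
                   paste0("ID=", m$gene_id)), con)
    writeLines(fmt(m$chrom, "mRNA", m$gene_start, m$gene_end, m$strand,
                   paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)), con)
    for (i in seq_len(nrow(m$exons)))
      writeLines(fmt(m$chrom, "exon", m$exons[i, "start"], m$exons[i, "end"],
                     m$strand, paste0("Parent=", m$transcript_id)), con)
    for (i in seq_len(nrow(m$cds)))
      writeLines(fmt(m$chrom, "CDS", m$cds[i, "start"], m$cds[i, "end"],
                     m$strand, paste0("Parent=", m$transcript_id)), con)
  }
  invisible(path)
}

# Spliced CDS sequence of a model in transcript orientation (5'->3').
cds_sequence <- function(model, genome) {
  pieces <- vapply(seq_len(nrow(model$cds)), function(i)
    genome_subseq(genome, model$chrom, model$cds[i, "start"], model$cds[i, "end"]),
    character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- revcomp(s) else s
}
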