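# Shared fixtures and independent oracles used across the suite.

# --- tiny hand-built genome/gene fixtures --------------------------------

# plus-strand single-exon gene with CDS "ATGGGGTGGTAA" at 11..22 on a
# 40-bp chromosome
toy_coding_genome <- function() {
  seq <- paste0("TTTTTTTTTT", "ATGGGGTGGTAA", "TTTTTTTTTTTTTTTTTT")
  genome_sequence(c(c1 = seq))
}

toy_coding_gene <- function(strand = "+") {
  gene_model(gene_id = "g1", transcript_id = "g1.1", chrom = "c1",
             strand = strand, cds = data.frame(start = 11, end = 22))
}

# the reverse-complement layout of the plus-strand fixture: same chromosome
# mirrored, gene on the minus strand
toy_coding_genome_rc <- function() {
  g <- toy_coding_genome()
  genome_sequence(c(c1 = revcomp(g$seq[["c1"]])))
}

# build a cohort_vcf in code
make_vcf <- function(chrom, pos, ref, alt, qv, gt_rows, plants) {
  gt <- do.call(rbind, gt_rows)
  cohort_vcf(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        qv = qv), gt, plants)
}

# hand-enumerated 12-record, 3-plant curation fixture:
# 7 unique-het records pass; 2 multi-carrier, 1 hom-alt, 1 low-QV and
# 1 repeat-masked deletion are filtered out (mask covers c1:200-300)
curation_fixture <- function() {
  plants <- c("p1", "p2", "p3")
  HR <- "hom_ref"; HET <- "het"; HA <- "hom_alt"
  rows <- list(
    c(HET, HR, HR),   # 1 pass (SNV)
    c(HR, HET, HR),   # 2 pass (SNV)
    c(HR, HR, HET),   # 3 pass (SNV)
    c(HET, HET, HR),  # 4 multi-carrier
    c(HET, HR, HA),   # 5 multi-carrier
    c(HR, HA, HR),    # 6 hom-alt only
    c(HET, HR, HR),   # 7 low QV
    c(HET, HR, HR),   # 8 pass (deletion outside mask)
    c(HR, HET, HR),   # 9 masked deletion
    c(HR, HET, "missing"), # 10 pass (missing elsewhere ignored)
    c(HR, HR, HET),   # 11 pass (insertion)
    c(HET, HR, HR))   # 12 pass (SNV at masked pos: SNVs ignore the mask)
  vcf <- make_vcf(
    chrom = rep("c1", 12),
    pos = c(10, 20, 30, 40, 50, 60, 70, 80, 210, 90, 100, 250),
    ref = c("G", "C", "G", "A", "T", "G", "G", "ATT", "GCA", "C", "A", "G"),
    alt = c("A", "T", "A", "G", "A", "A", "A", "A", "G", "T", "ACC", "A"),
    qv = c(150, 200, 95, 180, 120, 140, 60, 300, 250, 110, 90, 130),
    gt_rows = rows, plants = plants)
  mask <- interval_set(data.frame(chrom = "c1", start = 200, end = 300))
  list(vcf = vcf, mask = mask, expected_pass = 7L)
}

# --- independent oracles -------------------------------------------------

# brute-force interval membership by scanning every interval
bf_interval_member <- function(df, chrom, pos) {
  mapply(function(ch, p) {
    any(df$chrom == ch & df$start <= p & df$end >= p)
  }, chrom, pos, USE.NAMES = FALSE)
}

# brute-force effect classifier: rebuilds the whole transcript sequence,
# applies the variant to a copy of the genome and re-translates with the
# Biostrings genetic code. Independent of the package's codon arithmetic.
bf_classify_snv <- function(chrom, pos, ref, alt, model, genome, w = 5000) {
  if (chrom != model$chrom) return(NULL)
  st <- model$strand
  if (pos < model$gene_start || pos > model$gene_end) {
    if (pos >= model$gene_start - w && pos < model$gene_start)
      return(if (st == "+") "upstream" else "downstream")
    if (pos > model$gene_end && pos <= model$gene_end + w)
      return(if (st == "+") "downstream" else "upstream")
    return(NULL)
  }
  cds <- model$cds
  in_cds <- any(pos >= cds[, "start"] & pos <= cds[, "end"])
  if (in_cds) {
    build_cds <- function(chrom_seq) {
      s <- paste(vapply(seq_len(nrow(cds)), function(i)
        substring(chrom_seq, cds[i, "start"], cds[i, "end"]), ""),
        collapse = "")
      if (st == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      s
    }
    ref_seq <- genome$seq[[chrom]]
    mut_seq <- ref_seq
    substr(mut_seq, pos, pos) <- alt
    cds_ref <- build_cds(ref_seq)
    cds_mut <- build_cds(mut_seq)
    ncod <- nchar(cds_ref) %/% 3L
    codons <- function(s) substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    cr <- codons(cds_ref); cm <- codons(cds_mut)
    k <- which(cr != cm)
    if (!length(k)) return("synonymous")  # change in a partial tail codon
    k <- k[1]
    tr <- function(cod) unname(Biostrings::GENETIC_CODE[cod])
    ra <- tr(cr[k]); ma <- tr(cm[k])
    if (k == 1 && cr[k] == "ATG" && cm[k] != "ATG") return("start_lost")
    if (ra == "*" && ma != "*") return("stop_lost")
    if (ma == "*" && ra != "*") return("stop_gained")
    if (ra != ma) return("missense")
    return("synonymous")
  }
  ex <- model$exons
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      is_ <- ex[i, "end"] + 1; ie_ <- ex[i + 1, "start"] - 1
      five <- pos >= is_ && pos <= min(is_ + 1, ie_)
      three <- pos >= max(ie_ - 1, is_) && pos <= ie_
      if (five || three) {
        donor <- if (st == "+") five else three
        return(if (donor) "splice_donor" else "splice_acceptor")
      }
    }
  }
  in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
  if (in_exon) {
    # transcript-coordinate route to the UTR side
    tx_pos <- unlist(lapply(seq_len(nrow(ex)), function(i)
      ex[i, "start"]:ex[i, "end"]))
    if (st == "-") tx_pos <- rev(tx_pos)
    cds_pos_g <- unlist(lapply(seq_len(nrow(cds)), function(i)
      cds[i, "start"]:cds[i, "end"]))
    ti <- match(pos, tx_pos)
    ci <- range(match(cds_pos_g, tx_pos))
    if (ti < ci[1]) return("five_prime_utr")
    if (ti > ci[2]) return("three_prime_utr")
    return("intron")
  }
  "intron"
}

# random toy gene set (both strands, multi-exon, with UTR-less CDS models
# plus one UTR-carrying model) for oracle-equivalence tests
random_gene_fixture <- function(seed) {
  set.seed(seed)
  L <- 60000L
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(.282, .218, .218, .282)), collapse = "")
  genome <- genome_sequence(c(cX = seq))
  models <- list()
  cursor <- 1500L
  gi <- 0L
  while (cursor < L - 8000L) {
    gi <- gi + 1L
    k <- sample(1:3, 1)
    exon_lens <- 3L * sample(30:80, k, replace = TRUE)
    intron_lens <- if (k > 1) sample(30:200, k - 1, replace = TRUE) else integer()
    starts <- cursor + cumsum(c(0L, head(exon_lens, -1L) + intron_lens))
    ends <- starts + exon_lens - 1L
    models[[gi]] <- gene_model(
      gene_id = sprintf("tg%02d", gi), transcript_id = sprintf("tg%02d.t", gi),
      chrom = "cX", strand = sample(c("+", "-"), 1),
      cds = data.frame(start = starts, end = ends))
    cursor <- max(ends) + sample(800:4000, 1)
  }
  list(genome = genome, genes = gene_model_set(models))
}
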