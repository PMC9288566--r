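# Substitution counts observed in the 266-plant MNU cohort; their
# proportions are the default class probabilities of the simulator.
MNU_SPECTRUM_COUNTS <- c(
  AC = 1060, AG = 8000, AT = 11768, CA = 7288, CG = 623, CT = 301984,
  GA = 297005, GC = 708, GT = 7336, TA = 11776, TC = 8155, TG = 966)

#' Configuration for the synthetic M1 cohort simulator
#'
#' Defaults reproduce the statistical structure of an MNU-mutagenized rice
#' M1 library: 266 plants; per-plant SNV counts from a lognormal
#' (meanlog 7.49, sdlog 0.9) truncated to \[134, 13222\], matching a mean of
#' 2468.7; the 12-class substitution spectrum of the observed cohort
#' (G/C->A/T transitions dominate, Ts/Tv 14.81); a -1 purine / +1 thymine
#' context bias around mutated guanines (+15.8 points A and +18.7 points G
#' at -1, +6.4 points T at +1, remaining bases renormalized
#' proportionally); a 0.47% InDel fraction with deletions:insertions
#' 2486:632 and ~80% of sizes under 3 bp; false-positive calls with low
#' quality values (FP QV ~ Uniform(30, 100) vs true QV ~ Uniform(60, 500));
#' seed-setting percentages negatively correlated with mutation count
#' (target Pearson r = -0.43 after clamping to \[0, 100\]); and a 15.2%
#' transmission-loss probability.
#'
#' @param n_plants cohort size.
#' @param chrom_lengths integer vector of chromosome lengths (bp), named or
#'   not; defaults to a 1/12-scale genome of 12 x 2.6 Mb chromosomes.
#' @param base_composition named A/C/G/T probabilities for the i.i.d. genome.
#' @param snv_count list: `family` is `"lognormal"` (fields `meanlog`,
#'   `sdlog`, `min`, `max`) or `"fixed"` (field `value`).
#' @param class_probs named 12-vector of substitution-class probabilities.
#' @param context_bias list with `minus1` (named increments, percentage
#'   points/100) and `plus1`.
#' @param indel_fraction expected InDel share of all true variants.
#' @param deletion_prob probability an InDel is a deletion.
#' @param indel_size_geom_p,indel_max_size geometric size parameter and cap.
#' @param fp_rate fraction of emitted VCF records that are false positives.
#' @param fp_qv_range,tp_qv_range uniform QV ranges for false/true calls.
#' @param missing_rate probability a non-carrier genotype is missing.
#' @param phenotype list: `intercept`, `slope` (seed-setting points per
#'   SNV), `noise_sd`, `target_r` (documentation of the calibration target).
#' @param transmission_loss probability a true variant is not transmitted.
#' @param n_validation_snv,n_validation_indel validation-table subsample
#'   sizes.
#' @param gene_fraction,mask_fraction target genome fractions covered by
#'   gene models and by the repeat mask.
#' @param rng_seed integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_plants = 266L,
    chrom_lengths = rep(2.6e6, 12),
    base_composition = c(A = 0.282, C = 0.218, G = 0.218, T = 0.282),
    snv_count = list(family = "lognormal", meanlog = 7.49, sdlog = 0.9,
                     min = 134, max = 13222),
    class_probs = MNU_SPECTRUM_COUNTS / sum(MNU_SPECTRUM_COUNTS),
    context_bias = list(minus1 = c(A = 0.158, G = 0.187),
                        plus1 = c(T = 0.064)),
    indel_fraction = 0.0047,
    deletion_prob = 2486 / 3118,
    indel_size_geom_p = 0.555,
    indel_max_size = 15L,
    fp_rate = 0.1,
    fp_qv_range = c(30, 100),
    tp_qv_range = c(60, 500),
    missing_rate = 0.02,
    phenotype = list(intercept = 48, slope = -0.006, noise_sd = 22.5,
                     target_r = -0.43),
    transmission_loss = 0.152,
    n_validation_snv = 101L,
    n_validation_indel = 16L,
    gene_fraction = 0.3,
    mask_fraction = 0.3,
    rng_seed = 1L) {
  stopifnot(all(chrom_lengths >= 1e4),
            abs(sum(base_composition) - 1) < 1e-8,
            abs(sum(class_probs) - 1) < 1e-8,
            setequal(names(class_probs), SUB_CLASSES),
            indel_fraction >= 0, indel_fraction <= 1,
            fp_rate >= 0, fp_rate < 1,
            transmission_loss >= 0, transmission_loss <= 1,
            missing_rate >= 0, missing_rate < 1,
            gene_fraction >= 0, gene_fraction < 1,
            mask_fraction >= 0, mask_fraction < 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%02d", seq_along(chrom_lengths))
  structure(list(
    n_plants = as.integer(n_plants), chrom_lengths = chrom_lengths,
    base_composition = base_composition[c("A", "C", "G", "T")],
    snv_count = snv_count, class_probs = class_probs[SUB_CLASSES],
    context_bias = context_bias, indel_fraction = indel_fraction,
    deletion_prob = deletion_prob, indel_size_geom_p = indel_size_geom_p,
    indel_max_size = as.integer(indel_max_size), fp_rate = fp_rate,
    fp_qv_range = fp_qv_range, tp_qv_range = tp_qv_range,
    missing_rate = missing_rate, phenotype = phenotype,
    transmission_loss = transmission_loss,
    n_validation_snv = as.integer(n_validation_snv),
    n_validation_indel = as.integer(n_validation_indel),
    gene_fraction = gene_fraction, mask_fraction = mask_fraction,
    rng_seed = rng_seed), class = "cohort_sim_config")
}

.draw_snv_counts <- function(config, n) {
  sc <- config$snv_count
  if (identical(sc$family, "fixed")) return(rep(as.integer(sc$value), n))
  if (!identical(sc$family, "lognormal"))
    stop("unsupported snv_count family: ", sc$family)
  x <- stats::rlnorm(n, sc$meanlog, sc$sdlog)
  while (any(bad <- x < sc$min | x > sc$max))
    x[bad] <- stats::rlnorm(sum(bad), sc$meanlog, sc$sdlog)
  as.integer(round(x))
}

#' Simulate a toy genome, gene models and repeat mask
#'
#' Bases are i.i.d. at the configured composition. Non-overlapping
#' multi-exon protein-coding genes are placed on both strands until the
#' target genic fraction is reached; each gets an ATG start and a TAA stop
#' written into the sequence so coding annotation is exercised end-to-end.
#' The mask covers approximately `mask_fraction` of the genome with random
#' intervals.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `genome` ([genome_sequence()]), `genes`
#'   ([gene_model_set()]) and `mask` ([interval_set()]).
#' @export
simulate_genome <- function(config) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  bases <- c("A", "C", "G", "T")
  raws <- lapply(config$chrom_lengths, function(L)
    charToRaw(paste(sample(bases, L, replace = TRUE,
                           prob = config$base_composition), collapse = "")))
  models <- list()
  mask_rows <- list()
  for (ch in names(raws)) {
    L <- length(raws[[ch]])
    # gene placement: cursor walk until the genic fraction is reached
    if (config$gene_fraction > 0) {
      cursor <- sample(2000:6000, 1)
      genic <- 0
      gi <- 0L
      repeat {
        k <- sample(1:4, 1)
        exon_lens <- 3L * sample(40:200, k, replace = TRUE)
        intron_lens <- if (k > 1L) sample(50:500, k - 1L, replace = TRUE)
                       else integer()
        span <- sum(exon_lens) + sum(intron_lens)
        if (cursor + span > L - 2000 ||
            genic / L >= config$gene_fraction) break
        gi <- gi + 1L
        starts <- cursor + cumsum(c(0L, utils::head(exon_lens, -1L) +
                                        intron_lens))
        ends <- starts + exon_lens - 1L
        strand <- sample(c("+", "-"), 1)
        gid <- sprintf("gene_%s_%03d", ch, gi)
        models[[length(models) + 1L]] <- gene_model(
          gene_id = gid, transcript_id = paste0(gid, ".1"),
          chrom = ch, strand = strand,
          cds = data.frame(start = starts, end = ends))
        # force start/stop codons into the sequence, strand-aware
        s5 <- min(starts); e3 <- max(ends)
        if (strand == "+") {
          raws[[ch]][s5:(s5 + 2L)] <- charToRaw("ATG")
          raws[[ch]][(e3 - 2L):e3] <- charToRaw("TAA")
        } else {
          raws[[ch]][(e3 - 2L):e3] <- charToRaw("CAT")
          raws[[ch]][s5:(s5 + 2L)] <- charToRaw("TTA")
        }
        genic <- genic + span
        cursor <- cursor + span + sample(1000:8000, 1)
        if (cursor > L - 2000) break
      }
    }
    # mask placement: interval lengths U(500,5000), gaps sized so the
    # expected coverage matches mask_fraction
    if (config$mask_fraction > 0) {
      f <- config$mask_fraction
      cur <- sample(1:2000, 1)
      repeat {
        len <- sample(500:5000, 1)
        if (cur + len > L) break
        mask_rows[[length(mask_rows) + 1L]] <-
          data.frame(chrom = ch, start = cur, end = cur + len - 1L)
        gap <- sample.int(max(2L, as.integer(2 * len * (1 - f) / f)), 1)
        cur <- cur + len + gap
      }
    }
  }
  seqs <- vapply(raws, rawToChar, character(1))
  mask_df <- if (length(mask_rows)) do.call(rbind, mask_rows)
             else data.frame(chrom = character(), start = integer(),
                             end = integer())
  list(genome = genome_sequence(seqs),
       genes = gene_model_set(models),
       mask = interval_set(mask_df))
}

#' Seed-setting phenotype model
#'
#' Seed-setting percentage is a linear function of the plant's mutation
#' count plus Gaussian noise, clamped to \[0, 100\]. The shipped constants
#' (intercept 48, slope -0.006 per SNV, noise sd 22.5) were calibrated once
#' by Monte Carlo so that a 266-plant cohort at the default count
#' distribution shows a post-clamp Pearson correlation near the -0.43
#' target; clamping slightly attenuates the pre-clamp correlation.
#'
#' @param snv_counts non-negative mutation counts, one per plant.
#' @param config a [cohort_sim_config()].
#' @param rng_seed optional seed; `NULL` uses the current RNG state.
#' @return Numeric vector of seed-setting percentages in \[0, 100\].
#' @export
phenotype_model <- function(snv_counts, config = cohort_sim_config(),
                            rng_seed = NULL) {
  stopifnot(all(snv_counts >= 0))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ph <- config$phenotype
  y <- ph$intercept + ph$slope * snv_counts +
    stats::rnorm(length(snv_counts), 0, ph$noise_sd)
  pmin(pmax(y, 0), 100)
}

# positions of each A/C/G/T base per chromosome, as integer vectors
.base_positions <- function(genome) {
  lapply(genome$seq, function(s) {
    lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
      p <- gregexpr(b, s, fixed = TRUE)[[1]]
      if (p[1] == -1L) integer() else as.integer(p)
    })
  })
}

#' Simulate a joint-genotyped M1 cohort
#'
#' Draws per-plant mutation counts and substitution classes, places each
#' mutation at a uniformly chosen genome position carrying the required REF
#' base (unique across the cohort, heterozygous in exactly one plant),
#' rewrites the -1/+1 neighbors of mutated-G sites according to the
#' configured context bias before the reference is emitted, adds short
#' InDels and false-positive calls with low quality values, and generates
#' seed-setting phenotypes and a Sanger-style validation subsample.
#'
#' @param config a [cohort_sim_config()].
#' @param genome,genes,mask output of [simulate_genome()] (the mask is
#'   carried through for downstream curation; it does not constrain
#'   placement).
#' @return list with `vcf` ([cohort_vcf()]), `truth` (data.frame:
#'   `plant_id`, `chrom`, `pos`, `ref`, `alt`, `qv`, `variant_class`,
#'   `is_true`, `was_transmitted`), `phenotype` (data.frame: `plant_id`,
#'   `n_snv`, `seed_setting_pct`), `validation` (data.frame subsample with
#'   `confirmed`/`transmitted`), and `genome`, the reference with context
#'   bias applied (supersedes the input genome for downstream analysis).
#' @export
simulate_cohort <- function(config, genome, genes = NULL, mask = NULL) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed + 1L)
  plants <- sprintf("M1_%04d", seq_len(config$n_plants))
  n_snv <- .draw_snv_counts(config, config$n_plants)
  n_indel <- stats::rbinom(config$n_plants, n_snv,
                           config$indel_fraction / (1 - config$indel_fraction))

  # --- SNV classes and REF-conditional placement -------------------------
  total_snv <- sum(n_snv)
  cls <- sample(SUB_CLASSES, total_snv, replace = TRUE,
                prob = config$class_probs)
  snv_plant <- rep(plants, n_snv)
  ref_b <- substr(cls, 1L, 1L)
  alt_b <- substr(cls, 2L, 2L)
  pools <- .base_positions(genome)
  chroms <- genome$chrom_names
  snv_chrom <- character(total_snv)
  snv_pos <- integer(total_snv)
  used <- lapply(genome$lengths, function(L) logical(L))
  for (b in c("A", "C", "G", "T")) {
    need <- which(ref_b == b)
    if (!length(need)) next
    pool_sizes <- vapply(chroms, function(ch) length(pools[[ch]][[b]]),
                         numeric(1))
    if (sum(pool_sizes) < length(need))
      stop("genome too small to place requested mutations (", b,
           " pool ", sum(pool_sizes), " < ", length(need), ")")
    flat <- sample.int(sum(pool_sizes), length(need))
    cum <- cumsum(pool_sizes)
    ch_idx <- findInterval(flat - 1L, c(0, cum), rightmost.closed = FALSE)
    off <- flat - c(0, cum)[ch_idx]
    snv_chrom[need] <- chroms[ch_idx]
    for (ci in unique(ch_idx)) {
      sel <- ch_idx == ci
      ch <- chroms[ci]
      p <- pools[[ch]][[b]][off[sel]]
      snv_pos[need[sel]] <- p
      used[[ch]][p] <- TRUE
    }
  }

  # --- context bias: rewrite -1/+1 neighbors of mutated-G sites ----------
  comp <- config$base_composition
  biased_dist <- function(increments) {
    p <- comp
    p[names(increments)] <- p[names(increments)] + increments
    rest <- setdiff(names(p), names(increments))
    p[rest] <- p[rest] * (1 - sum(p[names(increments)])) / sum(comp[rest])
    p / sum(p)
  }
  p_minus1 <- biased_dist(config$context_bias$minus1)
  p_plus1 <- biased_dist(config$context_bias$plus1)
  raws <- lapply(genome$seq, charToRaw)
  g_sites <- which(ref_b == "G")
  for (side in c(-1L, 1L)) {
    pr <- if (side == -1L) p_minus1 else p_plus1
    nb_pos <- snv_pos[g_sites] + side
    for (ch in chroms) {
      sel <- snv_chrom[g_sites] == ch
      q <- nb_pos[sel]
      ok <- q >= 1L & q <= genome$lengths[[ch]]
      q <- q[ok]
      q <- q[!used[[ch]][q]]  # never rewrite a base that is itself a site
      if (!length(q)) next
      raws[[ch]][q] <- charToRaw(paste(
        sample(names(pr), length(q), replace = TRUE, prob = pr),
        collapse = ""))
    }
  }
  genome <- genome_sequence(vapply(raws, rawToChar, character(1)))

  # --- InDels (placed on the final reference) ----------------------------
  total_indel <- sum(n_indel)
  ind_plant <- rep(plants, n_indel)
  ind_chrom <- character(total_indel)
  ind_pos <- integer(total_indel)
  ind_ref <- character(total_indel)
  ind_alt <- character(total_indel)
  if (total_indel) {
    is_del <- stats::runif(total_indel) < config$deletion_prob
    size <- pmin(stats::rgeom(total_indel, config$indel_size_geom_p) + 1L,
                 config$indel_max_size)
    margin <- config$indel_max_size + 1L
    for (i in seq_len(total_indel)) {
      repeat {
        ch <- sample(chroms, 1, prob = genome$lengths / sum(genome$lengths))
        p <- sample.int(genome$lengths[[ch]] - margin, 1)
        if (!used[[ch]][p]) break
      }
      used[[ch]][p] <- TRUE
      ind_chrom[i] <- ch
      ind_pos[i] <- p
      anchor <- genome_subseq(genome, ch, p, p)
      if (is_del[i]) {
        ind_ref[i] <- genome_subseq(genome, ch, p, p + size[i])
        ind_alt[i] <- anchor
      } else {
        ind_ref[i] <- anchor
        ind_alt[i] <- paste0(anchor, paste(
          sample(c("A", "C", "G", "T"), size[i], replace = TRUE,
                 prob = comp), collapse = ""))
      }
    }
  }

  # --- false positives ---------------------------------------------------
  n_true <- total_snv + total_indel
  n_fp <- round(config$fp_rate / (1 - config$fp_rate) * n_true)
  fp_chrom <- character(n_fp); fp_pos <- integer(n_fp)
  fp_ref <- character(n_fp); fp_alt <- character(n_fp)
  if (n_fp > 0) {
    for (i in seq_len(n_fp)) {
      repeat {
        ch <- sample(chroms, 1, prob = genome$lengths / sum(genome$lengths))
        p <- sample.int(genome$lengths[[ch]], 1)
        b <- genome_subseq(genome, ch, p, p)
        if (!used[[ch]][p] && b != "N") break
      }
      used[[ch]][p] <- TRUE
      fp_chrom[i] <- ch; fp_pos[i] <- p; fp_ref[i] <- b
      fp_alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
  }

  # --- assemble records --------------------------------------------------
  rec <- data.frame(
    plant_id = c(snv_plant, ind_plant, if (n_fp) sample(plants, n_fp,
                                                        replace = TRUE)),
    chrom = c(snv_chrom, ind_chrom, fp_chrom),
    pos = c(snv_pos, ind_pos, fp_pos),
    ref = c(ref_b, ind_ref, fp_ref),
    alt = c(alt_b, ind_alt, fp_alt),
    is_true = rep(c(TRUE, FALSE), c(n_true, n_fp)))
  rec$qv <- round(ifelse(rec$is_true,
                         stats::runif(nrow(rec), config$tp_qv_range[1],
                                      config$tp_qv_range[2]),
                         stats::runif(nrow(rec), config$fp_qv_range[1],
                                      config$fp_qv_range[2])), 1)
  vc <- variant_class_of(rec$ref, rec$alt)
  rec$variant_class <- vc$variant_class
  rec$was_transmitted <- ifelse(
    rec$is_true, stats::runif(nrow(rec)) >= config$transmission_loss, NA)
  rec <- rec[order(match(rec$chrom, chroms), rec$pos), , drop = FALSE]
  rownames(rec) <- NULL

  gt <- matrix("hom_ref", nrow(rec), length(plants),
               dimnames = list(NULL, plants))
  if (config$missing_rate > 0 && length(gt)) {
    # sample missing cells by index rather than testing every cell
    n_miss <- stats::rbinom(1, length(gt), config$missing_rate)
    gt[sample.int(length(gt), n_miss)] <- "missing"
  }
  gt[cbind(seq_len(nrow(rec)), match(rec$plant_id, plants))] <- "het"
  vcf <- cohort_vcf(rec[c("chrom", "pos", "ref", "alt", "qv")], gt, plants)

  phen <- data.frame(plant_id = plants, n_snv = n_snv,
                     seed_setting_pct = round(
                       phenotype_model(n_snv, config), 1))

  # validation subsample (SNVs and InDels drawn separately, like a
  # Sanger panel)
  snv_rows <- which(rec$variant_class == "SNV")
  ind_rows <- which(rec$variant_class != "SNV")
  val_idx <- c(
    if (length(snv_rows))
      sort(sample(snv_rows, min(config$n_validation_snv, length(snv_rows)))),
    if (length(ind_rows))
      sort(sample(ind_rows, min(config$n_validation_indel,
                                length(ind_rows)))))
  val <- rec[val_idx, c("plant_id", "chrom", "pos", "ref", "alt",
                        "variant_class", "qv"), drop = FALSE]
  val$confirmed <- ifelse(rec$is_true[val_idx], "yes", "no")
  val$transmitted <- ifelse(!rec$is_true[val_idx], "no",
                            ifelse(rec$was_transmitted[val_idx], "yes", "no"))
  rownames(val) <- NULL

  list(vcf = vcf,
       truth = rec[c("plant_id", "chrom", "pos", "ref", "alt", "qv",
                     "variant_class", "is_true", "was_transmitted")],
       phenotype = phen, validation = val, genome = genome,
       genes = genes, mask = mask)
}

#' Write all simulator outputs to a directory
#'
#' Emits `genome.fa`, `genes.gff3`, `mask.bed`, `cohort.vcf`, `truth.tsv`,
#' `phenotype.tsv` and `validation.tsv`.
#'
#' @param sim output of [simulate_cohort()].
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort_outputs <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  if (!is.null(sim$genes))
    write_gene_models_gff3(sim$genes, file.path(outdir, "genes.gff3"))
  if (!is.null(sim$mask))
    write_mask_bed(sim$mask, file.path(outdir, "mask.bed"))
  write_joint_vcf(sim$vcf, file.path(outdir, "cohort.vcf"),
                  contigs = sim$genome$lengths)
  write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  write_tsv(sim$phenotype, file.path(outdir, "phenotype.tsv"))
  write_tsv(sim$validation, file.path(outdir, "validation.tsv"))
  invisible(outdir)
}
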