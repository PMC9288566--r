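test_that("simulated genomes match the configured base composition", {
  cfg <- cohort_sim_config(n_plants = 2, chrom_lengths = c(a = 1e6),
                           gene_fraction = 0, mask_fraction = 0,
                           rng_seed = 61)
  g <- simulate_genome(cfg)$genome
  comp <- genome_composition(g)
  for (b in names(comp)) {
    p <- cfg$base_composition[[b]]
    expect_lt(abs(comp[[b]] - p), 3 * sqrt(p * (1 - p) / 1e6))
  }
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- cohort_sim_config(n_plants = 3, chrom_lengths = c(a = 1e5),
                           snv_count = list(family = "fixed", value = 80),
                           rng_seed = 67)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(g1$genes$index, g2$genes$index)
  s1 <- simulate_cohort(cfg, g1$genome)
  s2 <- simulate_cohort(cfg, g2$genome)
  p1 <- tempfile(); p2 <- tempfile()
  write_joint_vcf(s1$vcf, p1); write_joint_vcf(s2$vcf, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical output
  expect_identical(s1$phenotype, s2$phenotype)
})

test_that("gene fraction zero produces no gene models", {
  cfg <- cohort_sim_config(n_plants = 2, chrom_lengths = c(a = 5e4),
                           gene_fraction = 0, rng_seed = 71)
  expect_equal(length(simulate_genome(cfg)$genes$models), 0L)
})

test_that("simulated gene models are complete and carry start/stop codons", {
  cfg <- cohort_sim_config(n_plants = 2, chrom_lengths = c(a = 3e5),
                           rng_seed = 73)
  g <- simulate_genome(cfg)
  expect_gt(length(g$genes$models), 5L)
  expect_true(all(g$genes$index$complete))
  for (m in g$genes$models[1:5]) {
    cds <- cds_sequence(m, g$genome)
    expect_identical(substring(cds, 1, 3), "ATG")
    expect_identical(substring(cds, nchar(cds) - 2, nchar(cds)), "TAA")
  }
})

test_that("every true variant is heterozygous in exactly one plant", {
  cfg <- cohort_sim_config(n_plants = 5, chrom_lengths = c(a = 4e5),
                           snv_count = list(family = "fixed", value = 300),
                           rng_seed = 79)
  g <- simulate_genome(cfg)
  sim <- simulate_cohort(cfg, g$genome)
  gt <- sim$vcf$genotypes
  non_ref <- gt == "het" | gt == "hom_alt"
  expect_true(all(rowSums(non_ref) == 1L))
  expect_true(all(gt[non_ref] == "het"))
  # truth rows correspond one-to-one with emitted records
  expect_equal(nrow(sim$truth), nrow(sim$vcf$variants))
  expect_false(any(duplicated(paste(sim$truth$chrom, sim$truth$pos))))
})

test_that("REF alleles always match the emitted reference genome", {
  cfg <- cohort_sim_config(n_plants = 4, chrom_lengths = c(a = 2e5, b = 1e5),
                           snv_count = list(family = "fixed", value = 150),
                           rng_seed = 83)
  g <- simulate_genome(cfg)
  sim <- simulate_cohort(cfg, g$genome)
  v <- sim$vcf$variants
  first <- genome_base(sim$genome, v$chrom, v$pos)
  expect_identical(first, substring(v$ref, 1, 1))
  # full REF string for InDels
  ind <- v[nchar(v$ref) > 1, ]
  if (nrow(ind)) {
    full <- mapply(function(ch, p, r) genome_subseq(sim$genome, ch, p,
                                                    p + nchar(r) - 1L),
                   ind$chrom, ind$pos, ind$ref)
    expect_identical(unname(full), ind$ref)
  }
})

test_that("per-plant count distribution matches the configured lognormal", {
  cfg <- cohort_sim_config(rng_seed = 89)
  set.seed(89)
  x <- mnutill:::.draw_snv_counts(cfg, 5000)
  expect_true(all(x >= 134 & x <= 13222))
  expect_lt(abs(mean(x) - 2468.7) / 2468.7, 0.05)
})

test_that("phenotype model degenerates correctly", {
  cfg <- cohort_sim_config(rng_seed = 97)
  cfg$phenotype$noise_sd <- 0
  counts <- c(1000, 2000, 3000, 4000)
  y <- phenotype_model(counts, cfg)
  expect_equal(stats::cor(counts, y), -1)  # noise-free line
  cfg$phenotype$slope <- 0
  cfg$phenotype$noise_sd <- 10
  set.seed(1)
  y0 <- phenotype_model(rep(c(500, 5000), 200), cfg)
  r0 <- stats::cor(rep(c(500, 5000), 200), y0)
  expect_lt(abs(r0), 0.15)  # slope zero: no association
})

test_that("a too-small genome raises a capacity error", {
  cfg <- cohort_sim_config(n_plants = 4, chrom_lengths = c(a = 1e4),
                           snv_count = list(family = "fixed", value = 5000),
                           gene_fraction = 0, mask_fraction = 0,
                           rng_seed = 101)
  g <- simulate_genome(cfg)
  expect_error(simulate_cohort(cfg, g$genome), "too small")
})

test_that("false positives carry low QVs and appear in the validation set", {
  cfg <- cohort_sim_config(n_plants = 4, chrom_lengths = c(a = 3e5),
                           snv_count = list(family = "fixed", value = 300),
                           fp_rate = 0.2, n_validation_snv = 200L,
                           rng_seed = 103)
  g <- simulate_genome(cfg)
  sim <- simulate_cohort(cfg, g$genome)
  tr <- sim$truth
  expect_equal(sum(!tr$is_true) / nrow(tr), 0.2, tolerance = 0.01)
  expect_true(all(tr$qv[!tr$is_true] <= 100))
  expect_true(all(tr$qv[tr$is_true] >= 60))
  expect_true(any(sim$validation$confirmed == "no"))
  # transmission flags only exist for true variants
  expect_true(all(is.na(tr$was_transmitted[!tr$is_true])))
})

test_that("simulator outputs round-trip through their file formats", {
  cfg <- cohort_sim_config(n_plants = 3, chrom_lengths = c(a = 1.5e5),
                           snv_count = list(family = "fixed", value = 60),
                           rng_seed = 107)
  g <- simulate_genome(cfg)
  sim <- simulate_cohort(cfg, g$genome, g$genes, g$mask)
  outdir <- file.path(tempdir(), "simout")
  write_cohort_outputs(sim, outdir)
  vcf <- read_joint_vcf(file.path(outdir, "cohort.vcf"))
  expect_equal(vcf$variants, sim$vcf$variants)
  genome <- read_genome_fasta(file.path(outdir, "genome.fa"))
  expect_identical(genome$seq, sim$genome$seq)
  genes <- read_gene_models_gff3(file.path(outdir, "genes.gff3"))
  expect_equal(genes$index$gene_id, g$genes$index$gene_id)
  val <- read_table_tsv(file.path(outdir, "validation.tsv"),
                        required = c("qv", "confirmed", "transmitted"))
  expect_equal(nrow(val), nrow(sim$validation))
})
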