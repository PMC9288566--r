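test_that("coding SNVs classify by codon change on the plus strand", {
  g <- toy_coding_genome()        # CDS "ATGGGGTGGTAA" at c1:11-22
  gs <- gene_model_set(list(toy_coding_gene("+")))
  annotate1 <- function(pos, ref, alt)
    annotate_variants(data.frame(chrom = "c1", pos = pos, ref = ref,
                                 alt = alt), gs, g)
  a <- annotate1(15, "G", "A")   # codon 2 GGG -> GAG
  expect_equal(a$category, "missense")
  expect_equal(a$ref_aa, "G"); expect_equal(a$alt_aa, "E")
  expect_equal(a$aa_pos, 2L)
  expect_equal(a$impact, "MODERATE")

  a <- annotate1(16, "G", "A")   # GGG -> GGA
  expect_equal(a$category, "synonymous")
  expect_equal(a$impact, "LOW")

  a <- annotate1(17, "T", "A")   # TGG -> AGG, Trp -> Arg
  expect_equal(a$category, "missense")

  a <- annotate1(19, "G", "A")   # TGG -> TGA stop
  expect_equal(a$category, "stop_gained")
  expect_equal(a$impact, "HIGH")

  a <- annotate1(12, "T", "C")   # ATG -> ACG start lost
  expect_equal(a$category, "start_lost")

  a <- annotate1(21, "A", "C")   # TAA -> TCA stop lost
  expect_equal(a$category, "stop_lost")
})

test_that("a mirrored minus-strand gene yields identical classifications", {
  g_plus <- toy_coding_genome()
  g_minus <- toy_coding_genome_rc()
  L <- g_plus$lengths[["c1"]]
  gs_plus <- gene_model_set(list(toy_coding_gene("+")))
  gs_minus <- gene_model_set(list(
    gene_model("g1", "g1.1", "c1", "-",
               cds = data.frame(start = L - 22 + 1, end = L - 11 + 1))))
  for (pos in 11:22) {
    ref <- genome_base(g_plus, "c1", pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a_plus <- annotate_variants(
        data.frame(chrom = "c1", pos = pos, ref = ref, alt = alt),
        gs_plus, g_plus)
      mpos <- L - pos + 1
      a_minus <- annotate_variants(
        data.frame(chrom = "c1", pos = mpos,
                   ref = unname(mnutill:::REV_COMP[ref]),
                   alt = unname(mnutill:::REV_COMP[alt])),
        gs_minus, g_minus)
      expect_identical(a_minus$category, a_plus$category)
      expect_identical(a_minus$ref_aa, a_plus$ref_aa)
      expect_identical(a_minus$alt_aa, a_plus$alt_aa)
      expect_identical(a_minus$aa_pos, a_plus$aa_pos)
    }
  }
})

test_that("splice, UTR, intron and flanking classes follow the layout", {
  # exons 101-160 and 301-360; CDS 121-160 and 301-340; UTRs at the ends
  seq <- strrep("ACGT", 250)
  g <- genome_sequence(c(c1 = seq))
  m <- gene_model("g1", "g1.1", "c1", "+",
                  cds = data.frame(start = c(121, 301), end = c(160, 340)),
                  exons = data.frame(start = c(101, 301), end = c(160, 360)))
  gs <- gene_model_set(list(m))
  cat_of <- function(pos) {
    ref <- genome_base(g, "c1", pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotate_variants(data.frame(chrom = "c1", pos = pos, ref = ref,
                                 alt = alt), gs, g)$category
  }
  expect_equal(cat_of(110), "five_prime_utr")
  expect_equal(cat_of(350), "three_prime_utr")
  expect_equal(cat_of(161), "splice_donor")
  expect_equal(cat_of(162), "splice_donor")
  expect_equal(cat_of(299), "splice_acceptor")
  expect_equal(cat_of(300), "splice_acceptor")
  expect_equal(cat_of(200), "intron")
  expect_equal(cat_of(90), "upstream")
  expect_equal(cat_of(400), "downstream")
  # minus strand flips donor/acceptor and upstream/downstream
  gs_m <- gene_model_set(list(
    gene_model("g2", "g2.1", "c1", "-",
               cds = data.frame(start = c(121, 301), end = c(160, 340)),
               exons = data.frame(start = c(101, 301), end = c(160, 360)))))
  cat_m <- function(pos) {
    ref <- genome_base(g, "c1", pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotate_variants(data.frame(chrom = "c1", pos = pos, ref = ref,
                                 alt = alt), gs_m, g)$category
  }
  expect_equal(cat_m(161), "splice_acceptor")
  expect_equal(cat_m(300), "splice_donor")
  expect_equal(cat_m(90), "downstream")
  expect_equal(cat_m(400), "upstream")
})

test_that("variants outside all windows are intergenic; InDels positional", {
  g <- genome_sequence(c(c1 = strrep("ACGT", 5000)))
  m <- gene_model("g1", "g1.1", "c1", "+",
                  cds = data.frame(start = 9001, end = 9300))
  gs <- gene_model_set(list(m))
  a <- annotate_variants(data.frame(chrom = "c1", pos = 100,
                                    ref = genome_base(g, "c1", 100),
                                    alt = "C"), gs, g)
  expect_equal(a$category, "intergenic")
  expect_true(is.na(a$gene_id))
  b <- genome_base(g, "c1", 9100)
  ind <- annotate_variants(data.frame(chrom = "c1", pos = 9100,
                                      ref = paste0(b, genome_base(g, "c1", 9101)),
                                      alt = b), gs, g)
  expect_equal(ind$category, "gene")
  expect_equal(ind$impact, "MODIFIER")
})

test_that("REF/genome mismatches are rejected", {
  g <- toy_coding_genome()
  gs <- gene_model_set(list(toy_coding_gene("+")))
  expect_error(annotate_variants(data.frame(chrom = "c1", pos = 15,
                                            ref = "C", alt = "A"), gs, g),
               "match")
})

test_that("annotation agrees with the brute-force classifier everywhere", {
  for (seed in c(101, 202)) {
    fix <- random_gene_fixture(seed)
    set.seed(seed + 1)
    pos <- sort(sample.int(fix$genome$lengths[[1]], 600))
    ref <- genome_base(fix$genome, "cX", pos)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    vars <- data.frame(chrom = "cX", pos = pos, ref = ref, alt = alt)
    ann <- annotate_variants(vars, fix$genes, fix$genome)
    for (v in seq_len(nrow(vars))) {
      expected <- list()
      for (m in fix$genes$models) {
        cl <- bf_classify_snv("cX", pos[v], ref[v], alt[v], m, fix$genome)
        if (!is.null(cl)) expected[[m$gene_id]] <- cl
      }
      got <- ann[ann$pos == pos[v], , drop = FALSE]
      if (!length(expected)) {
        expect_identical(got$category, "intergenic")
      } else {
        expect_identical(
          stats::setNames(got$category, got$gene_id)[names(expected)],
          unlist(expected))
      }
    }
    # every recorded ref codon translates back to the recorded ref_aa
    coding <- ann[!is.na(ann$ref_aa), ]
    for (m in fix$genes$models) {
      rows <- coding[coding$gene_id == m$gene_id, ]
      if (!nrow(rows)) next
      cds <- cds_sequence(m, fix$genome)
      cods <- substring(cds, 3 * rows$aa_pos - 2, 3 * rows$aa_pos)
      expect_identical(translate_codon(cods), rows$ref_aa)
    }
  }
})

test_that("every variant gets at least one annotation, mutually exclusive", {
  fix <- random_gene_fixture(303)
  set.seed(304)
  pos <- sample.int(fix$genome$lengths[[1]], 300)
  ref <- genome_base(fix$genome, "cX", pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  ann <- annotate_variants(data.frame(chrom = "cX", pos = pos, ref = ref,
                                      alt = alt), fix$genes, fix$genome)
  expect_true(all(pos %in% ann$pos))
  expect_false(any(duplicated(paste(ann$pos, ann$gene_id))))
})

test_that("most-severe collapse and category percentages are consistent", {
  ann <- data.frame(
    plant_id = "p", chrom = "c1", pos = c(1, 1, 2, 3, 4),
    ref = "G", alt = "A",
    gene_id = c("g1", "g2", NA, "g1", "g2"),
    transcript_id = NA, category = c("missense", "upstream", "intergenic",
                                     "upstream", "intron"),
    impact = c("MODERATE", "MODIFIER", "MODIFIER", "MODIFIER", "MODIFIER"),
    ref_aa = NA, aa_pos = NA_integer_, alt_aa = NA, flagged = FALSE)
  ms <- most_severe_per_variant(ann)
  expect_equal(nrow(ms), 4L)
  expect_equal(ms$category[ms$pos == 1], "missense")
  cd <- category_distribution(ann)
  expect_equal(cd$pct[cd$category == "missense"], 25)
  expect_equal(sum(cd$n), 4L)
  expect_equal(nrow(category_distribution(ann[0, ])), 0L)
})

test_that("gene-coverage proportions match the published arithmetic", {
  expect_equal(gene_coverage_pct(23081, 37662), 61.3)
  expect_equal(gene_coverage_pct(1696, 37662), 4.5)
  expect_equal(gene_coverage_pct(3248, 37662), 8.6)
  ann <- data.frame(plant_id = "p", chrom = "c", pos = 1:3, ref = "G",
                    alt = "A", gene_id = c("g1", "g1", "g2"),
                    transcript_id = NA,
                    category = c("missense", "missense", "stop_gained"),
                    impact = c("MODERATE", "MODERATE", "HIGH"),
                    ref_aa = NA, aa_pos = NA_integer_, alt_aa = NA,
                    flagged = FALSE)
  sm <- summarize_gene_coverage(ann, n_annotated_genes = 10)
  bc <- sm$by_category
  expect_equal(bc$n_snvs[bc$category == "missense"], 2L)
  expect_equal(bc$n_genes[bc$category == "missense"], 1L)
  expect_equal(bc$pct_of_annotated_genes[bc$category == "missense"], 10)
  bi <- sm$by_impact
  expect_equal(bi$n_genes[bi$impact == "HIGH"], 1L)
  empty <- summarize_gene_coverage(ann[0, ], 10)
  expect_true(all(empty$by_impact$n_snvs == 0))
})
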