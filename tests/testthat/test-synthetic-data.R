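test_that("generated genomes honor size, GC content and determinism", {
  cfg <- sim_config(genome_lengths = c(chr = 100000L), n_genes = 30L,
                    rng_seed = 11L)
  ga <- generate_genome(cfg)
  expect_equal(unname(genome_lengths(ga$genome)), 100000L)
  gc <- sum(Biostrings::alphabetFrequency(ga$genome$seq)[1, c("C", "G")]) / 1e5
  expect_lt(abs(gc - 0.62), 0.01)
  # same seed twice: byte-identical FASTA and GFF3
  ga2 <- generate_genome(cfg)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); f2 <- file.path(d, "b.fa")
  write_genome_fasta(ga$genome, f1); write_genome_fasta(ga2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- file.path(d, "a.gff3"); g2 <- file.path(d, "b.gff3")
  write_annotation_gff3(ga$annotation, g1); write_annotation_gff3(ga2$annotation, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("gene placement respects intergenic gaps and feasibility", {
  cfg <- sim_config(genome_lengths = c(chr = 60000L), n_genes = 25L,
                    rng_seed = 2L)
  ga <- generate_genome(cfg)
  a <- ga$annotation[order(ga$annotation$start), ]
  expect_equal(nrow(a), 25L)
  expect_true(all(diff(a$start) > 0))
  gaps <- a$start[-1] - a$end[-nrow(a)] - 1L
  expect_true(all(gaps >= cfg$min_intergenic))
  # infeasible request errors with a sizing message
  bad <- sim_config(genome_lengths = c(chr = 5000L), n_genes = 50L)
  expect_error(generate_genome(bad), "cannot place")
  # empty case
  none <- sim_config(genome_lengths = c(chr = 5000L), n_genes = 0L)
  expect_equal(nrow(generate_genome(none)$annotation), 0L)
})

test_that("planted transcripts satisfy their class rules by construction", {
  cfg <- sim_config(genome_lengths = c(chr = 150000L), n_genes = 50L,
                    n_transcripts = 40L, rng_seed = 5L)
  ga <- generate_genome(cfg)
  truth <- plant_transcripts(ga$genome, ga$annotation, cfg)
  expect_equal(nrow(truth), 40L)
  expect_true(all(truth$length >= 50 & truth$length <= 350))
  # round-trip: the classifier reproduces every true class and subtype
  params <- classifier_params()
  for (i in seq_len(nrow(truth))) {
    got <- classify_contig(
      data.frame(replicon = truth$replicon[i], strand = truth$strand[i],
                 start = truth$start[i], end = truth$end[i]),
      ga$annotation, params)
    expect_identical(got$class, truth$true_class[i])
    expect_identical(got$subtype, truth$true_subtype[i])
  }
  # the independent decision-table oracle agrees with the planted labels
  genes <- ga$annotation[ga$annotation$kind %in% c("CDS", "transposase"), ]
  for (i in seq_len(nrow(truth))) {
    o <- oracle_classify(truth$start[i], truth$end[i], truth$strand[i],
                         genes[genes$replicon == truth$replicon[i], ], params)
    expect_identical(o$class, truth$true_class[i])
  }
})

test_that("a pure class mix forces that class, and zero transcripts plant nothing", {
  cfg <- sim_config(genome_lengths = c(chr = 150000L), n_genes = 40L,
                    n_transcripts = 12L, class_mix = c(trans = 1.0),
                    rng_seed = 7L)
  ga <- generate_genome(cfg)
  truth <- plant_transcripts(ga$genome, ga$annotation, cfg)
  expect_true(all(truth$true_class == "trans"))
  cfg0 <- sim_config(genome_lengths = c(chr = 50000L), n_genes = 10L,
                     n_transcripts = 0L)
  ga0 <- generate_genome(cfg0)
  expect_equal(nrow(plant_transcripts(ga0$genome, ga0$annotation, cfg0)), 0L)
  # leader plants obey the interval rule against their gene
  cfgL <- sim_config(genome_lengths = c(chr = 150000L), n_genes = 40L,
                     n_transcripts = 10L, class_mix = c(leader = 1.0),
                     rng_seed = 8L)
  gaL <- generate_genome(cfgL)
  tl <- plant_transcripts(gaL$genome, gaL$annotation, cfgL)
  for (i in seq_len(nrow(tl))) {
    g <- gaL$annotation[gaL$annotation$gene_id == tl$associated_gene[i], ]
    if (g$strand == "+") {
      expect_true(tl$tss[i] >= g$start - 40 && tl$tss[i] <= g$start + 1)
      expect_true(tl$end3[i] > g$start && tl$end3[i] < g$end)
    } else {
      expect_true(tl$tss[i] <= g$end + 40 && tl$tss[i] >= g$end - 1)
      expect_true(tl$end3[i] < g$end && tl$end3[i] > g$start)
    }
  }
})

test_that("read simulation follows the end model, depth law and bounds", {
  cfg <- sim_config(genome_lengths = c(chr = 100000L), n_genes = 30L,
                    n_transcripts = 15L, end_noise_sd = 0, rng_seed = 13L)
  ga <- generate_genome(cfg)
  truth <- plant_transcripts(ga$genome, ga$annotation, cfg)
  al <- simulate_reads(truth, ga$genome, cfg, "s1_primary")
  # s1 with zero noise: every read of a primary transcript starts at its TSS
  for (i in which(truth$is_primary)) {
    tr <- truth[i, ]
    inside <- al$strand == tr$strand & al$replicon == tr$replicon &
      al$start >= min(tr$tss, tr$end3) & al$end <= max(tr$tss, tr$end3)
    p5 <- ifelse(tr$strand == "+", al$start[inside], al$end[inside])
    if (length(p5) > 0) expect_true(all(p5 == tr$tss))
  }
  # read intervals never exceed replicon bounds
  expect_true(all(al$start >= 1 & al$end <= 100000))
  # zero-depth, zero-background: no reads at all
  cfg0 <- sim_config(genome_lengths = c(chr = 60000L), n_genes = 10L,
                     n_transcripts = 5L, mean_depth = 0,
                     background_read_rate = 0, rng_seed = 3L)
  ga0 <- generate_genome(cfg0)
  t0 <- plant_transcripts(ga0$genome, ga0$annotation, cfg0)
  expect_equal(nrow(simulate_reads(t0, ga0$genome, cfg0, "s2_processed")), 0L)
  # unknown protocol errors
  expect_error(simulate_reads(truth, ga$genome, cfg, "s3"), "arg")
  # total protocol: strandless alignments
  tot <- simulate_reads(truth, ga$genome, cfg, "total")
  expect_true(all(is.na(tot$strand)))
})

test_that("per-transcript read counts follow the Poisson law", {
  # one planted transcript, mean depth 20: the count lies within 3*sqrt(20)
  # of 20 in at least 99% of seeded replicates
  cfg_base <- sim_config(genome_lengths = c(chr = 30000L), n_genes = 5L,
                         n_transcripts = 1L, class_mix = c(trans = 1.0),
                         mean_depth = 20, background_read_rate = 0,
                         primary_fraction = 1, rng_seed = 1L)
  ga <- generate_genome(cfg_base)
  truth <- plant_transcripts(ga$genome, ga$annotation, cfg_base)
  counts <- vapply(1:1000, function(s) {
    cfg <- cfg_base; cfg$rng_seed <- s
    nrow(simulate_reads(truth, ga$genome, cfg, "s1_primary"))
  }, numeric(1))
  inside <- mean(abs(counts - 20) <= 3 * sqrt(20))
  expect_gte(inside, 0.99)
})

test_that("reads crossing a circular origin are split into two segments", {
  g <- make_genome(c(chr = strrep("ACGT", 500)), circular = TRUE)
  truth <- data.frame(transcript_id = "t1", replicon = "chr", strand = "+",
                      tss = 1950L, end3 = 149L, start = 1950L, end = 149L,
                      length = 200L, true_class = "trans", true_subtype = "2",
                      associated_gene = NA, is_primary = TRUE,
                      cleavage_site = NA_integer_)
  cfg <- sim_config(genome_lengths = c(chr = 2000L), n_genes = 0L,
                    n_transcripts = 1L, mean_depth = 10,
                    background_read_rate = 0, end_noise_sd = 0,
                    full_length_prob = 1, circular = TRUE, rng_seed = 4L)
  al <- simulate_reads(truth, g, cfg, "s1_primary")
  expect_true(all(al$start >= 1 & al$end <= 2000))
  split_ids <- names(which(table(al$read_id) == 2))
  expect_gt(length(split_ids), 0)
  seg <- al[al$read_id == split_ids[1], ]
  expect_true(any(seg$start == 1950 & seg$end == 2000))
  expect_true(any(seg$start == 1 & seg$end == 149))
})
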