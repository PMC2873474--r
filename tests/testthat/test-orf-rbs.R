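test_that("the 60-nt ORF boundary is exact and completeness is required", {
  # ATG + 18 codons + TAA = 60 nt
  mid60 <- strrep("GCT", 18)
  sq60 <- paste0("CCCC", "ATG", mid60, "TAA", "CCCC")
  o <- find_orfs(sq60)
  expect_equal(nrow(o), 1L)
  expect_equal(o$length, 60L)
  expect_equal(o$start, 5L)
  expect_equal(o$stop, 64L)
  # 57 nt: below the threshold
  sq57 <- paste0("CCCC", "ATG", strrep("GCT", 17), "TAA", "CCCC")
  expect_equal(nrow(find_orfs(sq57)), 0L)
  # no stop codon anywhere: no complete ORF
  expect_equal(nrow(find_orfs(paste0("ATG", strrep("GCA", 40)))), 0L)
  expect_error(find_orfs("ATGNNN"), "ACGT")
})

test_that("random sequences match the brute-force three-frame oracle", {
  set.seed(61)
  for (rep_i in 1:80) {
    sq <- random_dna(400, gc = 0.5)
    got <- find_orfs(sq)
    want <- oracle_orfs(sq)
    expect_equal(got$start, want$start)
    expect_equal(got$stop, want$stop)
    expect_equal(got$length, want$length)
    if (nrow(got) > 0) {
      expect_true(all(got$length %% 3 == 0))
      expect_true(all(got$length >= 60))
      expect_true(all(substr(sq, got$start, got$start + 2) %in%
                        c("ATG", "GTG", "TTG")))
      expect_true(all(substr(sq, got$stop - 2, got$stop) %in%
                        c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("lowering min_len never removes ORFs", {
  set.seed(62)
  sq <- random_dna(600, gc = 0.45)
  n90 <- nrow(find_orfs(sq, min_len = 90))
  n60 <- nrow(find_orfs(sq, min_len = 60))
  n30 <- nrow(find_orfs(sq, min_len = 30))
  expect_lte(n90, n60)
  expect_lte(n60, n30)
})

test_that("anti-SD hybridization energy follows the duplex oracle", {
  params <- rbs_params()
  # a strong SD-like window passes the threshold
  r <- rbs_energy("CCCCAGGAGGCCCCC", params)
  expect_lte(r$energy, -3.4535)
  expect_true(r$has_rbs)
  # poly-T offers no stable duplex
  r2 <- rbs_energy(strrep("T", 15), params)
  expect_equal(r2$energy, 0)
  expect_false(r2$has_rbs)
  # window shorter than the anti-SD: no call
  r3 <- rbs_energy("ACGT", params)
  expect_true(is.na(r3$energy))
  expect_true(is.na(r3$has_rbs))
  # exhaustive-offset oracle on random windows
  set.seed(63)
  st <- params$model$stack
  asd <- strsplit(chartr("T", "U", params$anti_sd), "")[[1]]
  m <- length(asd)
  oracle_rbs <- function(win) {
    wb <- strsplit(chartr("T", "U", win), "")[[1]]
    best <- 0
    for (o in 0:(length(wb) - m)) {
      pairs <- rep(NA_character_, m)
      for (j in seq_len(m)) {
        w <- wb[o + (m - j + 1)]
        p <- paste0(w, asd[j])
        if (p %in% rownames(st)) pairs[m - j + 1] <- p
      }
      e <- 0
      for (k in seq_len(m - 1))
        if (!is.na(pairs[k]) && !is.na(pairs[k + 1]))
          e <- e + st[pairs[k], pairs[k + 1]]
      best <- min(best, e)
    }
    best
  }
  for (rep_i in 1:60) {
    win <- random_dna(sample(8:25, 1), gc = 0.55)
    expect_equal(rbs_energy(win, params)$energy, oracle_rbs(win))
  }
})

test_that("rbs calls are monotone in the threshold and window-local", {
  set.seed(64)
  win <- "GGGGAGGTGGCCAA"
  e <- rbs_energy(win, rbs_params())$energy
  lax <- rbs_params(energy_threshold = -0.5)
  strict <- rbs_params(energy_threshold = -12)
  expect_gte(rbs_energy(win, lax)$has_rbs,
             rbs_energy(win, strict)$has_rbs)
  # appending non-complementary bases outside the window leaves energy alone
  expect_equal(rbs_energy(paste0(win, "TTTT"), rbs_params())$energy, e)
})

test_that("ORF-gene relations follow the frame arithmetic", {
  gene <- data.frame(gene_id = "g1", replicon = "chr", strand = "+",
                     start = 1001L, end = 1300L, kind = "CDS",
                     stringsAsFactors = FALSE)
  contig <- data.frame(contig_id = "c1", replicon = "chr", strand = "+",
                       start = 1101L, end = 1320L, stringsAsFactors = FALSE)
  # ORF ending exactly at the gene stop in the same frame
  orf_same <- data.frame(frame = 0L, start = 101L, stop = 200L + 0L)
  # place: genomic start 1201, genomic stop 1300; same frame iff
  # (1201 - 1001) %% 3 == 0 -> 200 %% 3 = 2 -> shift start to 1202
  orf_same <- data.frame(frame = 0L, start = 102L, stop = 200L)
  expect_equal(relate_orf_to_gene(orf_same, contig, gene),
               "same_frame_shared_stop")
  # inside the gene, different frame
  orf_diff <- data.frame(frame = 1L, start = 50L, stop = 130L)
  expect_equal(relate_orf_to_gene(orf_diff, contig, gene),
               "overlapping_other_frame")
  # ORF starting at the gene's own start codon is excluded
  contig2 <- data.frame(contig_id = "c2", replicon = "chr", strand = "+",
                        start = 961L, end = 1100L, stringsAsFactors = FALSE)
  orf_gene_start <- data.frame(frame = 0L, start = 41L, stop = 120L)
  expect_equal(relate_orf_to_gene(orf_gene_start, contig2, gene),
               "gene_start_excluded")
  # entirely upstream of the start codon: within the 5'-UTR
  contig3 <- data.frame(contig_id = "c3", replicon = "chr", strand = "+",
                        start = 901L, end = 1000L, stringsAsFactors = FALSE)
  orf_up <- data.frame(frame = 0L, start = 10L, stop = 90L)
  expect_equal(relate_orf_to_gene(orf_up, contig3, gene), "within_5utr")
  # randomized placements agree with a mod-3 oracle
  set.seed(65)
  for (rep_i in 1:60) {
    cstart <- sample(900:1250, 1)
    olen <- 3L * sample(20:40, 1)
    ostart <- sample(1:60, 1)
    contig_r <- data.frame(contig_id = "cr", replicon = "chr", strand = "+",
                           start = cstart, end = cstart + 400L,
                           stringsAsFactors = FALSE)
    orf_r <- data.frame(frame = (ostart - 1L) %% 3L, start = ostart,
                        stop = ostart + olen - 1L)
    got <- relate_orf_to_gene(orf_r, contig_r, gene)
    g5 <- cstart + ostart - 1L
    g3 <- cstart + ostart + olen - 2L
    want <- if (g5 == 1001L) "gene_start_excluded"
      else if ((g5 - 1001L) %% 3L == 0L && g3 == 1300L) "same_frame_shared_stop"
      else if (g5 <= 1300L && g3 >= 1001L) "overlapping_other_frame"
      else if (g3 < 1001L) "within_5utr"
      else "none"
    expect_equal(got, want)
  }
})

test_that("the candidate screen threads sequences, RBS and relations together", {
  # build a tiny genome holding one candidate with a known ORF + SD site
  set.seed(66)
  orf_seq <- paste0("ATG", strrep("GCT", 24), "TAA")   # 78 nt
  cand <- paste0("GG", "TAGGAGGTCACGTACGT", orf_seq, "CGCA")
  left <- random_dna(300, gc = 0.5)
  g <- make_genome(c(chr = paste0(left, cand, random_dna(200, gc = 0.5))))
  classified <- data.frame(
    contig_id = "c1", replicon = "chr", strand = "+",
    start = 301L, end = 300L + nchar(cand), length = nchar(cand),
    rna_class = "trans", subtype = "2", associated_genes = "",
    te_associated = FALSE, excluded = FALSE, excluded_reason = NA,
    stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = character(0), replicon = character(0),
                    strand = character(0), start = integer(0),
                    end = integer(0), kind = character(0))
  res <- screen_orfs(classified, g, ann)
  expect_gte(nrow(res), 1L)
  main <- res[res$length == 78L, ]
  expect_equal(nrow(main), 1L)
  expect_true(main$has_rbs)   # AGGAGG sits 11-6 nt upstream of the ATG
  expect_equal(main$relation_to_gene, "none")
})
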