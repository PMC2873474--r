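test_that("rule-forced placements get their textbook classes", {
  ann <- toy_two_gene_annotation("+", "+")
  params <- classifier_params()
  cl <- function(start, end, strand)
    classify_contig(data.frame(replicon = "chr", strand = strand,
                               start = start, end = end), ann, params)
  # minus-strand contig wholly inside a plus-strand CDS interior: antisense 2
  r <- cl(1100, 1200, "-")
  expect_equal(r$class, "antisense"); expect_equal(r$subtype, "2")
  # 5'-end 35 nt upstream of the start codon, 3'-end mid-CDS: leader
  r <- cl(1001 - 35, 1150, "+")
  expect_equal(r$class, "leader")
  # 5'-end in the -60..-41 band: sense type 1
  r <- cl(1001 - 50, 1150, "+")
  expect_equal(r$class, "sense"); expect_equal(r$subtype, "1")
  # fully inside the CDS on the same strand: sense type 2
  r <- cl(1050, 1200, "+")
  expect_equal(r$class, "sense"); expect_equal(r$subtype, "2")
  # overlapping the stop codon into the 3'-UTR: sense type 3
  r <- cl(1200, 1310, "+")
  expect_equal(r$class, "sense"); expect_equal(r$subtype, "3")
  # starting inside the 3'-UTR: sense type 4
  r <- cl(1305, 1400, "+")
  expect_equal(r$class, "sense"); expect_equal(r$subtype, "4")
  # covering the whole CDS: orf_cover
  r <- cl(995, 1310, "+")
  expect_equal(r$class, "orf_cover")
  # mid-intergenic, both neighbours on + strand, contig on -: trans type 1
  r <- cl(1500, 1600, "-")
  expect_equal(r$class, "trans"); expect_equal(r$subtype, "1")
  # same but contig on +: flanked by same-orientation genes, trans type 2
  r <- cl(1500, 1600, "+")
  expect_equal(r$class, "trans"); expect_equal(r$subtype, "2")
  # unstranded contigs cannot be classified
  expect_error(cl(1500, 1600, NA_character_), "unstranded")
})

test_that("an exhaustive sweep reproduces the decision-table oracle", {
  params <- classifier_params()
  for (cfg in list(c("+", "+"), c("+", "-"), c("-", "+"), c("-", "-"))) {
    ann <- toy_two_gene_annotation(cfg[1], cfg[2])
    for (strand in c("+", "-")) {
      for (start in seq(700, 2600, by = 3)) {
        contig <- data.frame(replicon = "chr", strand = strand,
                             start = start, end = start + 99L)
        got <- classify_contig(contig, ann, params)
        want <- oracle_classify(start, start + 99L, strand, ann, params)
        if (!identical(got$class, want$class) ||
            !identical(got$subtype, want$subtype)) {
          fail(sprintf("mismatch at start=%d strand=%s genes=%s%s: got %s/%s want %s/%s",
                       start, strand, cfg[1], cfg[2], got$class, got$subtype,
                       want$class, want$subtype))
        }
      }
    }
  }
  succeed()
})

test_that("contigs over structural RNAs and repeats are excluded, TEs flagged", {
  ann <- data.frame(gene_id = c("g1", "r1", "t1"), replicon = "chr",
                    strand = "+", start = c(1001L, 2001L, 3001L),
                    end = c(1300L, 2120L, 3300L),
                    kind = c("CDS", "rRNA", "transposase"),
                    stringsAsFactors = FALSE)
  contigs <- data.frame(contig_id = c("c1", "c2", "c3"), replicon = "chr",
                        strand = "+", start = c(1050L, 2050L, 3050L),
                        end = c(1150L, 2100L, 3150L),
                        stringsAsFactors = FALSE)
  cl <- classify_contigs(contigs, ann)
  expect_false(cl$excluded[1])
  expect_true(cl$excluded[2])
  expect_match(cl$excluded_reason[2], "rRNA")
  expect_false(cl$excluded[3])
  expect_true(cl$te_associated[3])
  expect_equal(cl$rna_class[3], "sense")
})

test_that("class counts are invariant under coordinate translation", {
  params <- classifier_params()
  ann <- toy_two_gene_annotation("+", "-")
  set.seed(33)
  starts <- sample(seq(700, 2500), 30)
  contigs <- data.frame(contig_id = sprintf("c%02d", 1:30), replicon = "chr",
                        strand = sample(c("+", "-"), 30, replace = TRUE),
                        start = starts, end = starts + 99L,
                        stringsAsFactors = FALSE)
  base <- classify_contigs(contigs, ann, params)
  shift <- 5000L
  ann2 <- transform(ann, start = start + shift, end = end + shift,
                    replicon = "chr2")
  contigs2 <- transform(contigs, start = start + shift, end = end + shift,
                        replicon = "chr2")
  shifted <- classify_contigs(contigs2, ann2, params)
  expect_equal(table(base$rna_class, base$subtype),
               table(shifted$rna_class, shifted$subtype))
})

test_that("clusters use strict single-linkage below the gap", {
  params <- classifier_params()
  mk <- function(starts, len = 80L) {
    d <- data.frame(contig_id = sprintf("c%02d", seq_along(starts)),
                    replicon = "chr", strand = "+", start = starts,
                    end = starts + len - 1L, length = len,
                    rna_class = "trans", subtype = "2",
                    associated_genes = "", te_associated = FALSE,
                    excluded = FALSE, excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
    d
  }
  # gap of 150 nt: one cluster of two
  cl <- find_clusters(mk(c(1000L, 1000L + 80L + 150L)), params)
  expect_equal(nrow(cl), 2L)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  # gap of exactly 200 nt: "less than 200" fails
  cl2 <- find_clusters(mk(c(1000L, 1000L + 80L + 200L)), params)
  expect_equal(nrow(cl2), 0L)
  # random layouts match a single-linkage oracle
  set.seed(14)
  for (rep_i in 1:60) {
    n <- sample(3:10, 1)
    starts <- sort(sample.int(5000, n)) + 1000L
    d <- mk(starts)
    got <- find_clusters(d, params)
    # oracle: chain sorted intervals whenever gap < 200
    gaps <- starts[-1] - (starts[-n] + 79L) - 1L
    grp <- cumsum(c(1L, as.integer(gaps >= 200)))
    keep <- grp %in% which(tabulate(grp) >= 2)
    want_members <- d$contig_id[keep]
    expect_setequal(got$contig_id, want_members)
    if (nrow(got) > 0) {
      want_sizes <- sort(as.vector(table(grp[keep])))
      expect_equal(sort(as.vector(table(got$cluster_id))), want_sizes)
    }
  }
})

test_that("summaries report counts and interpolated quartiles", {
  one <- data.frame(contig_id = "c1", replicon = "chr", strand = "+",
                    start = 1L, end = 100L, length = 100L,
                    rna_class = "trans", subtype = "2", associated_genes = "",
                    te_associated = FALSE, excluded = FALSE,
                    excluded_reason = NA_character_, stringsAsFactors = FALSE)
  s <- summarize_classes(one)
  expect_equal(s$size_stats$min, 100)
  expect_equal(s$size_stats$q1, 100)
  expect_equal(s$size_stats$median, 100)
  expect_equal(s$size_stats$mean, 100)
  expect_equal(s$size_stats$max, 100)
  # random lengths match the sorted-list quantile oracle
  set.seed(8)
  lens <- sample(53:259, 40, replace = TRUE)
  many <- do.call(rbind, lapply(seq_along(lens), function(i)
    transform(one, contig_id = sprintf("c%02d", i), end = lens[i],
              length = lens[i])))
  s2 <- summarize_classes(many)
  expect_equal(s2$size_stats$q1,
               unname(quantile(lens, 0.25, type = 7)))
  expect_equal(s2$size_stats$median, unname(quantile(lens, 0.5, type = 7)))
  expect_equal(s2$size_stats$q3, unname(quantile(lens, 0.75, type = 7)))
  expect_true(with(s2$size_stats, min <= q1 && q1 <= median &&
                     median <= q3 && q3 <= max))
  # empty input: empty summary
  s0 <- summarize_classes(one[0, ])
  expect_equal(nrow(s0$counts), 0L)
  expect_equal(nrow(s0$size_stats), 0L)
})
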