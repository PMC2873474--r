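make_contig <- function(start, end, strand = "+", id = "contig_0001") {
  data.frame(contig_id = id, replicon = "chr", strand = strand,
             start = start, end = end, stringsAsFactors = FALSE)
}

test_that("the distinct-end thresholds are literal", {
  L <- 300
  depth <- numeric(L); depth[101:200] <- 50
  s5 <- numeric(L); s5[101] <- 6            # "more than 5" means >= 6
  tr <- make_depth_track(depth, starts5 = s5)
  e <- call_distinct_ends(make_contig(101, 200), tr, samples = "x")
  expect_equal(e$five_prime$position, 101)
  expect_equal(e$end_category_5, "1")
  expect_equal(e$end_category_3, "0")
  # five reads do not qualify
  s5b <- numeric(L); s5b[101] <- 5
  e2 <- call_distinct_ends(make_contig(101, 200),
                           make_depth_track(depth, starts5 = s5b),
                           samples = "x")
  expect_equal(nrow(e2$five_prime), 0L)
  expect_equal(e2$end_category_5, "0")
  # away from the edge the 10%-of-mean rule also applies: mean depth 50
  s5c <- numeric(L); s5c[150] <- 4.9 * 0 + 4  # 4 < 5: fails the >5 rule anyway
  s5c[160] <- 6                                # 6 > 5 but 6 >= 5 = 0.1 * 50
  s5c[170] <- 6
  depth_hi <- numeric(L); depth_hi[101:200] <- 70  # mean 70 -> 10% = 7 > 6
  e3 <- call_distinct_ends(make_contig(101, 200),
                           make_depth_track(depth_hi, starts5 = s5c),
                           samples = "x")
  expect_equal(nrow(e3$five_prime), 0L)
  e4 <- call_distinct_ends(make_contig(101, 200),
                           make_depth_track(depth, starts5 = s5c),
                           samples = "x")
  expect_equal(e4$five_prime$position, c(160, 170))
  expect_equal(e4$end_category_5, "2")
})

test_that("strand awareness: minus-strand 5'-ends sit at the high edge", {
  L <- 300
  depth <- numeric(L); depth[101:200] <- 30
  s5 <- numeric(L); s5[200] <- 10      # biological 5'-end of a minus contig
  e <- call_distinct_ends(make_contig(101, 200, strand = "-"),
                          make_depth_track(depth, starts5 = s5, strand = "-"),
                          samples = "x")
  expect_equal(e$five_prime$position, 200)
})

test_that("random count vectors match the rule-enumeration oracle", {
  set.seed(21)
  for (rep_i in 1:150) {
    L <- 200
    a <- 51L; b <- 150L
    depth <- numeric(L); depth[a:b] <- sample(10:80, 1)
    md <- mean(depth[a:b])
    s5 <- numeric(L); e3v <- numeric(L)
    pos5 <- sample(a:b, sample(1:8, 1))
    s5[pos5] <- sample(1:15, length(pos5), replace = TRUE)
    pos3 <- sample(a:b, sample(1:8, 1))
    e3v[pos3] <- sample(1:15, length(pos3), replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    tr <- make_depth_track(depth, starts5 = s5, ends3 = e3v, strand = strand)
    e <- call_distinct_ends(make_contig(a, b, strand = strand), tr,
                            samples = "x")
    edge5 <- if (strand == "+") c(a, a + 1L) else c(b, b - 1L)
    edge3 <- if (strand == "+") c(b, b - 1L) else c(a, a + 1L)
    expect_equal(e$five_prime$position,
                 oracle_distinct_ends(s5, a, b, edge5, md))
    expect_equal(e$three_prime$position,
                 oracle_distinct_ends(e3v, a, b, edge3, md))
  }
})

test_that("raising the read-count threshold never adds distinct ends", {
  set.seed(5)
  L <- 200; a <- 51L; b <- 150L
  depth <- numeric(L); depth[a:b] <- 40
  s5 <- numeric(L); s5[sample(a:b, 12)] <- sample(2:20, 12, replace = TRUE)
  tr <- make_depth_track(depth, starts5 = s5)
  n_prev <- Inf
  for (thr in c(3, 5, 8, 12)) {
    e <- call_distinct_ends(make_contig(a, b), tr, samples = "x",
                            min_reads = thr)
    expect_lte(nrow(e$five_prime), n_prev)
    n_prev <- nrow(e$five_prime)
  }
})

test_that("primary labels come from the s1 library", {
  L <- 300
  depth <- numeric(L); depth[101:200] <- 40
  s5_a <- numeric(L); s5_a[101] <- 20                 # distinct in s1
  s5_b <- numeric(L); s5_b[101] <- 20; s5_b[140] <- 10  # s2 adds one more
  tr1 <- make_depth_track(depth, starts5 = s5_a, sample = "s1")
  tr2 <- make_depth_track(depth, starts5 = s5_b, sample = "s2")
  e1 <- call_distinct_ends(make_contig(101, 200), tr1, samples = "s1")
  e2 <- call_distinct_ends(make_contig(101, 200), tr2, samples = "s2")
  lab <- label_primary(e1, e2)
  expect_equal(lab$five_prime$position, c(101, 140))
  expect_equal(lab$five_prime$is_primary, c(TRUE, FALSE))
  expect_equal(lab$five_prime$samples, c("s1,s2", "s2"))
  expect_equal(lab$end_category_5, "2")
  # mismatched contigs are rejected
  e3 <- call_distinct_ends(make_contig(101, 200, id = "contig_0002"), tr2,
                           samples = "s2")
  expect_error(label_primary(e1, e3), "different contigs")
})

test_that("merge radius groups near-identical ends only when requested", {
  L <- 300
  depth <- numeric(L); depth[101:200] <- 40
  s5 <- numeric(L); s5[101] <- 20; s5[102] <- 8; s5[150] <- 10
  tr <- make_depth_track(depth, starts5 = s5)
  e0 <- call_distinct_ends(make_contig(101, 200), tr, samples = "x")
  expect_equal(e0$five_prime$position, c(101, 102, 150))
  e1 <- call_distinct_ends(make_contig(101, 200), tr, samples = "x",
                           merge_radius = 2)
  expect_equal(e1$five_prime$position, c(101, 150))
  expect_equal(e1$five_prime$count[1], 28)
})

test_that("primary-TSS recovery on synthetic data matches the planted truth", {
  cfg <- sim_config(genome_lengths = c(chr = 200000L), n_genes = 60L,
                    n_transcripts = 40L, end_noise_sd = 0, rng_seed = 31L)
  ga <- generate_genome(cfg)
  truth <- plant_transcripts(ga$genome, ga$annotation, cfg)
  al <- rbind(simulate_reads(truth, ga$genome, cfg, "s1_primary"),
              simulate_reads(truth, ga$genome, cfg, "s2_processed"))
  track <- build_coverage(al, ga$genome)
  contigs <- call_contigs(track)
  labeled <- lapply(seq_len(nrow(contigs)), function(i) {
    ci <- contigs[i, ]
    label_primary(call_distinct_ends(ci, track, samples = "s1_primary"),
                  call_distinct_ends(ci, track, samples = "s2_processed"))
  })
  has_primary <- vapply(labeled, function(e) any(e$five_prime$is_primary),
                        logical(1))
  # match each contig to its planted transcript
  matched_primary <- vapply(seq_len(nrow(contigs)), function(i) {
    ci <- contigs[i, ]
    hit <- truth$replicon == ci$replicon & truth$strand == ci$strand &
      truth$start <= ci$end & truth$end >= ci$start
    any(truth$is_primary[hit])
  }, logical(1))
  frac_called <- mean(has_primary)
  frac_true <- mean(matched_primary)
  # binomial 95% CI around the planted fraction
  n <- length(has_primary)
  expect_lt(abs(frac_called - frac_true), 1.96 * sqrt(0.25 / n) + 1e-9)
  # end-category cross-tabulation agrees with a direct recomputation
  tab <- tabulate_end_categories(labeled)
  expect_equal(sum(tab$n), length(labeled))
  recount <- table(vapply(labeled, function(e) e$end_category_5, ""))
  for (cat in names(recount))
    expect_equal(sum(tab$n[tab$cat5 == cat]), unname(recount[[cat]]))
})
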