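# Independent brute-force oracles and fixture builders shared by the tests.
# These deliberately re-derive every rule in the plainest possible way and
# never call back into the code paths they check.

# ---- coverage / contig fixtures ------------------------------------------

# wrap a raw depth vector (plus optional end-count vectors) into a coverage
# track with one sample "x", replicon "chr", strand "+"
make_depth_track <- function(depth, starts5 = NULL, ends3 = NULL,
                             sample = "x", strand = "+") {
  L <- length(depth)
  if (is.null(starts5)) starts5 <- numeric(L)
  if (is.null(ends3)) ends3 <- numeric(L)
  samples <- list()
  samples[[sample]] <- list(chr = setNames(
    list(list(depth = depth, starts5 = starts5, ends3 = ends3)), strand))
  structure(list(samples = samples, replicon_lengths = c(chr = L),
                 sample_names = sample),
            class = "sr_coverage")
}

# brute-force seed/extend caller on one depth vector: enumerate all maximal
# runs with depth >= C of length >= L_min, grow each while depth >= c,
# deduplicate the grown intervals
oracle_contigs <- function(depth, L_min, L_max, C, c) {
  n <- length(depth)
  seeds <- list()
  i <- 1
  while (i <= n) {
    if (depth[i] >= C) {
      j <- i
      while (j < n && depth[j + 1] >= C) j <- j + 1
      if (j - i + 1 >= L_min) seeds[[length(seeds) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  grown <- lapply(seeds, function(s) {
    a <- s[1]; b <- s[2]
    while (a > 1 && depth[a - 1] >= c) a <- a - 1
    while (b < n && depth[b + 1] >= c) b <- b + 1
    c(a, b)
  })
  grown <- unique(grown)
  if (length(grown) == 0) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, grown)
  m[order(m[, 1]), , drop = FALSE]
}

# ---- distinct-end rule oracle --------------------------------------------

# literal enumeration of the distinct-end rule over a contig [a, b]
oracle_distinct_ends <- function(counts, a, b, first_two, mean_depth,
                                 min_reads = 5, frac = 0.10) {
  keep <- integer(0)
  for (p in a:b) {
    if (p %in% first_two) {
      if (counts[p] > min_reads) keep <- c(keep, p)
    } else {
      if (counts[p] > min_reads && counts[p] >= frac * mean_depth)
        keep <- c(keep, p)
    }
  }
  keep
}

# ---- classifier decision-table oracle ------------------------------------

# verbatim re-implementation of the positional decision table in genomic
# coordinates with explicit per-strand branches (no gene-frame transform)
oracle_classify <- function(start, end, strand, genes, params) {
  utr5 <- params$utr5; utr3 <- params$utr3
  lw <- params$leader_window
  c5 <- if (strand == "+") start else end    # contig 5' end
  c3 <- if (strand == "+") end else start
  per_gene <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (g$strand == "+") {
      mtu <- c(g$start - utr5, g$end + utr3)
      u5r <- c(g$start - utr5, g$start - 1)
      u3r <- c(g$end + 1, g$end + utr3)
    } else {
      mtu <- c(g$start - utr3, g$end + utr5)
      u5r <- c(g$end + 1, g$end + utr5)
      u3r <- c(g$start - utr3, g$start - 1)
    }
    if (end < mtu[1] || start > mtu[2]) next
    if (strand == g$strand) {
      covers <- start <= g$start && end >= g$end
      if (covers) { per_gene[[length(per_gene) + 1]] <-
        list(class = "orf_cover", sub = "", id = g$gene_id); next }
      if (g$strand == "+") {
        is_leader <- c5 >= g$start - lw && c5 <= g$start + 1 &&
          c3 > g$start && c3 < g$end
        s1 <- c5 >= g$start - utr5 && c5 <= g$start - lw - 1 &&
          c3 >= g$start && c3 <= g$end
        s2 <- c5 >= g$start && c3 <= g$end
        s3 <- start <= g$end && end >= g$start &&
          c3 >= g$end + 1 && c3 <= g$end + utr3
        s4 <- c5 >= g$end + 1 && c5 <= g$end + utr3
      } else {
        is_leader <- c5 <= g$end + lw && c5 >= g$end - 1 &&
          c3 < g$end && c3 > g$start
        s1 <- c5 <= g$end + utr5 && c5 >= g$end + lw + 1 &&
          c3 <= g$end && c3 >= g$start
        s2 <- c5 <= g$end && c3 >= g$start
        s3 <- start <= g$end && end >= g$start &&
          c3 <= g$start - 1 && c3 >= g$start - utr3
        s4 <- c5 <= g$start - 1 && c5 >= g$start - utr3
      }
      if (is_leader) { per_gene[[length(per_gene) + 1]] <-
        list(class = "leader", sub = "", id = g$gene_id); next }
      subs <- c("1", "2", "3", "4")[c(s1, s2, s3, s4)]
      if (length(subs) == 0) {
        # degenerate fallback mirrors the documented behavior
        if (end <= u5r[2] && end >= mtu[1] && g$strand == "+") subs <- "1"
        else if (start >= u5r[1] && g$strand == "-" && start >= g$end + 1) subs <- "1"
        else if ((g$strand == "+" && start >= u3r[1]) ||
                 (g$strand == "-" && end <= u3r[2] && end < g$start)) subs <- "4"
        else subs <- "2"
      }
      per_gene[[length(per_gene) + 1]] <-
        list(class = "sense", sub = paste(sort(unique(subs)), collapse = "/"),
             id = g$gene_id)
    } else {
      subs <- character(0)
      if (end >= u5r[1] && start <= u5r[2]) subs <- c(subs, "1")
      if (end >= g$start && start <= g$end) subs <- c(subs, "2")
      if (end >= u3r[1] && start <= u3r[2]) subs <- c(subs, "3")
      per_gene[[length(per_gene) + 1]] <-
        list(class = "antisense", sub = paste(sort(unique(subs)), collapse = "/"),
             id = g$gene_id)
    }
  }
  rank <- c(trans = 1, antisense = 2, sense = 3, leader = 4, orf_cover = 5)
  if (length(per_gene) > 0) {
    best <- names(which.max(rank[vapply(per_gene, `[[`, "", "class")]))
    sel <- Filter(function(h) h$class == best, per_gene)
    subs <- unlist(strsplit(unlist(lapply(sel, `[[`, "sub")), "/"))
    subs <- sort(unique(subs[nzchar(subs)]))
    return(list(class = best, subtype = paste(subs, collapse = "/")))
  }
  left <- genes[genes$end < start, , drop = FALSE]
  right <- genes[genes$start > end, , drop = FALSE]
  type <- "2"
  if (nrow(left) > 0 && nrow(right) > 0) {
    gl <- left[which.max(left$end), ]; gr <- right[which.min(right$start), ]
    if (gl$strand != strand && gr$strand != strand) type <- "1"
  }
  list(class = "trans", subtype = type)
}

# ---- PSSM word enumeration ------------------------------------------------

# score distribution of a PSSM by enumerating all 4^w words
oracle_pssm_enumeration <- function(log_odds, background) {
  w <- ncol(log_odds)
  words <- expand.grid(rep(list(1:4), w))
  score <- apply(words, 1, function(ix)
    sum(log_odds[cbind(ix, seq_len(w))]))
  prob <- apply(words, 1, function(ix) prod(background[ix]))
  list(score = score, prob = prob)
}

# ---- structure enumeration ------------------------------------------------

# all secondary structures (dot-bracket) with minimum hairpin loop 3
oracle_enum_structures <- function(n, minh = 3) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (j < i) return("")
    out <- paste0(".", rec(i + 1, j))
    if (j - i >= minh + 1) for (l in (i + minh + 1):j) {
      inner <- rec(i + 1, l - 1); rest <- rec(l + 1, j)
      out <- c(out, as.vector(outer(inner, rest,
                                    function(a, b) paste0("(", a, ")", b))))
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# exact shape probabilities by enumerating the full ensemble
oracle_shape_probs <- function(sq, model) {
  structs <- oracle_enum_structures(nchar(sq), model$min_hairpin)
  w <- vapply(structs, function(st) {
    e <- tryCatch(structure_energy(st, sq, model), error = function(e) NA_real_)
    if (is.na(e)) 0 else exp(-e / model$RT)
  }, numeric(1))
  keep <- w > 0
  structs <- structs[keep]; w <- w[keep]
  shp <- vapply(structs, abstract_shape, "")
  p <- tapply(w / sum(w), shp, sum)
  list(probs = p, Z = sum(w) + 0)
}

# ---- ORF brute force -------------------------------------------------------

oracle_orfs <- function(sq, min_len = 60,
                        starts = c("ATG", "GTG", "TTG"),
                        stops = c("TAA", "TAG", "TGA")) {
  n <- nchar(sq)
  rows <- list()
  for (i in seq_len(n - 5)) {
    if (!substr(sq, i, i + 2) %in% starts) next
    j <- i + 3
    while (j + 2 <= n) {
      cod <- substr(sq, j, j + 2)
      if (cod %in% stops) {
        len <- j + 2 - i + 1
        if (len >= min_len)
          rows[[length(rows) + 1]] <- data.frame(
            frame = (i - 1) %% 3, start = i, stop = j + 2, length = len)
        break
      }
      j <- j + 3
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(0), start = integer(0),
                      stop = integer(0), length = integer(0))
  out[order(out$start, out$stop), , drop = FALSE]
}

# ---- shared small fixtures -------------------------------------------------

# random ACGT string
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

make_genome <- function(seqs, circular = FALSE) {
  structure(list(seq = Biostrings::DNAStringSet(seqs),
                 circular = setNames(rep(circular, length(seqs)), names(seqs))),
            class = "sr_genome")
}

# a toy two-gene annotation on one 3 kb replicon used for classifier sweeps
toy_two_gene_annotation <- function(strand1 = "+", strand2 = "+") {
  data.frame(gene_id = c("gA", "gB"), replicon = "chr",
             strand = c(strand1, strand2),
             start = c(1001L, 2001L), end = c(1300L, 2400L),
             kind = "CDS", stringsAsFactors = FALSE)
}
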