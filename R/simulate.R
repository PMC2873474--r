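#' Simulation configuration
#'
#' Settings for the seeded synthetic-data generator. The defaults emulate the
#' study design the pipeline was built for: a GC-rich (62%) multi-replicon
#' alphaproteobacterial genome, planted small transcripts of every positional
#' class with lengths in the sequenced size window (50--348 nt), a
#' primary-transcript-enriched library (s1) whose reads start at the
#' transcription start site, and a processed-transcript-enriched library (s2)
#' whose reads start either at the TSS or at one internal processing site per
#' transcript.
#'
#' @param genome_lengths named integer vector of replicon lengths
#' @param n_genes total number of annotated genes to place
#' @param gc_fraction genome GC content (default 0.62)
#' @param n_transcripts number of planted transcripts
#' @param class_mix named proportions over classes trans/antisense/leader/
#'   sense/orf_cover; must sum to 1
#' @param mean_depth Poisson mean read count per planted transcript per library
#' @param background_read_rate background ("degradation") reads per nt per
#'   strand per library
#' @param end_noise_sd Gaussian sd (nt) on simulated 5'-end positions
#' @param primary_fraction probability a planted transcript is primary
#'   (carries a true TSS visible in s1)
#' @param s1_processed_depth_factor depth multiplier in s1 for non-primary
#'   transcripts (enrichment against processed RNA)
#' @param full_length_prob probability a read runs through to the transcript
#'   3'-end (gives distinct 3'-ends)
#' @param read_length_range 454-like read length bounds (default c(50, 350))
#' @param short_read_length Illumina-like fixed read length (default 36)
#' @param read_mode "454" (variable-length) or "illumina" (fixed short reads)
#' @param min_intergenic minimum gap between placed genes (default 150 nt)
#' @param gene_length_range CDS length bounds, multiples of 3 within
#' @param transcript_length_range planted transcript length bounds
#' @param circular logical, replicons circular (default FALSE)
#' @param rng_seed integer seed driving all randomness
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(genome_lengths = c(chromosome = 200000L,
                                          plasmid_a = 100000L,
                                          plasmid_b = 100000L),
                       n_genes = 120L,
                       gc_fraction = 0.62,
                       n_transcripts = 60L,
                       class_mix = c(trans = 0.15, antisense = 0.10,
                                     leader = 0.34, sense = 0.40,
                                     orf_cover = 0.01),
                       mean_depth = 25,
                       background_read_rate = 1e-5,
                       end_noise_sd = 0,
                       primary_fraction = 0.7,
                       s1_processed_depth_factor = 0.1,
                       full_length_prob = 0.5,
                       read_length_range = c(50L, 350L),
                       short_read_length = 36L,
                       read_mode = c("454", "illumina"),
                       min_intergenic = 150L,
                       gene_length_range = c(180L, 1200L),
                       transcript_length_range = c(50L, 348L),
                       circular = FALSE,
                       rng_seed = 1L) {
  if (is.null(names(genome_lengths)) || anyDuplicated(names(genome_lengths)))
    stop("genome_lengths must be a uniquely named vector")
  .stopifnot_scalar_number(gc_fraction, "gc_fraction", 0, 1)
  .stopifnot_scalar_number(mean_depth, "mean_depth", min = 0)
  .stopifnot_scalar_number(background_read_rate, "background_read_rate", min = 0)
  .stopifnot_scalar_number(end_noise_sd, "end_noise_sd", min = 0)
  .stopifnot_scalar_number(primary_fraction, "primary_fraction", 0, 1)
  cls <- c("trans", "antisense", "leader", "sense", "orf_cover")
  if (!all(names(class_mix) %in% cls)) stop("unknown class in class_mix")
  mix <- setNames(numeric(5), cls)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-8) stop("class_mix proportions must sum to 1")
  structure(list(
    genome_lengths = genome_lengths, n_genes = as.integer(n_genes),
    gc_fraction = gc_fraction, n_transcripts = as.integer(n_transcripts),
    class_mix = mix, mean_depth = mean_depth,
    background_read_rate = background_read_rate, end_noise_sd = end_noise_sd,
    primary_fraction = primary_fraction,
    s1_processed_depth_factor = s1_processed_depth_factor,
    full_length_prob = full_length_prob,
    read_length_range = as.integer(read_length_range),
    short_read_length = as.integer(short_read_length),
    read_mode = match.arg(read_mode),
    min_intergenic = as.integer(min_intergenic),
    gene_length_range = as.integer(gene_length_range),
    transcript_length_range = as.integer(transcript_length_range),
    circular = circular, rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

.gene_kind_probs <- c(CDS = 0.92, rRNA = 0.02, tRNA = 0.02, "repeat" = 0.02,
                      transposase = 0.02)

#' Generate a synthetic genome and annotation
#'
#' Replicon sequences are i.i.d. bases at the configured GC fraction. Genes
#' (mostly CDS, with a small admixture of rRNA/tRNA/repeat/transposase
#' features) are placed non-overlapping along each replicon on random strands
#' with intergenic gaps of at least \code{min_intergenic} nt. Deterministic
#' given \code{rng_seed}.
#'
#' @param config [sim_config()]
#' @return list with \code{genome} (class \code{sr_genome}: a
#'   \code{DNAStringSet} plus a circularity flag) and \code{annotation}
#'   (data.frame gene_id, replicon, strand, start, end, kind)
#' @export
generate_genome <- function(config = sim_config()) {
  set.seed(.derive_seed(config$rng_seed, 1L))
  gc <- config$gc_fraction
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(config$genome_lengths, function(L) {
    paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
          collapse = "")
  }, character(1))
  genome <- structure(list(
    seq = Biostrings::DNAStringSet(seqs),
    circular = setNames(rep(config$circular, length(seqs)), names(seqs))),
    class = "sr_genome")

  ann <- data.frame(gene_id = character(0), replicon = character(0),
                    strand = character(0), start = integer(0), end = integer(0),
                    kind = character(0), stringsAsFactors = FALSE)
  if (config$n_genes > 0) {
    lens <- config$genome_lengths
    per <- round(config$n_genes * lens / sum(lens))
    # fix rounding so the total matches exactly
    d <- config$n_genes - sum(per)
    if (d != 0) per[1] <- per[1] + d
    rows <- list(); gi <- 0L
    for (r in names(lens)) {
      k <- per[[r]]
      if (k == 0) next
      glr <- config$gene_length_range
      glen <- 3L * sample(seq(ceiling(glr[1] / 3), floor(glr[2] / 3)), k,
                          replace = TRUE)
      need <- sum(glen) + (k + 1L) * config$min_intergenic
      if (need > lens[[r]])
        stop(sprintf("cannot place %d genes on replicon '%s' (%d nt needed, %d available)",
                     k, r, need, lens[[r]]))
      slack <- lens[[r]] - need
      extra <- as.vector(rmultinom(1, slack, rep(1, k + 1L)))
      pos <- config$min_intergenic + extra[1] + 1L
      for (j in seq_len(k)) {
        gi <- gi + 1L
        rows[[gi]] <- data.frame(
          gene_id = sprintf("gene_%04d", gi), replicon = r,
          strand = sample(c("+", "-"), 1), start = pos,
          end = pos + glen[j] - 1L,
          kind = sample(names(.gene_kind_probs), 1, prob = .gene_kind_probs),
          stringsAsFactors = FALSE)
        pos <- pos + glen[j] + config$min_intergenic + extra[j + 1L]
      }
    }
    ann <- do.call(rbind, rows)
  }
  list(genome = genome, annotation = ann)
}

#' Replicon lengths of a synthetic genome
#' @param genome \code{sr_genome}
#' @return named integer vector
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome$seq), names(genome$seq))
}

# gene-frame -> genomic conversion for an interval [u_lo, u_hi] relative to
# gene g (u = 0 at the first CDS base along the gene's direction)
.frame_to_genomic <- function(g, u_lo, u_hi) {
  if (g$strand == "+") c(g$start + u_lo, g$start + u_hi)
  else c(g$end - u_hi, g$end - u_lo)
}

#' Plant synthetic transcripts of every class
#'
#' Draws class labels from \code{class_mix} and places each transcript so that
#' its (strand, TSS, 3'-end) provably satisfies the positional rule of its
#' class against the annotation; every placement is verified with the same
#' geometric classifier used downstream and retried elsewhere if it fails
#' (bounded retries). Each transcript is marked primary (carries a true TSS)
#' with probability \code{primary_fraction} and gets one internal cleavage
#' site (when long enough) used by the processed-library read model.
#'
#' @param genome,annotation output of [generate_genome()]
#' @param config [sim_config()]
#' @param params [classifier_params()] used for placement geometry
#' @return data.frame (class \code{sr_truth}): transcript_id, replicon,
#'   strand, tss, end3, start, end, length, true_class, true_subtype,
#'   associated_gene, is_primary, cleavage_site
#' @export
plant_transcripts <- function(genome, annotation, config = sim_config(),
                              params = classifier_params()) {
  set.seed(.derive_seed(config$rng_seed, 2L))
  n <- config$n_transcripts
  empty <- data.frame(transcript_id = character(0), replicon = character(0),
                      strand = character(0), tss = integer(0), end3 = integer(0),
                      start = integer(0), end = integer(0), length = integer(0),
                      true_class = character(0), true_subtype = character(0),
                      associated_gene = character(0), is_primary = logical(0),
                      cleavage_site = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("sr_truth", "data.frame")
  if (n == 0) return(empty)
  counts <- as.vector(rmultinom(1, n, config$class_mix))
  classes <- rep(names(config$class_mix), counts)
  classes <- sample(classes)  # interleave
  gene_classes <- c("antisense", "leader", "sense", "orf_cover")
  if (any(classes %in% gene_classes) && nrow(annotation) == 0)
    stop("annotation is empty but class_mix includes gene-associated classes")

  lens <- genome_lengths(genome)
  cds <- annotation[annotation$kind == "CDS", , drop = FALSE]
  tlr <- config$transcript_length_range
  margin <- 400L          # keep away from replicon ends
  sep <- 30L              # min same-strand separation between plants
  occupied <- list()      # per replicon/strand list of intervals
  occ_key <- function(r, s) paste0(r, s)
  overlaps_occupied <- function(r, s, a, b) {
    iv <- occupied[[occ_key(r, s)]]
    if (is.null(iv)) return(FALSE)
    any(iv[, 1] <= b + sep & iv[, 2] >= a - sep)
  }
  push_occupied <- function(r, s, a, b) {
    k <- occ_key(r, s)
    occupied[[k]] <<- rbind(occupied[[k]], c(a, b))
  }
  # intervals free of every MTU (both strands), per replicon, for trans plants
  free_iv <- lapply(names(lens), function(r) {
    gr <- annotation[annotation$replicon == r &
                     annotation$kind %in% .coding_kinds, , drop = FALSE]
    lo <- margin; hi <- lens[[r]] - margin
    if (nrow(gr) == 0) return(matrix(c(lo, hi), ncol = 2))
    mlo <- ifelse(gr$strand == "+", gr$start - params$utr5, gr$start - params$utr3)
    mhi <- ifelse(gr$strand == "+", gr$end + params$utr3, gr$end + params$utr5)
    o <- order(mlo)
    mlo <- mlo[o]; mhi <- mhi[o]
    out <- NULL; cur <- lo
    for (i in seq_along(mlo)) {
      if (mlo[i] - 1 >= cur) out <- rbind(out, c(cur, mlo[i] - 1))
      cur <- max(cur, mhi[i] + 1)
    }
    if (cur <= hi) out <- rbind(out, c(cur, hi))
    if (is.null(out)) matrix(numeric(0), ncol = 2) else out
  })
  names(free_iv) <- names(lens)

  propose <- function(cls) {
    # returns list(replicon, strand, start, end, gene) or NULL
    rlen <- function(len) sample(seq(tlr[1], min(tlr[2], len)), 1)
    if (cls == "trans") {
      r <- sample(names(lens), 1, prob = lens)
      iv <- free_iv[[r]]
      len <- rlen(tlr[2])
      ok <- which(iv[, 2] - iv[, 1] + 1 >= len + 2)
      if (length(ok) == 0) return(NULL)
      i <- ok[sample.int(length(ok), 1)]
      a <- sample(seq(iv[i, 1], iv[i, 2] - len + 1), 1)
      return(list(replicon = r, strand = sample(c("+", "-"), 1),
                  start = a, end = a + len - 1, gene = NA_character_))
    }
    if (nrow(cds) == 0) return(NULL)
    g <- cds[sample.int(nrow(cds), 1), ]
    gl <- g$end - g$start + 1L
    u <- switch(cls,
      leader = {
        if (gl < 120) return(NULL)
        u5 <- sample(seq(-params$leader_window, 1), 1)
        lmax <- min(tlr[2], gl - 2L - u5 + 1L)
        if (lmax < tlr[1]) return(NULL)
        len <- sample(seq(tlr[1], lmax), 1)
        c(u5, u5 + len - 1L)
      },
      orf_cover = {
        room <- tlr[2] - gl
        if (room < 2 || gl < tlr[1]) return(NULL)
        u5 <- -sample(0:min(8, room - 1), 1)
        u3 <- gl - 1L + sample(0:min(8, room + u5), 1)
        c(u5, u3)
      },
      sense = {
        st <- sample(1:4, 1)
        if (st == 1) {
          u5 <- sample(seq(-params$utr5, -params$leader_window - 1L), 1)
          lmax <- min(tlr[2], gl - 1L - u5 + 1L)
          lmin <- max(tlr[1], 1L - u5)   # 3'-end must reach the CDS
          if (lmax < lmin) return(NULL)
          len <- sample(seq(lmin, lmax), 1)
          c(u5, u5 + len - 1L)
        } else if (st == 2) {
          if (gl < tlr[1] + 3L) return(NULL)
          lmax <- min(tlr[2], gl - 3L)
          len <- sample(seq(tlr[1], lmax), 1)
          u5 <- sample(seq(2L, gl - 1L - len + 1L), 1)
          c(u5, u5 + len - 1L)
        } else if (st == 3) {
          u3 <- gl + sample(0:(params$utr3 - 1L), 1)
          lmax <- min(tlr[2], u3 - 2L + 1L)
          lmin <- max(tlr[1], u3 - (gl - 1L) + 1L)  # 5'-end inside the CDS
          if (lmax < lmin) return(NULL)
          len <- sample(seq(lmin, lmax), 1)
          c(u3 - len + 1L, u3)
        } else {
          u5 <- gl + sample(0:(params$utr3 - 1L), 1)
          len <- rlen(tlr[2])
          c(u5, u5 + len - 1L)
        }
      },
      antisense = {
        st <- sample(1:3, 1)
        if (st == 1) {
          y <- -sample(1:10, 1)
          len <- rlen(tlr[2])
          c(y - len + 1L, y)
        } else if (st == 2) {
          if (gl < tlr[1] + 2L) return(NULL)
          lmax <- min(tlr[2], gl - 2L)
          len <- sample(seq(tlr[1], lmax), 1)
          x <- sample(seq(1L, gl - 1L - len + 1L), 1)
          c(x, x + len - 1L)
        } else {
          x <- gl + sample(0:10, 1)
          len <- rlen(tlr[2])
          c(x, x + len - 1L)
        }
      })
    if (is.null(u)) return(NULL)
    ab <- .frame_to_genomic(g, u[1], u[2])
    strand <- if (cls == "antisense") .opposite_strand(g$strand) else g$strand
    list(replicon = g$replicon, strand = strand, start = ab[1], end = ab[2],
         gene = g$gene_id)
  }

  coding <- annotation[annotation$kind %in% .coding_kinds, , drop = FALSE]
  genes_by_rep <- split(coding, coding$replicon)
  excl <- annotation[annotation$kind %in% .excluded_kinds_default, ,
                     drop = FALSE]
  rows <- vector("list", length(classes))
  for (ti in seq_along(classes)) {
    cls <- classes[ti]
    placed <- FALSE
    for (try in 1:200) {
      p <- propose(cls)
      if (is.null(p)) next
      if (p$start < margin || p$end > lens[[p$replicon]] - margin) next
      if (overlaps_occupied(p$replicon, p$strand, p$start, p$end)) next
      if (nrow(excl) > 0 &&
          any(excl$replicon == p$replicon & excl$start <= p$end &
              excl$end >= p$start)) next
      gctx <- genes_by_rep[[p$replicon]]
      if (is.null(gctx)) gctx <- annotation[0, ]
      got <- .classify_interval(p$start, p$end, p$strand, gctx, params)
      if (got$class != cls) next
      len <- p$end - p$start + 1L
      tss <- .five_prime(p$start, p$end, p$strand)
      end3 <- .three_prime(p$start, p$end, p$strand)
      cleave <- NA_integer_
      if (len >= 110) {
        off <- sample(seq(30L, len - 60L), 1)
        cleave <- if (p$strand == "+") tss + off else tss - off
      }
      rows[[ti]] <- data.frame(
        transcript_id = sprintf("srna_%03d", ti), replicon = p$replicon,
        strand = p$strand, tss = tss, end3 = end3,
        start = p$start, end = p$end, length = len,
        true_class = cls, true_subtype = got$subtype,
        associated_gene = if (cls %in% c("trans")) NA_character_ else p$gene,
        is_primary = runif(1) < config$primary_fraction,
        cleavage_site = cleave, stringsAsFactors = FALSE)
      push_occupied(p$replicon, p$strand, p$start, p$end)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("no legal placement found for a '%s' transcript after bounded retries", cls))
  }
  truth <- do.call(rbind, rows)
  class(truth) <- c("sr_truth", "data.frame")
  truth
}

.protocols <- c("s1_primary", "s2_processed", "total")

#' Simulate strand-specific reads from planted transcripts
#'
#' Read model per protocol: in \code{s1_primary}, reads of primary transcripts
#' start at the TSS plus rounded Gaussian noise (\code{end_noise_sd});
#' non-primary transcripts appear only as depleted, uniformly fragmented
#' background (factor \code{s1_processed_depth_factor}). In
#' \code{s2_processed}, reads of every transcript start at the TSS with
#' probability 0.5 and at the transcript's internal cleavage site with
#' probability 0.5. Reads run through to the transcript 3'-end with
#' probability \code{full_length_prob}, otherwise they end prematurely at a
#' uniform position. \code{total} reads follow the s2 model but carry no
#' strand. Per-transcript read counts are Poisson(\code{mean_depth}); uniform
#' background reads are added at \code{background_read_rate} per nt per
#' strand. Reads on circular replicons that cross the origin are reported as
#' two alignment segments sharing a read id.
#'
#' @param truth output of [plant_transcripts()]
#' @param genome \code{sr_genome}
#' @param config [sim_config()]
#' @param protocol one of "s1_primary", "s2_processed", "total"
#' @return data.frame (class \code{sr_alignments}): read_id, replicon, strand,
#'   start, end, sample
#' @export
simulate_reads <- function(truth, genome, config = sim_config(),
                           protocol = c("s1_primary", "s2_processed", "total")) {
  protocol <- match.arg(protocol)
  set.seed(.derive_seed(config$rng_seed, 10L + match(protocol, .protocols)))
  lens <- genome_lengths(genome)
  rlr <- config$read_length_range
  illumina <- identical(config$read_mode, "illumina")
  rows <- list(); ridx <- 0L

  emit <- function(replicon, strand, a, b) {
    ridx <<- ridx + 1L
    L <- lens[[replicon]]
    id <- sprintf("%s_r%06d", protocol, ridx)
    circ <- genome$circular[[replicon]]
    if (a < 1 || b > L) {
      if (circ) {
        # wrap: split into two segments
        a1 <- ((a - 1) %% L) + 1; b1 <- ((b - 1) %% L) + 1
        if (a1 > b1) {
          rows[[length(rows) + 1L]] <<- data.frame(
            read_id = id, replicon = replicon, strand = strand,
            start = a1, end = L, sample = protocol, stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <<- data.frame(
            read_id = id, replicon = replicon, strand = strand,
            start = 1, end = b1, sample = protocol, stringsAsFactors = FALSE)
          return(invisible(NULL))
        }
        a <- a1; b <- b1
      } else {
        a <- max(1, a); b <- min(L, b)
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      read_id = id, replicon = replicon, strand = strand,
      start = a, end = b, sample = protocol, stringsAsFactors = FALSE)
  }

  strandless <- identical(protocol, "total")
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      depth <- config$mean_depth
      scatter <- FALSE
      if (protocol == "s1_primary" && !tr$is_primary) {
        depth <- depth * config$s1_processed_depth_factor
        scatter <- TRUE
      }
      nr <- rpois(1, depth)
      if (nr == 0) next
      dirn <- if (tr$strand == "+") 1L else -1L
      # transcript-frame offset of the planted internal cleavage site
      off_cleave <- if (is.na(tr$cleavage_site)) NA_integer_
                    else dirn * (tr$cleavage_site - tr$tss)
      for (k in seq_len(nr)) {
        # off5: read 5'-end offset along the transcript (0 = TSS)
        if (scatter) {
          off5 <- sample.int(max(1L, tr$length - rlr[1] + 1L), 1) - 1L
        } else if (protocol == "s1_primary") {
          off5 <- as.integer(round(rnorm(1, 0, config$end_noise_sd)))
        } else {
          base <- if (!is.na(off_cleave) && runif(1) < 0.5) off_cleave else 0L
          off5 <- base + as.integer(round(rnorm(1, 0, config$end_noise_sd)))
        }
        span <- tr$length - off5      # bases from the read 5'-end to the 3'-end
        if (span < rlr[1]) {          # pushed too close to the 3'-end
          off5 <- tr$length - min(rlr[1], tr$length)
          span <- tr$length - off5
        }
        if (illumina) {
          len <- min(config$short_read_length, span)
        } else if (runif(1) < config$full_length_prob) {
          len <- min(span, rlr[2])
        } else {
          len <- if (span <= rlr[1]) span
                 else sample(seq(rlr[1], min(rlr[2], span)), 1)
        }
        p5 <- tr$tss + dirn * off5
        p3 <- tr$tss + dirn * (off5 + len - 1L)
        emit(tr$replicon, if (strandless) NA_character_ else tr$strand,
             min(p5, p3), max(p5, p3))
      }
    }
  }
  if (config$background_read_rate > 0) {
    for (r in names(lens)) {
      for (s in c("+", "-")) {
        nb <- rpois(1, config$background_read_rate * lens[[r]])
        if (nb == 0) next
        for (k in seq_len(nb)) {
          a <- sample.int(lens[[r]], 1)
          len <- if (illumina) config$short_read_length
                 else sample(seq(rlr[1], rlr[2]), 1)
          emit(r, if (strandless) NA_character_ else s, a, a + len - 1L)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), replicon = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               sample = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sr_alignments", "data.frame")
  out
}
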