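.dna_bases <- c("A", "C", "G", "T")

#' Build a position-specific scoring matrix
#'
#' Column probabilities are pseudocount-smoothed frequencies,
#' P(b) = (count_b + pseudocount) / (n + 4 * pseudocount), and scores are
#' base-2 log-odds against the background: log2(P(b) / background(b)).
#'
#' @param training character vector of equal-length ACGT strings
#' @param pseudocount added to every base count (default 0.01)
#' @param background named base frequencies summing to 1 (default uniform)
#' @return object of class \code{pssm}
#' @export
build_pssm <- function(training, pseudocount = 0.01,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(training) == 0) stop("no training sequences")
  training <- toupper(training)
  w <- unique(nchar(training))
  if (length(w) != 1L) stop("training sequences have ragged lengths")
  mat <- do.call(rbind, strsplit(training, ""))
  if (!all(mat %in% .dna_bases)) stop("training sequences must be ACGT only")
  background <- background[.dna_bases]
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  counts <- apply(mat, 2, function(col)
    vapply(.dna_bases, function(b) sum(col == b), numeric(1)))
  probs <- (counts + pseudocount) /
    (length(training) + 4 * pseudocount)
  log_odds <- log2(probs / background)   # -Inf allowed when pseudocount = 0
  obj <- structure(list(width = w, counts = counts, pseudocount = pseudocount,
                        background = background, probs = probs,
                        log_odds = log_odds, .cache = new.env(parent = emptyenv())),
                   class = "pssm")
  obj
}

#' Score a sequence (or all its windows) with a PSSM
#'
#' @param pssm a [build_pssm()] object
#' @param sequence ACGT string; windows of width \code{pssm$width} are scored
#' @return numeric vector of window scores (length nchar - width + 1)
#' @export
pssm_score <- function(pssm, sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(s, .dna_bases)
  if (anyNA(idx)) stop("sequence must be ACGT only")
  n <- length(s) - pssm$width + 1L
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) {
    sum(pssm$log_odds[cbind(idx[i:(i + pssm$width - 1L)], seq_len(pssm$width))])
  }, numeric(1))
}

# exact distribution of the PSSM score under the background model, on a
# discretized lattice (bin bits per step); returns list(score, prob) sorted
.pssm_score_distribution <- function(pssm, bin = 1e-4) {
  key <- if (!is.null(pssm$.cache)) sprintf("dist_%g", bin) else NULL
  if (!is.null(key) && !is.null(pssm$.cache[[key]])) return(pssm$.cache[[key]])
  neg_key <- -.Machine$integer.max / 2   # sentinel lattice key for -Inf scores
  keys <- 0; probs <- 1
  for (j in seq_len(pssm$width)) {
    lo <- pssm$log_odds[, j]
    k_col <- ifelse(is.finite(lo), round(lo / bin), neg_key)
    new_keys <- as.vector(outer(keys, k_col, `+`))
    new_probs <- as.vector(outer(probs, pssm$background, `*`))
    agg <- tapply(new_probs, new_keys, sum)
    keys <- as.numeric(names(agg))
    probs <- as.vector(agg)
  }
  o <- order(keys)
  out <- list(score = keys[o] * bin, key = keys[o], prob = probs[o], bin = bin)
  if (!is.null(key)) pssm$.cache[[key]] <- out
  out
}

#' Exact P-value of a PSSM score
#'
#' P-value semantics: the probability that a random word drawn from the
#' background model scores at least \code{score}. Computed exactly by
#' dynamic-programming convolution of the per-column score distributions on a
#' lattice with \code{bin} bits per step (exact up to the discretization,
#' which is asserted against full word enumeration for small widths in the
#' test suite). Scores above the matrix maximum give 0, scores at or below
#' the minimum give 1.
#'
#' @param pssm a [build_pssm()] object
#' @param score numeric score(s) on the log-odds scale
#' @param bin lattice resolution in bits (default 1e-4)
#' @return P-value(s) in [0, 1]
#' @export
score_pvalue <- function(pssm, score, bin = 1e-4) {
  dist <- .pssm_score_distribution(pssm, bin)
  # lattice keys are per-column roundings, so a query rounded as a whole can
  # sit up to `width` bins away; the slack keeps equal scores equal without
  # merging genuinely distinct ones (score gaps are far larger than the bin)
  slack <- (pssm$width + 1) * bin
  vapply(score, function(s) {
    if (!is.finite(s)) return(if (s > 0) 0 else 1)
    sum(dist$prob[dist$key * bin >= s - slack])
  }, numeric(1))
}

#' Two-box sigma-70 promoter model
#'
#' A -35 box PSSM and a -10 box PSSM separated by a variable spacer. A
#' placement is a hit when the product of the two exact box P-values is at
#' or below \code{pvalue_cutoff}. The default cutoff is the published search
#' cutoff of the wide single-matrix search this model descends from; it is
#' extremely stringent for a 12-informative-position two-box score (see the
#' methods vignette), so practical scans may configure a laxer value.
#'
#' @param box35,box10 width-6 [build_pssm()] objects
#' @param spacer_range allowed spacer lengths in nt (default c(15, 19))
#' @param pvalue_cutoff combined P-value threshold (default 2.155343e-11)
#' @param tss_max_dist maximum distance (nt) from the -10 box 3'-end to the
#'   TSS (default 10)
#' @return object of class \code{promoter_model}
#' @export
promoter_model <- function(box35, box10, spacer_range = c(15L, 19L),
                           pvalue_cutoff = 2.155343e-11, tss_max_dist = 10L) {
  if (spacer_range[1] > spacer_range[2]) stop("bad spacer_range")
  structure(list(box35 = box35, box10 = box10,
                 spacer_range = as.integer(spacer_range),
                 pvalue_cutoff = pvalue_cutoff,
                 tss_max_dist = as.integer(tss_max_dist)),
            class = "promoter_model")
}

#' Consensus-trained promoter model
#'
#' Convenience constructor: trains both boxes on the literal consensus motif
#' (-35 box CTTGAC, -10 box CTATAT) repeated \code{n} times, with the given
#' pseudocount and background.
#'
#' @param n copies of the consensus in the training set (default 25)
#' @param pseudocount see [build_pssm()]
#' @param background base frequencies (default uniform); use the genome's
#'   base composition for genome scans
#' @param ... passed to [promoter_model()]
#' @return \code{promoter_model}
#' @export
consensus_promoter_model <- function(n = 25, pseudocount = 0.01,
                                     background = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25), ...) {
  promoter_model(build_pssm(rep("CTTGAC", n), pseudocount, background),
                 build_pssm(rep("CTATAT", n), pseudocount, background), ...)
}

#' Genome base frequencies
#' @param genome \code{sr_genome}
#' @return named frequency vector over A, C, G, T
#' @export
genome_base_frequencies <- function(genome) {
  f <- colSums(Biostrings::alphabetFrequency(genome$seq)[, .dna_bases,
                                                         drop = FALSE])
  f / sum(f)
}

#' Primary TSS positions from labeled ends
#' @param labeled_ends list of [label_primary()] results
#' @return data.frame contig_id, replicon, strand, position
#' @export
primary_tss_table <- function(labeled_ends) {
  rows <- lapply(labeled_ends, function(e) {
    f <- e$five_prime
    if (is.null(f$is_primary)) return(NULL)
    f <- f[which(f$is_primary), , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    data.frame(contig_id = e$contig_id, replicon = e$replicon,
               strand = e$strand, position = f$position,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), replicon = character(0),
                      strand = character(0), position = integer(0))
  rownames(out) <- NULL
  out
}

#' Scan upstream of TSSs for two-box promoter placements
#'
#' For each TSS the strand-aware upstream window is scanned for a -35 box,
#' a spacer within \code{spacer_range}, and a -10 box whose 3'-end lies
#' within \code{tss_max_dist} nt upstream of the TSS. The combined score is
#' the sum of the box scores; the combined P-value is the product of the two
#' exact box P-values (independence). All placements at or below the model's
#' cutoff are reported, so a TSS may yield several hits.
#'
#' @param model [promoter_model()]
#' @param genome \code{sr_genome}
#' @param tss data.frame replicon, strand, position (e.g.
#'   [primary_tss_table()]); an optional contig_id column is carried through
#' @param window upstream window length in nt (default 100)
#' @param pvalue_cutoff override of the model cutoff
#' @return data.frame: contig_id, replicon, strand, tss, box35_start, spacer,
#'   score, pvalue (box35_start is the genomic coordinate of the box base
#'   closest to the replicon start)
#' @export
scan_upstream <- function(model, genome, tss, window = 100,
                          pvalue_cutoff = model$pvalue_cutoff) {
  lens <- genome_lengths(genome)
  w35 <- model$box35$width; w10 <- model$box10$width
  hits <- list()
  for (i in seq_len(nrow(tss))) {
    t <- tss[i, ]
    L <- lens[[t$replicon]]
    W <- window
    if (t$strand == "+") {
      lo <- t$position - W; hi <- t$position - 1L
      if (lo < 1) { warning("upstream window truncated at replicon start")
        lo <- 1L }
    } else {
      lo <- t$position + 1L; hi <- t$position + W
      if (hi > L) { warning("upstream window truncated at replicon end")
        hi <- L }
    }
    if (hi < lo) next
    W <- hi - lo + 1L
    seq_w <- as.character(Biostrings::subseq(genome$seq[[t$replicon]], lo, hi))
    if (t$strand == "-")
      seq_w <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_w)))
    # frame position w = 1..W runs 5'->3' toward the TSS; distance of frame
    # position w to the TSS is W - w + 1
    s35 <- pssm_score(model$box35, seq_w)
    s10 <- pssm_score(model$box10, seq_w)
    for (i35 in seq_along(s35)) {
      for (sp in model$spacer_range[1]:model$spacer_range[2]) {
        i10 <- i35 + w35 + sp
        if (i10 > length(s10)) next
        end10 <- i10 + w10 - 1L
        dist_tss <- W - end10 + 1L
        if (dist_tss < 1L || dist_tss > model$tss_max_dist) next
        pv <- score_pvalue(model$box35, s35[i35]) *
          score_pvalue(model$box10, s10[i10])
        if (pv <= pvalue_cutoff) {
          g35 <- if (t$strand == "+") lo + i35 - 1L else hi - i35 + 1L - (w35 - 1L)
          hits[[length(hits) + 1L]] <- data.frame(
            contig_id = if ("contig_id" %in% names(t)) t$contig_id else NA_character_,
            replicon = t$replicon, strand = t$strand, tss = t$position,
            box35_start = g35, spacer = sp,
            score = s35[i35] + s10[i10], pvalue = pv,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), replicon = character(0),
                      strand = character(0), tss = integer(0),
                      box35_start = integer(0), spacer = integer(0),
                      score = numeric(0), pvalue = numeric(0))
  rownames(out) <- NULL
  out
}

#' Literal consensus motif matches
#'
#' Finds all (possibly overlapping) matches of the literal consensus
#' CTTGAC - N17 - CTATAT in a sequence, on the given strand (for "-" the
#' reverse complement is scanned and positions refer to the scanned
#' orientation).
#'
#' @param x DNA string (character or \code{DNAString})
#' @param strand "+" or "-"
#' @return integer vector of 1-based match start positions
#' @export
match_consensus <- function(x, strand = "+") {
  subj <- Biostrings::DNAString(as.character(x))
  if (strand == "-") subj <- Biostrings::reverseComplement(subj)
  pat <- paste0("CTTGAC", strrep("N", 17), "CTATAT")
  m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  IRanges::start(methods::as(m, "IRanges"))
}
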