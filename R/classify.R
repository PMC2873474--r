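#' Classifier parameters
#'
#' Geometry constants for positional classification of called transcription
#' units against the gene annotation. A gene's minimal transcription unit
#' (MTU) is its CDS extended by an assumed 5'-UTR of \code{utr5} nt and an
#' assumed 3'-UTR of \code{utr3} nt. \code{leader_window} is the span
#' immediately upstream of a start codon within which a same-strand 5'-end
#' marks an mRNA leader rather than a sense sRNA. \code{cluster_gap} is the
#' maximum separation (exclusive) for chaining candidates into clusters.
#'
#' @param utr5 assumed 5'-UTR length in nt (default 60)
#' @param utr3 assumed 3'-UTR length in nt (default 20)
#' @param leader_window leader 5'-end window upstream of the start codon (default 40)
#' @param cluster_gap cluster chaining gap in nt, exclusive (default 200)
#' @return object of class \code{classifier_params}
#' @export
classifier_params <- function(utr5 = 60, utr3 = 20, leader_window = 40,
                              cluster_gap = 200) {
  .stopifnot_scalar_number(utr5, "utr5", min = 0)
  .stopifnot_scalar_number(utr3, "utr3", min = 0)
  .stopifnot_scalar_number(leader_window, "leader_window", min = 0)
  .stopifnot_scalar_number(cluster_gap, "cluster_gap", min = 0)
  if (leader_window > utr5) stop("leader_window must not exceed utr5")
  structure(list(utr5 = utr5, utr3 = utr3, leader_window = leader_window,
                 cluster_gap = cluster_gap), class = "classifier_params")
}

.class_rank <- c(trans = 1, antisense = 2, sense = 3, leader = 4, orf_cover = 5)

# Relation of one stranded interval to one gene, in the gene's own frame.
# Frame coordinate u: u = 0 at the first base of the start codon,
# u = gl - 1 at the last base of the stop codon (gl = CDS length).
.relate_interval_to_gene <- function(start, end, strand, g, params) {
  gl <- g$end - g$start + 1L
  if (g$strand == "+") {
    c1 <- start - g$start; c2 <- end - g$start
  } else {
    c1 <- g$end - end; c2 <- g$end - start
  }
  x <- min(c1, c2); y <- max(c1, c2)
  mtu_lo <- -params$utr5; mtu_hi <- gl - 1L + params$utr3
  if (y < mtu_lo || x > mtu_hi) return(NULL)      # no MTU overlap
  same <- identical(strand, g$strand)
  if (same) {
    s5 <- x; s3 <- y                               # contig runs with the gene
    if (x <= 0 && y >= gl - 1L)
      return(list(class = "orf_cover", subtype = ""))
    if (s5 >= -params$leader_window && s5 <= 1 && s3 >= 1 && s3 <= gl - 2L)
      return(list(class = "leader", subtype = ""))
    sub <- character(0)
    if (s5 >= -params$utr5 && s5 <= -params$leader_window - 1L &&
        s3 >= 0 && s3 <= gl - 1L) sub <- c(sub, "1")
    if (s5 >= 0 && s3 <= gl - 1L) sub <- c(sub, "2")
    if (x <= gl - 1L && y >= 0 && s3 >= gl && s3 <= gl - 1L + params$utr3)
      sub <- c(sub, "3")
    if (s5 >= gl && s5 <= gl - 1L + params$utr3) sub <- c(sub, "4")
    if (length(sub) == 0L) {
      # degenerate layouts (e.g. contig wholly inside the 5'-UTR): fall back
      # to the overlapped MTU region
      if (y <= -1L) sub <- "1" else if (x >= gl) sub <- "4" else sub <- "2"
    }
    return(list(class = "sense", subtype = paste(sort(unique(sub)), collapse = "/")))
  }
  sub <- character(0)
  if (x <= -1L && y >= -params$utr5) sub <- c(sub, "1")          # anti 5'-UTR
  if (x <= gl - 1L && y >= 0) sub <- c(sub, "2")                 # anti CDS
  if (x <= gl - 1L + params$utr3 && y >= gl) sub <- c(sub, "3")  # anti 3'-UTR
  list(class = "antisense", subtype = paste(sort(unique(sub)), collapse = "/"))
}

# Core positional decision for one stranded interval. Returns list(class,
# subtype, genes). `genes` is the data.frame of context genes on the interval's
# replicon (protein-coding kinds only).
.classify_interval <- function(start, end, strand, genes, params) {
  best <- NULL; best_rank <- 0
  hits <- list()
  if (nrow(genes) > 0) {
    near <- which(genes$start <= end + params$utr5 + 1 &
                  genes$end >= start - params$utr5 - 1)
    for (i in near) {
      g <- genes[i, ]
      rel <- .relate_interval_to_gene(start, end, strand, g, params)
      if (is.null(rel)) next
      rel$gene_id <- g$gene_id
      hits[[length(hits) + 1L]] <- rel
      r <- .class_rank[[rel$class]]
      if (r > best_rank) { best_rank <- r; best <- rel$class }
    }
  }
  if (!is.null(best)) {
    sel <- Filter(function(h) h$class == best, hits)
    subs <- unlist(lapply(sel, `[[`, "subtype"))
    subs <- sort(unique(unlist(strsplit(subs[nzchar(subs)], "/", fixed = TRUE))))
    return(list(class = best,
                subtype = paste(subs, collapse = "/"),
                genes = vapply(sel, `[[`, "", "gene_id")))
  }
  # trans: no MTU overlap on either strand; type 1 iff the nearest flanking
  # gene on each side (either strand) is antisense to the interval
  type <- "2"
  if (nrow(genes) > 0) {
    left <- genes[genes$end < start, , drop = FALSE]
    right <- genes[genes$start > end, , drop = FALSE]
    if (nrow(left) > 0 && nrow(right) > 0) {
      gl <- left[which.max(left$end), ]
      gr <- right[which.min(right$start), ]
      if (gl$strand != strand && gr$strand != strand) type <- "1"
    }
  }
  list(class = "trans", subtype = type, genes = character(0))
}

.coding_kinds <- c("CDS", "transposase")
.excluded_kinds_default <- c("rRNA", "tRNA", "repeat")

#' Classify one contig against the annotation
#'
#' Assigns the positional RNA class of a called transcription unit relative to
#' annotated genes: \code{orf_cover} (same strand, covers a whole CDS),
#' \code{leader} (same strand, 5'-end within \code{leader_window} nt upstream
#' of -- or 1 nt into -- a start codon and 3'-end strictly inside the CDS),
#' \code{sense} (same strand, any other MTU overlap; subtypes 1--4 by which
#' part of the MTU is touched), \code{antisense} (opposite strand MTU overlap;
#' subtypes 1--3 for 5'-UTR/CDS/3'-UTR), and \code{trans} (no MTU overlap on
#' either strand; type 1 when both nearest flanking genes run antisense to the
#' contig, else type 2). Same-strand relations take precedence over antisense;
#' relations to several genes of the winning class yield joined subtypes such
#' as \code{"1/3"}.
#'
#' @param contig one-row data.frame with replicon, strand, start, end
#' @param annotation gene annotation data.frame (see [generate_genome()])
#' @param params [classifier_params()]
#' @return list with elements class, subtype, genes
#' @export
classify_contig <- function(contig, annotation, params = classifier_params()) {
  .check_strand(contig$strand)
  if (is.na(contig$strand)) stop("cannot classify an unstranded contig")
  genes <- annotation[annotation$replicon == contig$replicon &
                      annotation$kind %in% .coding_kinds, , drop = FALSE]
  .classify_interval(contig$start, contig$end, contig$strand, genes, params)
}

#' Classify a set of contigs
#'
#' Contigs overlapping annotated rRNA/tRNA/repeat features (on either strand)
#' are excluded before classification, mirroring the removal of structural-RNA
#' and repeat reads from the candidate set; contigs overlapping annotated
#' transposase genes are classified normally but flagged
#' (\code{te_associated}) so that transposable-element-associated candidates
#' can be reported separately.
#'
#' @param contigs contig data.frame from [call_contigs()]
#' @param annotation gene annotation data.frame
#' @param params [classifier_params()]
#' @param exclude_kinds annotation kinds that veto classification
#' @return data.frame with one row per contig: contig_id, replicon, strand,
#'   start, end, length, rna_class, subtype, associated_genes, te_associated,
#'   excluded, excluded_reason
#' @export
classify_contigs <- function(contigs, annotation, params = classifier_params(),
                             exclude_kinds = .excluded_kinds_default) {
  n <- nrow(contigs)
  out <- data.frame(
    contig_id = contigs$contig_id, replicon = contigs$replicon,
    strand = contigs$strand, start = contigs$start, end = contigs$end,
    length = contigs$end - contigs$start + 1L,
    rna_class = rep(NA_character_, n), subtype = rep(NA_character_, n),
    associated_genes = rep(NA_character_, n), te_associated = rep(FALSE, n),
    excluded = rep(FALSE, n), excluded_reason = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  excl <- annotation[annotation$kind %in% exclude_kinds, , drop = FALSE]
  te <- annotation[annotation$kind == "transposase", , drop = FALSE]
  for (i in seq_len(n)) {
    ci <- contigs[i, ]
    if (nrow(excl) > 0) {
      hit <- excl$replicon == ci$replicon & excl$start <= ci$end &
        excl$end >= ci$start
      if (any(hit)) {
        out$excluded[i] <- TRUE
        out$excluded_reason[i] <-
          paste0("overlaps ", paste(sort(unique(excl$kind[hit])), collapse = ","))
        next
      }
    }
    if (nrow(te) > 0) {
      out$te_associated[i] <- any(te$replicon == ci$replicon &
                                  te$start <= ci$end & te$end >= ci$start)
    }
    cl <- classify_contig(ci, annotation, params)
    out$rna_class[i] <- cl$class
    out$subtype[i] <- cl$subtype
    out$associated_genes[i] <- paste(cl$genes, collapse = ",")
  }
  out
}

#' Find clusters of candidates
#'
#' Single-linkage chaining of classified candidates along each replicon
#' (strand-agnostic): two neighbours belong to the same cluster when the
#' gap between them is strictly less than \code{cluster_gap} nt. Only
#' clusters of at least two members are reported.
#'
#' @param classified output of [classify_contigs()] (excluded rows are ignored)
#' @param params [classifier_params()]
#' @return data.frame with columns cluster_id, contig_id (empty if none)
#' @export
find_clusters <- function(classified, params = classifier_params()) {
  d <- classified[!classified$excluded, , drop = FALSE]
  empty <- data.frame(cluster_id = integer(0), contig_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(d) < 2) return(empty)
  d <- d[order(d$replicon, d$start, d$end), ]
  cl <- integer(nrow(d)); cl[1] <- 1L
  for (i in 2:nrow(d)) {
    gap <- d$start[i] - d$end[i - 1] - 1L
    new <- d$replicon[i] != d$replicon[i - 1] || gap >= params$cluster_gap
    cl[i] <- cl[i - 1] + as.integer(new)
  }
  keep <- cl %in% which(tabulate(cl) >= 2L)
  d <- d[keep, , drop = FALSE]; cl <- cl[keep]
  if (nrow(d) == 0) return(empty)
  data.frame(cluster_id = as.integer(factor(cl)), contig_id = d$contig_id,
             stringsAsFactors = FALSE)
}

#' Summarize classified candidates
#'
#' Counts per (replicon, class, subtype) plus per-class length statistics
#' (min, first quartile, median, mean, third quartile, max; quartiles by
#' linear interpolation).
#'
#' @param classified output of [classify_contigs()]
#' @return list with data.frames \code{counts} and \code{size_stats}
#' @export
summarize_classes <- function(classified) {
  d <- classified[!classified$excluded & !is.na(classified$rna_class), ,
                  drop = FALSE]
  if (nrow(d) == 0) {
    return(list(
      counts = data.frame(replicon = character(0), rna_class = character(0),
                          subtype = character(0), n = integer(0)),
      size_stats = data.frame(rna_class = character(0), n = integer(0),
                              min = numeric(0), q1 = numeric(0),
                              median = numeric(0), mean = numeric(0),
                              q3 = numeric(0), max = numeric(0))))
  }
  counts <- aggregate(list(n = seq_len(nrow(d))),
                      by = list(replicon = d$replicon, rna_class = d$rna_class,
                                subtype = d$subtype),
                      FUN = length)
  counts <- counts[order(counts$replicon, counts$rna_class, counts$subtype), ]
  rownames(counts) <- NULL
  stats_one <- function(lens) {
    q <- quantile(lens, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(lens), min = min(lens), q1 = q[1], median = q[2],
               mean = mean(lens), q3 = q[3], max = max(lens))
  }
  ss <- do.call(rbind, lapply(split(d$length, d$rna_class), stats_one))
  ss <- cbind(data.frame(rna_class = rownames(ss), stringsAsFactors = FALSE), ss)
  rownames(ss) <- NULL
  list(counts = counts, size_stats = ss)
}
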