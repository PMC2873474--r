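.end_category <- function(n) {
  if (n <= 2L) as.character(n) else "m"
}

#' Call distinct 5'- and 3'-ends of a contig
#'
#' A position is a distinct 5'-end when (a) it lies within the first two bases
#' of the contig (strand-aware) and more than \code{min_reads} reads share it
#' as their 5'-end, or (b) it lies elsewhere in the contig, more than
#' \code{min_reads} reads share it and that count is at least
#' \code{mean_fraction} of the contig's mean read depth. Symmetric rules apply
#' to distinct 3'-ends on the 3'-end counts. Ends closer than \code{merge_radius}
#' are optionally merged for reporting (default: reported separately, since
#' ends varying by one or two nucleotides are a real phenomenon).
#'
#' @param contig one-row contig data.frame (from [call_contigs()])
#' @param track \code{sr_coverage} the contig was called from
#' @param samples sample(s) whose end counts are interrogated (e.g.
#'   \code{"s1_primary"}); also used for the mean-depth reference
#' @param min_reads strict lower bound on shared-end reads (default 5:
#'   "more than 5" = at least 6)
#' @param mean_fraction fraction of contig mean depth required away from the
#'   contig edge (default 0.10)
#' @param merge_radius merge distance in nt for reporting (default 0)
#' @return list of class \code{sr_ends}: contig_id, strand, five_prime and
#'   three_prime data.frames (position, count), end_category_5/3
#'   (\code{"0"/"1"/"2"/"m"}), mean_depth
#' @export
call_distinct_ends <- function(contig, track, samples = NULL, min_reads = 5,
                               mean_fraction = 0.10, merge_radius = 0) {
  if (is.null(samples)) samples <- track$sample_names
  if (!contig$replicon %in% names(track$replicon_lengths))
    stop(sprintf("contig replicon '%s' not present in the coverage track",
                 contig$replicon))
  a <- contig$start; b <- contig$end; s <- contig$strand
  depth <- .pooled_vector(track, contig$replicon, s, samples, "depth")
  mean_depth <- mean(depth[a:b])
  starts5 <- .pooled_vector(track, contig$replicon, s, samples, "starts5")
  ends3 <- .pooled_vector(track, contig$replicon, s, samples, "ends3")
  first_two_5 <- if (s == "-") c(b, b - 1L) else c(a, a + 1L)
  first_two_3 <- if (s == "-") c(a, a + 1L) else c(b, b - 1L)
  pick <- function(counts, edge) {
    pos <- a:b
    cnt <- counts[pos]
    at_edge <- pos %in% edge
    keep <- (cnt > min_reads) &
      (at_edge | cnt >= mean_fraction * mean_depth)
    data.frame(position = pos[keep], count = cnt[keep])
  }
  merge_ends <- function(df) {
    if (merge_radius <= 0 || nrow(df) < 2) return(df)
    df <- df[order(df$position), ]
    grp <- cumsum(c(1L, diff(df$position) > merge_radius))
    do.call(rbind, lapply(split(df, grp), function(g) {
      data.frame(position = g$position[which.max(g$count)],
                 count = sum(g$count))
    }))
  }
  fp <- merge_ends(pick(starts5, first_two_5))
  tp <- merge_ends(pick(ends3, first_two_3))
  rownames(fp) <- rownames(tp) <- NULL
  structure(list(contig_id = contig$contig_id, strand = s,
                 replicon = contig$replicon,
                 five_prime = fp, three_prime = tp,
                 end_category_5 = .end_category(nrow(fp)),
                 end_category_3 = .end_category(nrow(tp)),
                 mean_depth = mean_depth, samples = samples),
            class = "sr_ends")
}

#' Label 5'-ends primary or processed by comparing libraries
#'
#' A 5'-end is primary iff it is a distinct 5'-end of the
#' primary-transcript-enriched library (s1); ends found only in the
#' processed-enriched library (s2) are processed. Ends present in both are
#' primary with support \code{"s1,s2"}. 3'-ends are merged with sample
#' support but carry no primary flag.
#'
#' @param ends_s1,ends_s2 \code{sr_ends} for the same contig, computed on the
#'   s1 and s2 samples respectively
#' @return \code{sr_ends} with extra columns samples and (5' only) is_primary;
#'   end categories recomputed on the merged lists
#' @export
label_primary <- function(ends_s1, ends_s2) {
  if (!identical(ends_s1$contig_id, ends_s2$contig_id))
    stop("ends were computed on different contigs")
  merge_lists <- function(d1, d2) {
    pos <- sort(unique(c(d1$position, d2$position)))
    in1 <- pos %in% d1$position; in2 <- pos %in% d2$position
    cnt <- ifelse(in1, d1$count[match(pos, d1$position)], 0) +
      ifelse(in2, d2$count[match(pos, d2$position)], 0)
    data.frame(position = pos, count = cnt,
               samples = ifelse(in1 & in2, "s1,s2", ifelse(in1, "s1", "s2")),
               stringsAsFactors = FALSE)
  }
  fp <- merge_lists(ends_s1$five_prime, ends_s2$five_prime)
  fp$is_primary <- grepl("s1", fp$samples, fixed = TRUE)
  tp <- merge_lists(ends_s1$three_prime, ends_s2$three_prime)
  structure(list(contig_id = ends_s1$contig_id, strand = ends_s1$strand,
                 replicon = ends_s1$replicon,
                 five_prime = fp, three_prime = tp,
                 end_category_5 = .end_category(nrow(fp)),
                 end_category_3 = .end_category(nrow(tp)),
                 mean_depth = ends_s1$mean_depth,
                 samples = c(ends_s1$samples, ends_s2$samples)),
            class = "sr_ends")
}

#' Cross-tabulate end categories and sample support
#'
#' Builds the end-property summary: for each candidate the 5'-end category
#' (0/1/2/m), the 3'-end category, and the sample support ("S1", "S2" or
#' "S1&2": which libraries contributed distinct ends; candidates with no
#' distinct end at all are tabulated under support "none").
#'
#' @param labeled_ends list of [label_primary()] results
#' @return data.frame cat5, cat3, support, n
#' @export
tabulate_end_categories <- function(labeled_ends) {
  rows <- lapply(labeled_ends, function(e) {
    smp <- unique(unlist(strsplit(c(e$five_prime$samples, e$three_prime$samples),
                                  ",", fixed = TRUE)))
    support <- if (length(smp) == 0) "none"
    else if (all(c("s1", "s2") %in% smp)) "S1&2"
    else if ("s1" %in% smp) "S1" else "S2"
    data.frame(cat5 = e$end_category_5, cat3 = e$end_category_3,
               support = support, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) == 0)
    return(data.frame(cat5 = character(0), cat3 = character(0),
                      support = character(0), n = integer(0)))
  out <- aggregate(list(n = seq_len(nrow(d))),
                   by = list(cat5 = d$cat5, cat3 = d$cat3, support = d$support),
                   FUN = length)
  out[order(out$cat5, out$cat3, out$support), , drop = FALSE]
}

#' Ends of all contigs as one table
#'
#' @param labeled_ends list of \code{sr_ends} (labeled or not)
#' @return data.frame contig_id, end_type, position, count, samples, is_primary
#' @export
ends_table <- function(labeled_ends) {
  rows <- lapply(labeled_ends, function(e) {
    f <- e$five_prime; t <- e$three_prime
    rbind(
      if (nrow(f)) data.frame(contig_id = e$contig_id, end_type = "5p",
                              position = f$position, count = f$count,
                              samples = f$samples %||% NA_character_,
                              is_primary = f$is_primary %||% NA,
                              stringsAsFactors = FALSE),
      if (nrow(t)) data.frame(contig_id = e$contig_id, end_type = "3p",
                              position = t$position, count = t$count,
                              samples = t$samples %||% NA_character_,
                              is_primary = NA, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), end_type = character(0),
                      position = integer(0), count = numeric(0),
                      samples = character(0), is_primary = logical(0))
  rownames(out) <- NULL
  out
}
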