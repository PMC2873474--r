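#' M/A values of two-channel probe signals
#'
#' M is the base-2 log ratio of the small-RNA-fraction channel over the
#' long-RNA-fraction channel; A is half the base-2 log of their product
#' (the standard MA-plot transform). Both channels must be positive.
#'
#' @param probes data.frame with probe_id, channel_small, channel_long
#' @return data.frame probe_id, M, A
#' @export
ma_values <- function(probes) {
  bad <- probes$channel_small <= 0 | probes$channel_long <= 0
  if (any(bad))
    stop(sprintf("non-positive intensity for probe '%s'",
                 probes$probe_id[which(bad)[1]]))
  data.frame(probe_id = probes$probe_id,
             M = log2(probes$channel_small / probes$channel_long),
             A = 0.5 * log2(probes$channel_small * probes$channel_long),
             stringsAsFactors = FALSE)
}

#' Two-channel enrichment candidates
#'
#' Probes whose M-value reaches \code{m_threshold} (inclusive). The default
#' threshold of 3 encodes an 8-fold (2^3) enrichment of the small-RNA
#' fraction.
#'
#' @param ma output of [ma_values()]
#' @param m_threshold minimum M-value (default 3)
#' @return character vector of candidate probe ids
#' @export
call_array_candidates <- function(ma, m_threshold = 3) {
  ma$probe_id[ma$M >= m_threshold]
}

#' Tiling-chip candidate regions
#'
#' A probe is significant when its signal is at least \code{fold} times its
#' background. Significant probes lying in the same intergenic region are
#' chained while consecutive probes are at most \code{max_gap} nt apart
#' (end-to-start distance); regions need at least two probes.
#'
#' @param probes data.frame probe_id, replicon, strand, start, end, signal,
#'   background
#' @param annotation gene annotation used to delimit intergenic regions
#'   (probes overlapping an annotated gene are not considered); pass NULL to
#'   treat each replicon as one region
#' @param fold signal-over-background factor (default 2)
#' @param max_gap maximum probe separation in nt (default 200, per the
#'   hybridization criteria; 150 is used by some reports of the same screen)
#' @return data.frame region_id, replicon, start, end, n_probes, probe_ids
#' @export
call_chip_candidates <- function(probes, annotation = NULL, fold = 2,
                                 max_gap = 200) {
  sig <- probes[probes$signal >= fold * probes$background, , drop = FALSE]
  empty <- data.frame(region_id = character(0), replicon = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), probe_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) < 2) return(empty)
  if (!is.null(annotation) && nrow(annotation) > 0) {
    in_gene <- vapply(seq_len(nrow(sig)), function(i) {
      any(annotation$replicon == sig$replicon[i] &
            annotation$start <= sig$end[i] & annotation$end >= sig$start[i])
    }, logical(1))
    sig <- sig[!in_gene, , drop = FALSE]
    # intergenic region index: number of genes fully upstream of the probe
    igr <- vapply(seq_len(nrow(sig)), function(i) {
      a <- annotation[annotation$replicon == sig$replicon[i], , drop = FALSE]
      paste(sig$replicon[i], sum(a$end < sig$start[i]))
    }, character(1))
  } else {
    igr <- sig$replicon
  }
  if (nrow(sig) < 2) return(empty)
  o <- order(sig$replicon, sig$start)
  sig <- sig[o, , drop = FALSE]; igr <- igr[o]
  grp <- integer(nrow(sig)); grp[1] <- 1L
  if (nrow(sig) > 1) for (i in 2:nrow(sig)) {
    gap <- sig$start[i] - sig$end[i - 1]
    new <- igr[i] != igr[i - 1] || gap > max_gap
    grp[i] <- grp[i - 1] + as.integer(new)
  }
  keep <- grp %in% which(tabulate(grp) >= 2L)
  sig <- sig[keep, , drop = FALSE]; grp <- grp[keep]
  if (nrow(sig) == 0) return(empty)
  out <- do.call(rbind, lapply(split(seq_len(nrow(sig)), grp), function(ix) {
    data.frame(replicon = sig$replicon[ix[1]], start = min(sig$start[ix]),
               end = max(sig$end[ix]), n_probes = length(ix),
               probe_ids = paste(sig$probe_id[ix], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- cbind(data.frame(region_id = sprintf("region_%03d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
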