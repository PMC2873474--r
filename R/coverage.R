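#' Build per-strand coverage tracks from alignments
#'
#' For every (sample, replicon, strand) the track holds three per-position
#' count vectors: \code{depth} (reads whose interval contains the position),
#' \code{starts5} (biological 5'-ends: the lower coordinate on "+", the
#' higher on "-") and \code{ends3} (biological 3'-ends). Unstranded
#' alignments (strand \code{NA}) are stored under strand \code{"*"} with
#' depth only.
#'
#' @param alignments data.frame read_id, replicon, strand, start, end, sample
#' @param genome \code{sr_genome} (supplies replicon lengths)
#' @return object of class \code{sr_coverage}
#' @export
build_coverage <- function(alignments, genome) {
  lens <- genome_lengths(genome)
  bad <- !alignments$replicon %in% names(lens)
  if (any(bad))
    stop(sprintf("alignment '%s' references unknown replicon '%s'",
                 alignments$read_id[which(bad)[1]],
                 alignments$replicon[which(bad)[1]]))
  out_of_range <- alignments$start < 1 |
    alignments$end > lens[alignments$replicon] | alignments$start > alignments$end
  if (any(out_of_range))
    stop(sprintf("alignment '%s' lies outside its replicon",
                 alignments$read_id[which(out_of_range)[1]]))
  .check_strand(alignments$strand)
  samples <- sort(unique(alignments$sample))
  tracks <- list()
  for (smp in samples) {
    al_s <- alignments[alignments$sample == smp, , drop = FALSE]
    tracks[[smp]] <- list()
    for (r in unique(al_s$replicon)) {
      al_r <- al_s[al_s$replicon == r, , drop = FALSE]
      L <- lens[[r]]
      tracks[[smp]][[r]] <- list()
      strands <- unique(ifelse(is.na(al_r$strand), "*", al_r$strand))
      for (s in strands) {
        if (s == "*") al <- al_r[is.na(al_r$strand), , drop = FALSE]
        else al <- al_r[!is.na(al_r$strand) & al_r$strand == s, , drop = FALSE]
        depth <- numeric(L)
        # difference-array accumulation of interval coverage
        d <- numeric(L + 1L)
        tab_a <- tabulate(al$start, nbins = L)
        tab_b <- tabulate(al$end + 1L, nbins = L + 1L)
        d[seq_len(L)] <- tab_a
        d <- d - tab_b
        depth <- cumsum(d[seq_len(L)])
        if (s == "*") {
          starts5 <- numeric(L); ends3 <- numeric(L)
        } else if (s == "+") {
          starts5 <- tabulate(al$start, nbins = L)
          ends3 <- tabulate(al$end, nbins = L)
        } else {
          starts5 <- tabulate(al$end, nbins = L)
          ends3 <- tabulate(al$start, nbins = L)
        }
        tracks[[smp]][[r]][[s]] <- list(depth = depth, starts5 = starts5,
                                        ends3 = ends3)
      }
    }
  }
  structure(list(samples = tracks, replicon_lengths = lens,
                 sample_names = samples), class = "sr_coverage")
}

# pooled per-position depth (or starts5/ends3) over chosen samples
.pooled_vector <- function(track, replicon, strand, samples, what = "depth",
                           include_unstranded = FALSE) {
  L <- track$replicon_lengths[[replicon]]
  if (is.null(L)) stop(sprintf("unknown replicon '%s'", replicon))
  v <- numeric(L)
  for (smp in samples) {
    t_r <- track$samples[[smp]][[replicon]]
    if (is.null(t_r)) next
    if (!is.null(t_r[[strand]])) v <- v + t_r[[strand]][[what]]
    if (include_unstranded && what == "depth" && !is.null(t_r[["*"]]))
      v <- v + t_r[["*"]][["depth"]]
  }
  v
}

#' Contig caller parameters
#'
#' Seed-and-extend thresholds: a contig is seeded by a run of positions with
#' depth at least \code{C} of length at least \code{L_min}, and extended on
#' either side while depth stays at least \code{c}. Contigs whose extended
#' length exceeds \code{L_max} are flagged over-length (the sequenced size
#' fraction makes such transcripts unobservable, so over-length calls signal
#' misconfiguration rather than biology).
#'
#' @param L_min,L_max seed length bounds in nt
#' @param C seed depth threshold (reads)
#' @param c extension depth threshold (reads)
#' @return object of class \code{contig_params}
#' @export
contig_params <- function(L_min = 50, L_max = 350, C = 10, c = 5) {
  if (!(c > 0 && c <= C)) stop("need 0 < c <= C")
  if (!(L_min > 0 && L_min <= L_max)) stop("need 0 < L_min <= L_max")
  structure(list(L_min = L_min, L_max = L_max, C = C, c = c),
            class = "contig_params")
}

#' 454 preset: L 50--350, C = 10, c = 5
#' @rdname contig_params
#' @export
contig_params_454 <- function() contig_params(50, 350, 10, 5)

#' Short-read preset: L = 50, C = 5, c = 2
#' @rdname contig_params
#' @export
contig_params_illumina <- function() contig_params(50, 350, 5, 2)

# maximal runs of v >= thr as a 2-column matrix (start, end); 0 rows if none
.runs_at_least <- function(v, thr) {
  ok <- v >= thr
  if (!any(ok)) return(matrix(integer(0), ncol = 2))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Call contigs with the seed-and-extend coverage rule
#'
#' Returns the maximal runs of pooled depth >= \code{c} that contain at least
#' one run of depth >= \code{C} of length >= \code{L_min}. The retained seed
#' interval is the longest qualifying >= C run (leftmost on ties). Unstranded
#' libraries contribute depth only when \code{include_unstranded = TRUE}
#' (strand information cannot be recovered from them, so by default they are
#' excluded from strand-specific calling).
#'
#' @param track \code{sr_coverage} from [build_coverage()]
#' @param params [contig_params()]
#' @param samples samples pooled for depth (default: all stranded samples in
#'   the track)
#' @param include_unstranded add unstranded ("*") depth to both strands
#' @param drop_over_length drop contigs longer than \code{L_max} from the
#'   result (default keeps them, flagged)
#' @return data.frame: contig_id, replicon, strand, start, end, length,
#'   mean_depth, seed_start, seed_end, over_length, plus one
#'   \code{mean_depth_<sample>} column per pooled sample
#' @export
call_contigs <- function(track, params = contig_params(), samples = NULL,
                         include_unstranded = FALSE,
                         drop_over_length = FALSE) {
  if (is.null(samples)) samples <- track$sample_names
  rows <- list()
  for (r in names(track$replicon_lengths)) {
    for (s in c("+", "-")) {
      v <- .pooled_vector(track, r, s, samples, "depth", include_unstranded)
      if (!any(v >= params$c)) next
      ext <- .runs_at_least(v, params$c)
      for (i in seq_len(nrow(ext))) {
        a <- ext[i, 1]; b <- ext[i, 2]
        seeds <- .runs_at_least(v[a:b], params$C)
        if (nrow(seeds) == 0) next
        seeds <- seeds[seeds[, 2] - seeds[, 1] + 1L >= params$L_min, ,
                       drop = FALSE]
        if (nrow(seeds) == 0) next
        best <- which.max(seeds[, 2] - seeds[, 1])
        row <- data.frame(
          replicon = r, strand = s, start = a, end = b,
          length = b - a + 1L,
          mean_depth = mean(v[a:b]),
          seed_start = a + seeds[best, 1] - 1L,
          seed_end = a + seeds[best, 2] - 1L,
          over_length = (b - a + 1L) > params$L_max,
          stringsAsFactors = FALSE)
        for (smp in samples) {
          vs <- .pooled_vector(track, r, s, smp, "depth", FALSE)
          row[[paste0("mean_depth_", smp)]] <- mean(vs[a:b])
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(contig_id = character(0), replicon = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mean_depth = numeric(0), seed_start = integer(0),
                      seed_end = integer(0), over_length = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("sr_contigs", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$replicon, out$strand, out$start), , drop = FALSE]
  if (drop_over_length) out <- out[!out$over_length, , drop = FALSE]
  out <- cbind(data.frame(contig_id = sprintf("contig_%04d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  class(out) <- c("sr_contigs", "data.frame")
  out
}
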