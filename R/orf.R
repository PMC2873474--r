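#' Ribosome-binding-site screen parameters
#'
#' @param anti_sd anti-Shine-Dalgarno tail of the 16S rRNA, 5'->3' RNA
#'   (default UCCUCCA)
#' @param energy_threshold duplex free-energy call threshold in kcal/mol
#'   (default -3.4535); an RBS is called when the best duplex energy is at or
#'   below it
#' @param search_window window relative to the ORF start codon searched for
#'   the SD site, default positions -20 .. -4
#' @param start_codons recognised start codons (default ATG, GTG, TTG)
#' @param model [energy_model()] providing the RNA:RNA stacking table
#' @return object of class \code{rbs_params}
#' @export
rbs_params <- function(anti_sd = "UCCUCCA", energy_threshold = -3.4535,
                       search_window = c(-20L, -4L),
                       start_codons = c("ATG", "GTG", "TTG"),
                       model = energy_model()) {
  if (energy_threshold >= 0) stop("energy_threshold must be negative")
  if (search_window[2] >= 0 || search_window[1] > search_window[2])
    stop("search_window must lie upstream of the start codon")
  structure(list(anti_sd = toupper(anti_sd),
                 energy_threshold = energy_threshold,
                 search_window = as.integer(search_window),
                 start_codons = toupper(start_codons), model = model),
            class = "rbs_params")
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Find complete ORFs in a sequence
#'
#' Scans all three frames of the given (sense) strand for complete open
#' reading frames: a start codon followed by an in-frame stop codon within
#' the sequence. Length is counted start through stop codon inclusive and
#' must reach \code{min_len}. Every qualifying start is reported (nested
#' starts sharing a stop give separate calls).
#'
#' @param sequence ACGT string
#' @param min_len minimum ORF length in nt (default 60)
#' @param start_codons recognised start codons
#' @return data.frame frame (0-2), start, stop, length (positions 1-based on
#'   the given sequence; stop is the last base of the stop codon)
#' @export
find_orfs <- function(sequence, min_len = 60,
                      start_codons = c("ATG", "GTG", "TTG")) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("sequence must be ACGT only")
  n <- nchar(sequence)
  rows <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n, by = 3L)
    starts <- starts[starts + 2L <= n]
    if (length(starts) == 0) next
    codons <- substring(sequence, starts, starts + 2L)
    is_start <- codons %in% start_codons
    is_stop <- codons %in% .stop_codons
    stop_idx <- which(is_stop)
    for (i in which(is_start)) {
      nx <- stop_idx[stop_idx > i]
      if (length(nx) == 0) next
      j <- nx[1]
      len <- (starts[j] + 2L) - starts[i] + 1L
      if (len < min_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, start = starts[i], stop = starts[j] + 2L, length = len)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(0), start = integer(0),
                      stop = integer(0), length = integer(0))
  out[order(out$start, out$stop), , drop = FALSE]
}

# RNA complementarity including wobble
.rna_complementary <- function(a, b) paste0(a, b) %in% .rna_pairs

#' Anti-SD hybridization energy of an upstream window
#'
#' Slides the anti-SD tail along the window (ungapped, antiparallel) and
#' returns the minimum duplex free energy over all offsets. The duplex energy
#' at one offset is the sum of nearest-neighbor RNA:RNA stacking energies
#' over consecutive paired positions (Watson-Crick and G:U pairs). An RBS is
#' called when the minimum energy is at or below the threshold.
#'
#' @param upstream window sequence 5'->3' (sense strand, DNA or RNA alphabet)
#' @param params [rbs_params()]
#' @return list(energy, has_rbs, offset); energy NA and has_rbs NA when the
#'   window is shorter than the anti-SD
#' @export
rbs_energy <- function(upstream, params = rbs_params()) {
  win <- chartr("T", "U", toupper(upstream))
  asd <- chartr("T", "U", params$anti_sd)
  m <- nchar(asd); n <- nchar(win)
  if (n < m) return(list(energy = NA_real_, has_rbs = NA, offset = NA_integer_))
  wb <- strsplit(win, "")[[1]]
  ab <- strsplit(asd, "")[[1]]
  st <- params$model$stack
  best <- 0; best_off <- NA_integer_
  for (o in 0:(n - m)) {
    # anti_sd position j (5'->3') pairs window position o + (m - j + 1)
    pair_of <- character(m)
    for (j in seq_len(m)) {
      wpos <- o + (m - j + 1L)
      p <- paste0(wb[wpos], ab[j])       # window base on top strand
      pair_of[wpos - o] <- if (p %in% .rna_pairs) p else NA_character_
    }
    e <- 0
    for (k in seq_len(m - 1L)) {
      if (!is.na(pair_of[k]) && !is.na(pair_of[k + 1L]))
        e <- e + st[pair_of[k], pair_of[k + 1L]]
    }
    if (e < best) { best <- e; best_off <- o }
  }
  list(energy = best, has_rbs = best <= params$energy_threshold,
       offset = best_off)
}

#' Relate an ORF inside a candidate to its associated gene
#'
#' Positions the ORF (called on the candidate's sense-strand sequence) on the
#' genome and compares it to the associated gene: ORFs sharing the gene's
#' reading frame and stop codon are \code{same_frame_shared_stop}; ORFs
#' overlapping the gene in another frame (or in the same frame without a
#' shared stop) are \code{overlapping_other_frame}; ORFs lying entirely
#' upstream of the gene's start codon are \code{within_5utr}; anything else
#' is \code{none}. ORFs beginning exactly at the gene's own start codon are
#' excluded (\code{gene_start_excluded}) since they lack an in-frame stop on
#' the sRNA itself.
#'
#' @param orf one row of [find_orfs()] output
#' @param contig one-row contig data.frame (replicon, strand, start, end)
#' @param gene one-row annotation data.frame for the associated gene
#' @return character relation code
#' @export
relate_orf_to_gene <- function(orf, contig, gene) {
  if (is.null(gene) || nrow(gene) == 0) return("none")
  if (contig$strand == "+") {
    g_start5 <- contig$start + orf$start - 1L
    g_stop3 <- contig$start + orf$stop - 1L
  } else {
    g_start5 <- contig$end - orf$start + 1L
    g_stop3 <- contig$end - orf$stop + 1L
  }
  if (contig$strand != gene$strand) return("none")
  gene5 <- .five_prime(gene$start, gene$end, gene$strand)
  gene3 <- .three_prime(gene$start, gene$end, gene$strand)
  if (g_start5 == gene5) return("gene_start_excluded")
  same_frame <- (g_start5 - gene5) %% 3L == 0L
  lo <- min(g_start5, g_stop3); hi <- max(g_start5, g_stop3)
  overlaps <- lo <= gene$end && hi >= gene$start
  if (same_frame && g_stop3 == gene3) return("same_frame_shared_stop")
  if (overlaps) return("overlapping_other_frame")
  upstream <- if (gene$strand == "+") max(g_start5, g_stop3) < gene$start
              else min(g_start5, g_stop3) > gene$end
  if (upstream) return("within_5utr")
  "none"
}

#' Screen classified candidates for small ORFs with RBS
#'
#' Extracts each candidate's sense-strand sequence, finds complete ORFs of at
#' least \code{min_len} nt, scores the upstream anti-SD window (taken from
#' the genome, strand-aware, so it may extend beyond the candidate), and
#' relates each ORF to the candidate's associated gene.
#'
#' @param classified output of [classify_contigs()]
#' @param genome \code{sr_genome}
#' @param annotation gene annotation
#' @param min_len minimum ORF length (default 60)
#' @param params [rbs_params()]
#' @return data.frame: contig_id, frame, start, stop, length (contig-relative),
#'   rbs_energy, has_rbs, relation_to_gene
#' @export
screen_orfs <- function(classified, genome, annotation, min_len = 60,
                        params = rbs_params()) {
  d <- classified[!classified$excluded, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(d))) {
    ci <- d[i, ]
    seq_c <- as.character(Biostrings::subseq(genome$seq[[ci$replicon]],
                                             ci$start, ci$end))
    if (ci$strand == "-")
      seq_c <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_c)))
    orfs <- find_orfs(seq_c, min_len = min_len,
                      start_codons = params$start_codons)
    if (nrow(orfs) == 0) next
    gene_id <- strsplit(ci$associated_genes %||% "", ",")[[1]][1]
    gene <- annotation[!is.na(gene_id) & annotation$gene_id %in% gene_id, ,
                       drop = FALSE]
    L <- genome_lengths(genome)[[ci$replicon]]
    for (k in seq_len(nrow(orfs))) {
      orf <- orfs[k, ]
      rel <- relate_orf_to_gene(orf, ci, gene)
      if (rel == "gene_start_excluded") next
      # genomic coordinates of the RBS window, strand-aware
      if (ci$strand == "+") {
        g_start <- ci$start + orf$start - 1L
        wlo <- g_start + params$search_window[1]
        whi <- g_start + params$search_window[2]
        if (wlo < 1) wlo <- 1L
        win <- if (whi >= wlo)
          as.character(Biostrings::subseq(genome$seq[[ci$replicon]], wlo, whi))
          else ""
      } else {
        g_start <- ci$end - orf$start + 1L
        wlo <- g_start - params$search_window[2]
        whi <- g_start - params$search_window[1]
        if (whi > L) whi <- L
        win <- if (whi >= wlo)
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(
            as.character(Biostrings::subseq(genome$seq[[ci$replicon]],
                                            wlo, whi)))))
          else ""
      }
      rbs <- rbs_energy(win, params)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = ci$contig_id, frame = orf$frame, start = orf$start,
        stop = orf$stop, length = orf$length,
        rbs_energy = rbs$energy, has_rbs = rbs$has_rbs,
        relation_to_gene = rel, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), frame = integer(0),
                      start = integer(0), stop = integer(0),
                      length = integer(0), rbs_energy = numeric(0),
                      has_rbs = logical(0), relation_to_gene = character(0))
  rownames(out) <- NULL
  out
}
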