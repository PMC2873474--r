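#' Write / read a genome as FASTA
#' @param genome \code{sr_genome}
#' @param path file path
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param circular circularity flag(s) applied to the replicons on read
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(seq = seqs,
                 circular = setNames(rep_len(circular, length(seqs)),
                                     names(seqs))),
            class = "sr_genome")
}

.kind_to_gff_type <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                       "repeat" = "repeat_region", transposase = "CDS")

#' Write / read the gene annotation as GFF3
#'
#' Coordinates are 1-based inclusive. The annotation \code{kind} is carried
#' in a \code{kind} attribute (with conventional GFF3 feature types:
#' repeat features as \code{repeat_region}, transposase genes as CDS).
#'
#' @param annotation annotation data.frame
#' @param path file path
#' @param genome optional \code{sr_genome} supplying sequence lengths
#' @export
write_annotation_gff3 <- function(annotation, path, genome = NULL) {
  if (nrow(annotation) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$replicon,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$source <- rep("srnascout", nrow(annotation))
  S4Vectors::mcols(gr)$type <- unname(.kind_to_gff_type[annotation$kind])
  S4Vectors::mcols(gr)$phase <-
    ifelse(.kind_to_gff_type[annotation$kind] == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$kind <- annotation$kind
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop(sprintf("%s line %d: expected 9 GFF3 columns", path, i))
    st <- suppressWarnings(as.integer(f[4])); en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en) || en < st)
      stop(sprintf("%s line %d: invalid coordinates (end < start?)", path, i))
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  m <- S4Vectors::mcols(gr)
  kind <- if ("kind" %in% names(m)) as.character(m$kind)
          else as.character(m$type)
  kind[kind == "repeat_region"] <- "repeat"
  data.frame(gene_id = as.character(m$ID),
             replicon = as.character(GenomeInfoDb::seqnames(gr)),
             strand = as.character(BiocGenerics::strand(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             kind = kind, stringsAsFactors = FALSE)
}

#' Write / read alignments in a minimal SAM dialect
#'
#' The dialect is intentionally small: a header (@HD, @SQ with lengths), one
#' line per aligned read with FLAG 0 or 16 (bit 0x10 = minus strand), 1-based
#' POS, a match-only CIGAR (\code{<n>M}) carrying the read length, and
#' \code{*} for SEQ/QUAL. One file holds one sample's alignments; unstranded
#' alignments cannot be expressed in SAM and use the TSV dialect instead.
#'
#' @param alignments alignment data.frame for a single sample
#' @param genome \code{sr_genome}
#' @param path file path
#' @export
write_alignments_sam <- function(alignments, genome, path) {
  if (any(is.na(alignments$strand)))
    stop("SAM cannot express unstranded alignments; use the TSV dialect")
  lens <- genome_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  a <- alignments[order(alignments$replicon, alignments$start), , drop = FALSE]
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                 a$read_id, ifelse(a$strand == "-", 16L, 0L), a$replicon,
                 a$start, a$end - a$start + 1L)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_alignments_sam
#' @param sample sample label attached to the alignments on read
#' @export
read_alignments_sam <- function(path, sample) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body) == 0)
    return(data.frame(read_id = character(0), replicon = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), sample = character(0)))
  f <- strsplit(lines[body], "\t", fixed = TRUE)
  parse_one <- function(i) {
    x <- f[[i]]
    if (length(x) < 11)
      stop(sprintf("%s line %d: truncated SAM record", path, body[i]))
    if (!grepl("^[0-9]+M$", x[6]))
      stop(sprintf("%s line %d: unsupported CIGAR '%s' (match-only dialect)",
                   path, body[i], x[6]))
    len <- as.integer(sub("M$", "", x[6]))
    flag <- as.integer(x[2])
    start <- as.integer(x[4])
    data.frame(read_id = x[1], replicon = x[3],
               strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
               start = start, end = start + len - 1L, sample = sample,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(body), parse_one))
  rownames(out) <- NULL
  class(out) <- c("sr_alignments", "data.frame")
  out
}

#' Write / read alignments in the 6-column TSV dialect
#'
#' Columns: read_id, replicon, strand (+, - or . for unstranded), start, end,
#' sample. Coordinates 1-based inclusive.
#'
#' @param alignments alignment data.frame
#' @param path file path
#' @export
write_alignments_tsv <- function(alignments, path) {
  a <- alignments
  a$strand <- ifelse(is.na(a$strand), ".", a$strand)
  write.table(a[, c("read_id", "replicon", "strand", "start", "end", "sample")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  a <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "character",
                                 "integer", "integer", "character"))
  a$strand[a$strand == "."] <- NA_character_
  bad <- which(a$start > a$end)
  if (length(bad) > 0)
    stop(sprintf("%s: start > end for read '%s'", path, a$read_id[bad[1]]))
  class(a) <- c("sr_alignments", "data.frame")
  a
}

#' Export contigs as BED6
#'
#' BED is 0-based half-open; the conversion from the package's 1-based
#' inclusive coordinates is delegated to rtracklayer. Scores are mean depths
#' capped at 1000.
#'
#' @param contigs contig data.frame
#' @param path file path
#' @export
write_contigs_bed <- function(contigs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = contigs$replicon,
    ranges = IRanges::IRanges(start = contigs$start, end = contigs$end),
    strand = contigs$strand)
  S4Vectors::mcols(gr)$name <- contigs$contig_id
  S4Vectors::mcols(gr)$score <- pmin(1000, round(contigs$mean_depth))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a coverage vector as bedGraph
#'
#' @param track \code{sr_coverage}
#' @param sample sample to export
#' @param strand "+", "-" or "*"
#' @param path file path
#' @export
write_coverage_bedgraph <- function(track, sample, strand, path) {
  grl <- list()
  for (r in names(track$replicon_lengths)) {
    t_r <- track$samples[[sample]][[r]][[strand]]
    if (is.null(t_r)) next
    rl <- rle(t_r$depth)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values != 0
    if (!any(keep)) next
    grl[[r]] <- GenomicRanges::GRanges(
      seqnames = r,
      ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
      score = rl$values[keep])
  }
  gr <- if (length(grl)) do.call(c, unname(grl)) else
    GenomicRanges::GRanges(score = numeric(0))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Export classified candidates as GFF3
#'
#' Features are written as type \code{ncRNA} with class/subtype/associated
#' gene attributes; excluded contigs are omitted.
#'
#' @param classified output of [classify_contigs()]
#' @param path file path
#' @export
write_classified_gff3 <- function(classified, path) {
  d <- classified[!classified$excluded, , drop = FALSE]
  if (nrow(d) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = d$replicon,
    ranges = IRanges::IRanges(start = d$start, end = d$end),
    strand = d$strand)
  S4Vectors::mcols(gr)$source <- rep("srnascout", nrow(d))
  S4Vectors::mcols(gr)$type <- rep("ncRNA", nrow(d))
  S4Vectors::mcols(gr)$ID <- d$contig_id
  S4Vectors::mcols(gr)$rna_class <- d$rna_class
  S4Vectors::mcols(gr)$subtype <- d$subtype
  S4Vectors::mcols(gr)$associated_genes <- d$associated_genes
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write / read the planted-transcript truth table as TSV
#' @param truth \code{sr_truth}
#' @param path file path
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  t <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(t) <- c("sr_truth", "data.frame")
  t
}

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits genome FASTA, annotation GFF3, truth TSV, per-sample alignments as
#' both minimal SAM and 6-column TSV (the unstranded "total" library as TSV
#' only).
#'
#' @param config [sim_config()]
#' @param dir output directory (created)
#' @param with_total also simulate the unstranded total-RNA library
#' @return invisibly, a list with genome, annotation, truth and alignments
#' @export
write_synthetic_dataset <- function(config = sim_config(), dir,
                                    with_total = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ga <- generate_genome(config)
  truth <- plant_transcripts(ga$genome, ga$annotation, config)
  protos <- c("s1_primary", "s2_processed", if (with_total) "total")
  als <- lapply(protos, function(p)
    simulate_reads(truth, ga$genome, config, protocol = p))
  names(als) <- protos
  write_genome_fasta(ga$genome, file.path(dir, "genome.fasta"))
  write_annotation_gff3(ga$annotation, file.path(dir, "annotation.gff3"),
                        ga$genome)
  write_truth_tsv(truth, file.path(dir, "truth.tsv"))
  for (p in protos) {
    write_alignments_tsv(als[[p]], file.path(dir, paste0(p, ".tsv")))
    if (p != "total")
      write_alignments_sam(als[[p]], ga$genome,
                           file.path(dir, paste0(p, ".sam")))
  }
  invisible(list(genome = ga$genome, annotation = ga$annotation,
                 truth = truth, alignments = als))
}
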