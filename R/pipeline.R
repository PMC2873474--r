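#' Pipeline configuration
#'
#' A single configuration object drives the end-to-end run. Inputs are either
#' file paths (\code{genome_fasta}, \code{annotation_gff3}, \code{alignments}
#' -- a named list mapping sample names \code{s1_primary}/\code{s2_processed}/
#' \code{total} to SAM or TSV files) or, when \code{simulate = TRUE}, a
#' [sim_config()] whose synthetic dataset is generated on the fly. Stage
#' parameters default to the 454 presets; pass
#' \code{contig = contig_params_illumina()} for the short-read preset.
#'
#' @param genome_fasta,annotation_gff3 input paths (ignored when simulating)
#' @param alignments named list of alignment file paths per sample
#' @param simulate generate inputs with the synthetic-data module
#' @param sim [sim_config()] used when simulating
#' @param contig [contig_params()]
#' @param classifier [classifier_params()]
#' @param promoter [promoter_model()]; NULL trains the consensus model on the
#'   genome background
#' @param promoter_window upstream scan window in nt
#' @param structure list(enabled, k, background_k, n_windows, max_candidates)
#' @param orf list(min_len, rbs = [rbs_params()])
#' @param probe_table optional two-channel probe TSV for the array screen
#' @param chip_table optional chip probe TSV (signal/background columns)
#' @param seed global RNG seed
#' @return object of class \code{pipeline_config}
#' @export
pipeline_config <- function(genome_fasta = NULL, annotation_gff3 = NULL,
                            alignments = list(), simulate = is.null(genome_fasta),
                            sim = sim_config(),
                            contig = contig_params_454(),
                            classifier = classifier_params(),
                            promoter = NULL, promoter_window = 100,
                            structure = list(enabled = TRUE, k = 600,
                                             background_k = 150,
                                             n_windows = 60,
                                             max_candidates = 15),
                            orf = list(min_len = 60, rbs = rbs_params()),
                            probe_table = NULL, chip_table = NULL,
                            seed = 1L) {
  structure(list(genome_fasta = genome_fasta,
                 annotation_gff3 = annotation_gff3, alignments = alignments,
                 simulate = simulate, sim = sim, contig = contig,
                 classifier = classifier, promoter = promoter,
                 promoter_window = promoter_window, structure = structure,
                 orf = orf, probe_table = probe_table,
                 chip_table = chip_table, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments; nested
#' parameter blocks (\code{sim}, \code{contig}, \code{classifier},
#' \code{structure}, \code{orf}) override the corresponding defaults
#' field-by-field.
#'
#' @param path YAML file
#' @return \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("genome_fasta", "annotation_gff3", "probe_table", "chip_table",
              "promoter_window", "seed", "simulate"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$alignments)) args$alignments <- y$alignments
  if (!is.null(y$sim)) {
    sa <- y$sim
    if (!is.null(sa$genome_lengths)) sa$genome_lengths <- unlist(sa$genome_lengths)
    if (!is.null(sa$class_mix)) sa$class_mix <- unlist(sa$class_mix)
    args$sim <- do.call(sim_config, sa)
  }
  if (!is.null(y$contig)) {
    if (identical(y$contig, "illumina")) args$contig <- contig_params_illumina()
    else args$contig <- do.call(contig_params, y$contig)
  }
  if (!is.null(y$classifier)) args$classifier <- do.call(classifier_params, y$classifier)
  if (!is.null(y$structure)) {
    s <- pipeline_config()$structure
    s[names(y$structure)] <- y$structure
    args$structure <- s
  }
  if (!is.null(y$orf)) {
    o <- list(min_len = y$orf$min_len %||% 60,
              rbs = if (is.null(y$orf$rbs)) rbs_params()
                    else do.call(rbs_params, y$orf$rbs))
    args$orf <- o
  }
  do.call(pipeline_config, args)
}

#' Read pipeline inputs into domain objects
#'
#' @param config [pipeline_config()]
#' @return list(genome, annotation, alignments, truth); truth is non-NULL
#'   only for simulated inputs
#' @export
read_inputs <- function(config) {
  if (isTRUE(config$simulate)) {
    sim <- config$sim
    sim$rng_seed <- .derive_seed(config$seed, 0L)
    ga <- generate_genome(sim)
    truth <- plant_transcripts(ga$genome, ga$annotation, sim)
    al <- rbind(simulate_reads(truth, ga$genome, sim, "s1_primary"),
                simulate_reads(truth, ga$genome, sim, "s2_processed"))
    return(list(genome = ga$genome, annotation = ga$annotation,
                alignments = al, truth = truth))
  }
  genome <- read_genome_fasta(config$genome_fasta)
  annotation <- read_annotation_gff3(config$annotation_gff3)
  als <- lapply(names(config$alignments), function(smp) {
    p <- config$alignments[[smp]]
    if (grepl("\\.sam$", p, ignore.case = TRUE))
      read_alignments_sam(p, sample = smp)
    else {
      a <- read_alignments_tsv(p)
      a$sample <- smp
      a
    }
  })
  list(genome = genome, annotation = annotation,
       alignments = do.call(rbind, als), truth = NULL)
}

#' Run the full discovery pipeline
#'
#' Chains every stage: coverage, contig calling, distinct-end calling with
#' primary/processed labeling, positional classification, cluster detection
#' and summaries, promoter scanning upstream of primary TSSs, shape
#' Z-scores, the small-ORF/RBS screen and (when probe tables are configured)
#' the hybridization filters. Writes candidate tables (TSV/GFF3/BED), the
#' end-category cross-tabulation, a JSON run manifest recording seeds and
#' parameters, and returns the report invisibly. Progress goes to stderr;
#' outputs only to files.
#'
#' @param config [pipeline_config()]
#' @param output_dir directory for result files (created)
#' @return (invisibly) list with all stage results
#' @export
run_pipeline <- function(config, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[srnascout +%.1fs] %s",
                                         as.numeric(Sys.time() - t0, "secs"), msg))
  stage("reading inputs")
  inp <- read_inputs(config)
  genome <- inp$genome; annotation <- inp$annotation

  stage("building coverage")
  track <- build_coverage(inp$alignments, genome)
  stranded <- setdiff(track$sample_names, "total")

  stage("calling contigs")
  contigs <- call_contigs(track, config$contig, samples = stranded)
  report_contigs <- contigs[!contigs$over_length, , drop = FALSE]

  stage("calling distinct ends")
  labeled <- list()
  if (nrow(report_contigs) > 0 &&
      all(c("s1_primary", "s2_processed") %in% stranded)) {
    labeled <- lapply(seq_len(nrow(report_contigs)), function(i) {
      ci <- report_contigs[i, ]
      label_primary(call_distinct_ends(ci, track, samples = "s1_primary"),
                    call_distinct_ends(ci, track, samples = "s2_processed"))
    })
  }

  stage("classifying candidates")
  classified <- classify_contigs(report_contigs, annotation, config$classifier)
  clusters <- find_clusters(classified, config$classifier)
  summary <- summarize_classes(classified)

  stage("scanning promoters")
  tss <- primary_tss_table(labeled)
  model <- config$promoter
  if (is.null(model))
    model <- consensus_promoter_model(background = genome_base_frequencies(genome))
  hits <- scan_upstream(model, genome, tss, window = config$promoter_window)

  zs <- NULL
  if (isTRUE(config$structure$enabled)) {
    stage("computing shape Z-scores")
    zs <- shape_zscores(classified, genome,
                        k = config$structure$k,
                        background_k = config$structure$background_k,
                        n_windows = config$structure$n_windows,
                        seed = .derive_seed(config$seed, 5L),
                        max_candidates = config$structure$max_candidates %||% Inf)
  }

  stage("screening small ORFs / RBS")
  orfs <- screen_orfs(classified, genome, annotation,
                      min_len = config$orf$min_len, params = config$orf$rbs)

  array_candidates <- NULL; chip_regions <- NULL
  if (!is.null(config$probe_table)) {
    stage("two-channel array screen")
    probes <- read.table(config$probe_table, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    array_candidates <- call_array_candidates(ma_values(probes))
  }
  if (!is.null(config$chip_table)) {
    stage("chip screen")
    probes <- read.table(config$chip_table, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    chip_regions <- call_chip_candidates(probes, annotation)
  }

  stage("writing outputs")
  .write_tsv(contigs, file.path(output_dir, "contigs.tsv"))
  write_contigs_bed(report_contigs, file.path(output_dir, "contigs.bed"))
  .write_tsv(classified, file.path(output_dir, "candidates.tsv"))
  write_classified_gff3(classified, file.path(output_dir, "candidates.gff3"))
  .write_tsv(ends_table(labeled), file.path(output_dir, "ends.tsv"))
  .write_tsv(tabulate_end_categories(labeled),
             file.path(output_dir, "end_categories.tsv"))
  .write_tsv(clusters, file.path(output_dir, "clusters.tsv"))
  .write_tsv(summary$counts, file.path(output_dir, "summary_counts.tsv"))
  .write_tsv(summary$size_stats, file.path(output_dir, "summary_sizes.tsv"))
  .write_tsv(hits, file.path(output_dir, "promoter_hits.tsv"))
  if (!is.null(zs)) .write_tsv(zs, file.path(output_dir, "zscores.tsv"))
  .write_tsv(orfs, file.path(output_dir, "orfs.tsv"))
  if (!is.null(inp$truth))
    write_truth_tsv(inp$truth, file.path(output_dir, "truth.tsv"))
  if (!is.null(array_candidates))
    writeLines(array_candidates, file.path(output_dir, "array_candidates.txt"))
  if (!is.null(chip_regions))
    .write_tsv(chip_regions, file.path(output_dir, "chip_regions.tsv"))

  manifest <- list(
    package = "srnascout",
    version = as.character(utils::packageVersion("srnascout")),
    seed = config$seed,
    simulate = config$simulate,
    contig_params = unclass(config$contig),
    classifier_params = unclass(config$classifier),
    promoter = list(cutoff = model$pvalue_cutoff,
                    spacer_range = model$spacer_range,
                    window = config$promoter_window),
    structure = config$structure,
    n_contigs = nrow(contigs),
    n_candidates = sum(!classified$excluded))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("done")
  invisible(list(genome = genome, annotation = annotation, truth = inp$truth,
                 track = track, contigs = contigs, classified = classified,
                 labeled_ends = labeled, clusters = clusters,
                 summary = summary, promoter_hits = hits, zscores = zs,
                 orfs = orfs, array_candidates = array_candidates,
                 chip_regions = chip_regions, manifest = manifest))
}
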