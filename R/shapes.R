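.rna_base_codes <- c(A = 0L, C = 1L, G = 2L, U = 3L)

.encode_rna <- function(sequence) {
  s <- chartr("T", "U", toupper(sequence))
  v <- .rna_base_codes[strsplit(s, "")[[1]]]
  if (anyNA(v)) stop("sequence must be over A, C, G, U/T")
  unname(v)
}

# pair table from dot-bracket: ptable[i] = partner of i or 0
.pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (!all(ch %in% c("(", ")", "."))) stop("invalid dot-bracket string")
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  pt
}

# top-level pairs (columns i, j) strictly inside [lo, hi]
.top_pairs <- function(pt, lo, hi) {
  out <- NULL
  i <- lo
  while (i <= hi) {
    if (pt[i] > i) { out <- rbind(out, c(i, pt[i])); i <- pt[i] + 1L }
    else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

#' Level-5 abstract shape of a secondary structure
#'
#' Collapses a dot-bracket structure to its most abstract shape: unpaired
#' regions are dropped, every maximal helix nesting (including interruptions
#' by bulges and interior loops) collapses to one bracket pair, so each
#' hairpin becomes \code{"[]"} and multiloop children concatenate inside the
#' enclosing bracket pair. An open chain with no pairs gives \code{"_"}.
#'
#' @param structure dot-bracket string
#' @return shape string over \code{[}, \code{]} (or \code{"_"})
#' @export
abstract_shape <- function(structure) {
  pt <- .pair_table(structure)
  shape_of_pair <- function(i, j) {
    kids <- .top_pairs(pt, i + 1L, j - 1L)
    if (nrow(kids) == 0) return("[]")
    if (nrow(kids) == 1) return(shape_of_pair(kids[1, 1], kids[1, 2]))
    paste0("[", paste(vapply(seq_len(nrow(kids)), function(r)
      shape_of_pair(kids[r, 1], kids[r, 2]), ""), collapse = ""), "]")
  }
  top <- .top_pairs(pt, 1L, length(pt))
  if (nrow(top) == 0) return("_")
  paste(vapply(seq_len(nrow(top)), function(r)
    shape_of_pair(top[r, 1], top[r, 2]), ""), collapse = "")
}

#' Loop-decomposed free energy of a structure
#'
#' Evaluates the energy model on one structure: a hairpin penalty per hairpin
#' loop, a stacking energy for each directly stacked pair, an affine interior
#' /bulge penalty, an affine multiloop penalty (per branch and per unpaired
#' loop base) and a free exterior loop. This is the same decomposition the
#' partition-function engine integrates over.
#'
#' @param structure dot-bracket string
#' @param sequence RNA/DNA string of equal length
#' @param model [energy_model()]
#' @return energy in kcal/mol
#' @export
structure_energy <- function(structure, sequence, model = energy_model()) {
  pt <- .pair_table(structure)
  b <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1]]
  if (length(b) != length(pt)) stop("sequence and structure lengths differ")
  pair_name <- function(i, j) {
    p <- paste0(b[i], b[j])
    if (!p %in% .rna_pairs) stop(sprintf("illegal pair %s at (%d,%d)", p, i, j))
    p
  }
  e <- 0
  all_pairs <- which(pt > seq_along(pt))
  for (i in all_pairs) pair_name(i, pt[i])   # validate every pair
  for (i in all_pairs) {
    j <- pt[i]
    kids <- .top_pairs(pt, i + 1L, j - 1L)
    nk <- nrow(kids)
    if (nk == 0) {
      e <- e + model$hairpin_a + model$hairpin_b * (j - i - 1 - model$min_hairpin)
    } else if (nk == 1) {
      k <- kids[1, 1]; l <- kids[1, 2]
      size <- (k - i - 1L) + (j - l - 1L)
      if (size == 0)
        e <- e + model$stack[pair_name(i, j), pair_name(k, l)]
      else
        e <- e + model$interior_a + model$interior_b * size
    } else {
      unpaired <- (j - i - 1L) - sum(kids[, 2] - kids[, 1] + 1L)
      e <- e + model$ml_a + model$ml_b * (nk + 1L) + model$ml_c * unpaired
    }
  }
  e
}

.model_for_cpp <- function(model) {
  list(stack = unname(model$stack), hairpin_a = model$hairpin_a,
       hairpin_b = model$hairpin_b, interior_a = model$interior_a,
       interior_b = model$interior_b, ml_a = model$ml_a, ml_b = model$ml_b,
       ml_c = model$ml_c, min_hairpin = model$min_hairpin,
       max_interior = model$max_interior, RT = model$RT)
}

#' Partition function of a sequence
#'
#' @param sequence RNA/DNA string
#' @param model [energy_model()]
#' @return the Boltzmann partition function (unpaired chain contributes 1)
#' @export
partition_function <- function(sequence, model = energy_model()) {
  .cpp_partition(.encode_rna(sequence), .model_for_cpp(model))
}

#' Dominant abstract shape and its Boltzmann probability
#'
#' Computes the partition function, draws \code{k} structures by stochastic
#' traceback, maps each through [abstract_shape()], and estimates the shape
#' probability Prob(t, p) as the sample frequency of the modal shape (ties
#' broken toward the lexicographically smaller shape string). The reported
#' representative structure is the lowest-energy sampled structure of the
#' dominant shape.
#'
#' @param sequence RNA/DNA string, length >= 10
#' @param model [energy_model()]
#' @param k number of sampled structures (default 1000)
#' @param seed optional integer; when given, seeds the sampler for
#'   reproducibility (otherwise the ambient RNG stream is used)
#' @return object of class \code{shape_profile}: sequence, shape, prob,
#'   mfe_representative, n, k, seed, shape_freqs, logZ
#' @export
shape_probabilities <- function(sequence, model = energy_model(), k = 1000,
                                seed = NULL) {
  enc <- .encode_rna(sequence)
  if (length(enc) < 10) stop("sequence must be at least 10 nt")
  if (!is.null(seed)) set.seed(seed)
  res <- .cpp_fold_sample(enc, .model_for_cpp(model), as.integer(k))
  shapes <- vapply(res$structures, abstract_shape, "", USE.NAMES = FALSE)
  tab <- table(shapes)
  freqs <- as.numeric(tab) / k
  names(freqs) <- names(tab)
  top <- names(freqs)[freqs == max(freqs)]
  dominant <- sort(top)[1]
  cand <- res$structures[shapes == dominant]
  energies <- vapply(cand, structure_energy, numeric(1),
                     sequence = sequence, model = model, USE.NAMES = FALSE)
  structure(list(sequence = sequence, shape = dominant,
                 prob = max(freqs),
                 mfe_representative = cand[[which.min(energies)]],
                 n = length(enc), k = k, seed = seed,
                 shape_freqs = sort(freqs, decreasing = TRUE),
                 logZ = res$logZ),
            class = "shape_profile")
}

#' Background distribution of a shape probability
#'
#' Scans same-strand genome windows of the transcript's length \code{n},
#' keeps the windows whose dominant shape equals \code{shape}, and summarizes
#' their shape probabilities Prob(w, p) by mean E(p, n) and standard
#' deviation S(p, n). Window choice: \code{"all"} windows, every
#' \code{stride}-th window, or (default) a seeded random subsample of
#' \code{n_windows} windows -- scanning every window of a full genome is not
#' desk-scale and subsampling consistency is asserted in the test suite.
#'
#' @param genome \code{sr_genome}
#' @param strand "+" or "-"
#' @param shape target shape string
#' @param n window length (the transcript length)
#' @param policy "random", "strided" or "all"
#' @param n_windows number of windows for the random policy (default 500)
#' @param stride step for the strided policy
#' @param model [energy_model()]
#' @param k sampled structures per window (default 200)
#' @param seed integer seed for window choice and sampling
#' @return object of class \code{shape_background}: shape, n, E, S,
#'   n_windows_used, n_windows_scanned, values, policy, seed, defined
#' @export
background_distribution <- function(genome, strand = "+", shape, n,
                                    policy = c("random", "strided", "all"),
                                    n_windows = 500, stride = 50,
                                    model = energy_model(), k = 200,
                                    seed = 1L) {
  policy <- match.arg(policy)
  lens <- genome_lengths(genome)
  counts <- pmax(lens - n + 1L, 0L)
  if (sum(counts) < 1) stop("genome shorter than the window length")
  set.seed(seed)
  idx_all <- seq_len(sum(counts))
  idx <- switch(policy,
    all = idx_all,
    strided = idx_all[seq(1L, length(idx_all), by = stride)],
    random = sort(sample(idx_all, min(n_windows, length(idx_all)))))
  offs <- c(0, cumsum(counts))
  vals <- numeric(0)
  for (ix in idx) {
    r <- findInterval(ix - 1, offs, rightmost.closed = FALSE)
    repl <- names(counts)[r]
    pos <- ix - offs[r]
    w <- as.character(Biostrings::subseq(genome$seq[[repl]], pos, pos + n - 1L))
    if (strand == "-")
      w <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    prof <- shape_probabilities(w, model, k = k, seed = NULL)
    if (prof$shape == shape) vals <- c(vals, prof$prob)
  }
  S <- if (length(vals) >= 2) sd(vals) else NA_real_
  structure(list(shape = shape, n = n,
                 E = if (length(vals) >= 1) mean(vals) else NA_real_,
                 S = S, n_windows_used = length(vals),
                 n_windows_scanned = length(idx), values = vals,
                 policy = policy, seed = seed,
                 defined = length(vals) >= 2 && is.finite(S) && S > 0),
            class = "shape_background")
}

#' Shape-probability Z-score
#'
#' Z = (Prob(t, p) - E(p, n)) / S(p, n): how much more sharply the
#' transcript commits to its dominant shape than same-length genome windows
#' sharing that dominant shape. Positive values indicate a better-defined
#' secondary structure than the genomic background.
#'
#' @param profile [shape_probabilities()] result
#' @param background [background_distribution()] result for the same shape
#'   and length
#' @return list of class \code{zscore_result}: Z, profile, background
#' @export
shape_zscore <- function(profile, background) {
  if (!identical(profile$shape, background$shape))
    stop("profile and background shapes differ")
  if (profile$n != background$n)
    stop("profile and background lengths differ")
  if (!isTRUE(background$defined))
    stop("background undefined (fewer than 2 qualifying windows or zero sd)")
  structure(list(Z = (profile$prob - background$E) / background$S,
                 profile = profile, background = background),
            class = "zscore_result")
}

#' Shape Z-scores for classified candidates
#'
#' Convenience wrapper: folds each candidate's sense-strand sequence,
#' computes (and caches per shape/length) the genome-window background, and
#' reports the Z-score. Candidates whose background is undefined get NA.
#'
#' @param classified output of [classify_contigs()] (excluded rows skipped)
#' @param genome \code{sr_genome}
#' @param model [energy_model()]
#' @param k sampled structures per candidate (default 1000)
#' @param background_k sampled structures per background window (default 200)
#' @param n_windows background windows (default 100)
#' @param seed integer seed
#' @param max_candidates cap on the number of candidates folded (by depth
#'   rank order of the input; default all)
#' @return data.frame contig_id, n, shape, prob, E, S, Z, n_windows_used
#' @export
shape_zscores <- function(classified, genome, model = energy_model(),
                          k = 1000, background_k = 200, n_windows = 100,
                          seed = 1L, max_candidates = Inf) {
  d <- classified[!classified$excluded, , drop = FALSE]
  if (nrow(d) > max_candidates) d <- d[seq_len(max_candidates), , drop = FALSE]
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    ci <- d[i, ]
    sq <- as.character(Biostrings::subseq(genome$seq[[ci$replicon]],
                                          ci$start, ci$end))
    if (ci$strand == "-")
      sq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sq)))
    prof <- shape_probabilities(sq, model, k = k,
                                seed = .derive_seed(seed, 100L + i))
    key <- sprintf("%s|%s|%d", prof$shape, ci$strand, prof$n)
    bg <- cache[[key]]
    if (is.null(bg)) {
      bg <- background_distribution(genome, ci$strand, prof$shape, prof$n,
                                    policy = "random", n_windows = n_windows,
                                    model = model, k = background_k,
                                    seed = .derive_seed(seed, 7L))
      cache[[key]] <- bg
    }
    z <- if (isTRUE(bg$defined)) (prof$prob - bg$E) / bg$S else NA_real_
    rows[[i]] <- data.frame(contig_id = ci$contig_id, n = prof$n,
                            shape = prof$shape, prob = prof$prob,
                            E = bg$E, S = bg$S, Z = z,
                            n_windows_used = bg$n_windows_used,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), n = integer(0),
                      shape = character(0), prob = numeric(0), E = numeric(0),
                      S = numeric(0), Z = numeric(0),
                      n_windows_used = integer(0))
  rownames(out) <- NULL
  out
}
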