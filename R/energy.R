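.rna_pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")

# Compact nearest-neighbor RNA:RNA stacking subset (kcal/mol at 37 C).
# stack[p, q]: pair q stacked 3' of pair p along the 5'->3' top strand.
.default_stack <- local({
  m <- matrix(c(
    #        AU     UA     CG     GC     GU     UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,   # AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,   # UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,   # CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,   # GC
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.5,   # GU
    -1.0, -0.6, -1.5, -1.4, -0.3, -0.5),  # UG
    nrow = 6, byrow = TRUE,
    dimnames = list(.rna_pairs, .rna_pairs))
  m
})

#' RNA folding energy model
#'
#' A compact nearest-neighbor parameter set used consistently for the
#' transcript and the genome-window background: stacking energies per
#' pair-on-pair, affine hairpin / interior-loop / multiloop penalties, a
#' minimum hairpin loop of 3 nt, and the folding temperature. The same
#' stacking table also scores RNA:RNA duplexes in the ribosome-binding-site
#' screen. Values are kcal/mol.
#'
#' @param stack 6x6 stacking matrix over pairs AU, UA, CG, GC, GU, UG
#' @param hairpin_a,hairpin_b hairpin penalty a + b * (size - 3)
#' @param interior_a,interior_b interior/bulge penalty a + b * size
#' @param ml_a,ml_b,ml_c multiloop affine penalty: a + b per branch
#'   (including the closing pair) + c per unpaired base
#' @param min_hairpin minimum hairpin loop size in nt (default 3)
#' @param max_interior maximum total interior/bulge loop size considered
#' @param temperature folding temperature in Celsius (default 37)
#' @return object of class \code{energy_model}
#' @export
energy_model <- function(stack = .default_stack,
                         hairpin_a = 5.0, hairpin_b = 0.1,
                         interior_a = 3.0, interior_b = 0.25,
                         ml_a = 3.4, ml_b = 0.4, ml_c = 0.1,
                         min_hairpin = 3L, max_interior = 30L,
                         temperature = 37) {
  stopifnot(identical(dim(stack), c(6L, 6L)), all(is.finite(stack)))
  structure(list(stack = stack, hairpin_a = hairpin_a, hairpin_b = hairpin_b,
                 interior_a = interior_a, interior_b = interior_b,
                 ml_a = ml_a, ml_b = ml_b, ml_c = ml_c,
                 min_hairpin = as.integer(min_hairpin),
                 max_interior = as.integer(max_interior),
                 temperature = temperature,
                 RT = 0.0019872 * (273.15 + temperature)),
            class = "energy_model")
}

#' Serialize / read an energy model as JSON
#' @param model [energy_model()]
#' @param path file path
#' @export
write_energy_model <- function(model, path) {
  x <- unclass(model)
  x$stack <- as.data.frame(x$stack)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_energy_model
#' @export
read_energy_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- as.matrix(x$stack)
  dimnames(st) <- list(.rna_pairs, .rna_pairs)
  energy_model(stack = st, hairpin_a = x$hairpin_a, hairpin_b = x$hairpin_b,
               interior_a = x$interior_a, interior_b = x$interior_b,
               ml_a = x$ml_a, ml_b = x$ml_b, ml_c = x$ml_c,
               min_hairpin = x$min_hairpin, max_interior = x$max_interior,
               temperature = x$temperature)
}

.rna_pair_name <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% .rna_pairs) p else NA_character_
}
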