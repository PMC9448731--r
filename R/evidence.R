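# Evidence matrix E (genes x omics layers) and the initial signal vector S.
# One point per omics layer with a significant, pre-thresholded hit; the row
# sum S_i is the signal mass diffused through the network. Hit lists arrive
# already thresholded upstream (e.g. FDR < 0.05 for transcriptome layers,
# 5e-8 for GWAS loci); the layer metadata records, but never applies, those
# cut-offs.

#' Build the binary evidence matrix
#'
#' @param universe character vector of gene symbols indexing the rows.
#' @param layers named list: layer label -> character vector of hit genes.
#'   An optional `thresholds` attribute (or the `thresholds` argument) is
#'   stored as per-layer threshold descriptions.
#' @param thresholds optional named character vector describing each layer's
#'   upstream inclusion threshold (metadata only).
#' @param permissive if `TRUE`, hit genes outside the universe are dropped
#'   with a warning instead of raising an error.
#' @return integer 0/1 matrix (genes x layers) with a `thresholds`
#'   attribute.
#' @examples
#' E <- build_evidence_matrix(c("A", "B", "C"),
#'   list(de = c("A", "B"), methylation = "A"))
#' build_signal_vector(E)
#' @export
build_evidence_matrix <- function(universe, layers, thresholds = NULL,
                                  permissive = FALSE) {
  labels <- names(layers)
  if (is.null(labels) || any(labels == ""))
    stop("every evidence layer needs a label")
  if (anyDuplicated(labels)) stop("duplicate layer labels")
  E <- matrix(0L, nrow = length(universe), ncol = length(layers),
              dimnames = list(universe, labels))
  for (j in seq_along(layers)) {
    hits <- unique(as.character(layers[[j]]))
    unknown <- setdiff(hits, universe)
    if (length(unknown) > 0) {
      if (!permissive)
        stop("layer '", labels[j], "' hit gene(s) not in universe: ",
             paste(utils::head(unknown, 5), collapse = ", "))
      warning("layer '", labels[j], "': dropping ", length(unknown),
              " hit gene(s) not in universe")
      hits <- setdiff(hits, unknown)
    }
    E[hits, j] <- 1L
  }
  attr(E, "thresholds") <- thresholds
  E
}

#' Row sums of the evidence matrix
#'
#' The initial signal vector: `S_i` counts the omics layers with a hit for
#' gene i (a gene that is differentially expressed and differentially
#' methylated gets `S_i = 2`). Genes with `S_i > 0` form the seed set.
#'
#' @param E evidence matrix from [build_evidence_matrix()].
#' @return named numeric vector S over the universe.
#' @export
build_signal_vector <- function(E) {
  if (!is.matrix(E) || !all(E %in% c(0L, 1L)))
    stop("E must be a binary gene x layer matrix")
  if (is.null(rownames(E))) stop("E must have gene rownames")
  rowSums(E)
}

#' Distribution of initial signal intensities over the seed set
#'
#' @param S signal vector from [build_signal_vector()].
#' @return data frame with `intensity`, `count` and `fraction` (fractions
#'   computed over genes with S >= 1 and summing to 1).
#' @export
summarize_signal_distribution <- function(S) {
  seeds <- S[S >= 1]
  if (length(seeds) == 0) stop("empty seed set: no gene has S >= 1")
  tab <- table(seeds)
  data.frame(intensity = as.numeric(names(tab)),
             count = as.integer(tab),
             fraction = as.numeric(tab) / length(seeds),
             row.names = NULL)
}
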