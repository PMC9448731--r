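# Candidate selection: a gene is "brain-high" when the maximum of its
# diffused intensity over all tissue/cell-type columns is attained in a brain
# column. Ties including a brain column count as brain-high; all-zero rows
# (genes untouched by diffusion) are never selected.

#' Select genes with brain-peaked diffused intensity
#'
#' @param intensity genes x tissues matrix of diffused intensities.
#' @param brain_tissues non-empty subset of the intensity column names.
#' @return data frame with `gene`, `tissue` (the brain column attaining the
#'   row maximum) and `intensity` (the row maximum), one row per selected
#'   gene.
#' @export
select_brain_high <- function(intensity, brain_tissues) {
  if (length(brain_tissues) == 0) stop("empty brain tissue set")
  if (!all(brain_tissues %in% colnames(intensity)))
    stop("brain tissue(s) not among intensity columns: ",
         paste(setdiff(brain_tissues, colnames(intensity)), collapse = ", "))
  rmax <- apply(intensity, 1L, max)
  brain <- intensity[, brain_tissues, drop = FALSE]
  bmax <- apply(brain, 1L, max)
  sel <- which(rmax > 0 & bmax >= rmax)
  if (length(sel) == 0) {
    return(data.frame(gene = character(0), tissue = character(0),
                      intensity = numeric(0)))
  }
  arg <- brain_tissues[apply(brain[sel, , drop = FALSE], 1L, which.max)]
  out <- data.frame(gene = rownames(intensity)[sel],
                    tissue = arg,
                    intensity = unname(rmax[sel]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$intensity), , drop = FALSE]
}

#' Partition candidates into known seeds and novel genes
#'
#' @param candidates a [select_brain_high()] data frame or a character
#'   vector of genes.
#' @param seed_genes character vector of evidence-carrying genes (S >= 1).
#' @return list with `known` and `novel` character vectors.
#' @export
split_known_novel <- function(candidates, seed_genes) {
  genes <- if (is.data.frame(candidates)) candidates$gene else candidates
  list(known = intersect(genes, seed_genes),
       novel = setdiff(genes, seed_genes))
}

#' Extract the interaction neighborhood of a gene set
#'
#' Collects all edges incident to the focal genes, reports the distinct
#' non-focal neighbors and the fraction of them found in a reference
#' risk-gene list.
#'
#' @param interactions an [merge_and_dedupe()] result.
#' @param focal non-empty character vector of focal genes.
#' @param reference character vector of known risk genes.
#' @return list of class `neighborhood_report` with `focal`, `edges` (the
#'   induced incident edge list), `neighbors`, `n_neighbors`, `n_edges`,
#'   `n_reference` (neighbors found in `reference`), `fraction` and
#'   `degenerate` (`TRUE` when there are no neighbors, in which case the
#'   fraction is reported as 0).
#' @export
extract_neighborhood <- function(interactions, focal,
                                 reference = character(0)) {
  if (length(focal) == 0) stop("empty focal gene set")
  inc <- interactions$gene_a %in% focal | interactions$gene_b %in% focal
  edges <- interactions[inc, , drop = FALSE]
  rownames(edges) <- NULL
  neighbors <- setdiff(unique(c(edges$gene_a, edges$gene_b)), focal)
  n_ref <- length(intersect(neighbors, reference))
  degenerate <- length(neighbors) == 0
  structure(list(focal = focal,
                 edges = edges,
                 neighbors = neighbors,
                 n_neighbors = length(neighbors),
                 n_edges = nrow(edges),
                 n_reference = n_ref,
                 fraction = if (degenerate) 0 else n_ref / length(neighbors),
                 degenerate = degenerate),
            class = "neighborhood_report")
}

#' @export
print.neighborhood_report <- function(x, ...) {
  cat("Neighborhood of", length(x$focal), "focal gene(s):",
      x$n_edges, "incident edges,", x$n_neighbors, "distinct neighbors\n")
  cat(sprintf("Reference risk genes among neighbors: %d (%.1f%%)%s\n",
              x$n_reference, 100 * x$fraction,
              if (x$degenerate) " [no neighbors]" else ""))
  invisible(x)
}
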