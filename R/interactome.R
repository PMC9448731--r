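# Interactome assembly and tissue-specific Markov transition matrices.
#
# Edges are undirected and canonicalized (lexicographically smaller symbol
# first); the per-tissue random-walk weight of an edge is
#   W_uv = max(Jaccard(domains_u, domains_v), floor) *
#          sqrt(map(level_u) * map(level_v))
# i.e. a subcellular co-localization term shared by all tissues times a
# tissue-specific ordinal-abundance term. Rows are normalized to sum to 1.

#' Merge and deduplicate multi-source edge lists
#'
#' Canonicalizes every edge as an unordered pair (lexicographic order within
#' the pair), drops self-pairs, takes the union across sources and retains
#' per-edge provenance as a semicolon-joined label set.
#'
#' @param sources a list of data frames with columns `gene_a`, `gene_b` and
#'   optionally `source`, or a single such data frame.
#' @param universe optional character vector; if given, edges referencing
#'   genes outside it raise an error naming the gene.
#' @return data frame of class `interaction_set` with columns `gene_a`,
#'   `gene_b` (gene_a < gene_b, each unordered pair once) and `sources`.
#' @examples
#' merge_and_dedupe(list(
#'   data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "A", "A")),
#'   data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))))
#' @export
merge_and_dedupe <- function(sources, universe = NULL) {
  if (is.data.frame(sources)) sources <- list(sources)
  if (length(sources) == 0) stop("no interaction sources supplied")
  recs <- do.call(rbind, lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    if (!all(c("gene_a", "gene_b") %in% names(s)))
      stop("source ", i, " lacks gene_a/gene_b columns")
    src <- if ("source" %in% names(s)) as.character(s$source)
           else if ("sources" %in% names(s)) as.character(s$sources)
           else names(sources)[i] %||% sprintf("source_%d", i)
    data.frame(gene_a = as.character(s$gene_a),
               gene_b = as.character(s$gene_b),
               source = src,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(universe)) {
    unknown <- setdiff(unique(c(recs$gene_a, recs$gene_b)), universe)
    if (length(unknown) > 0)
      stop("edge references unknown gene(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  a <- pmin(recs$gene_a, recs$gene_b)
  b <- pmax(recs$gene_a, recs$gene_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; src <- recs$source[keep]
  key <- paste(a, b, sep = "\r")
  srcs <- vapply(split(src, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  uk <- names(srcs)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, character(1), 1L),
                    gene_b = vapply(parts, `[`, character(1), 2L),
                    sources = unname(srcs),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Subcellular co-localization weight
#'
#' Jaccard similarity of the two micro-domain sets, floored at a small
#' positive value so that the random walk never disconnects along annotated
#' edges: proteins sharing compartments interact more readily than proteins
#' localized far apart.
#'
#' @param domains_a,domains_b non-empty character vectors of domain labels.
#' @param floor lower bound in (0, 1].
#' @return a number in \[floor, 1\]; symmetric in its arguments.
#' @export
localization_weight <- function(domains_a, domains_b, floor = 0.01) {
  if (length(domains_a) == 0 || length(domains_b) == 0)
    stop("localization missing: empty micro-domain set")
  if (floor <= 0 || floor > 1) stop("floor must lie in (0, 1]")
  max(jaccard(domains_a, domains_b), floor)
}

#' Pairwise abundance factor
#'
#' Geometric mean of the mapped ordinal abundance values of the two endpoint
#' proteins in the tissue under study; symmetric and scale-balanced.
#'
#' @param level_a,level_b ordinal level strings (see [abundance_levels()]).
#' @param mapping named positive numeric vector mapping level to weight.
#' @return positive number.
#' @export
abundance_factor <- function(level_a, level_b,
                             mapping = default_abundance_mapping()) {
  va <- mapping[level_a]
  vb <- mapping[level_b]
  if (anyNA(va) || anyNA(vb))
    stop("unmapped abundance level: ",
         paste(setdiff(c(level_a, level_b), names(mapping)), collapse = ", "))
  if (any(mapping <= 0)) stop("abundance mapping values must be > 0")
  sqrt(unname(va) * unname(vb))
}

#' Default ordinal abundance mapping
#'
#' `not_detected` keeps a small positive weight so annotated but undetected
#' proteins do not disconnect the chain.
#' @return named numeric vector over the four ordinal levels.
#' @export
default_abundance_mapping <- function() {
  c(not_detected = 0.1, low = 1, medium = 2, high = 3)
}

# Resolve universe, edge endpoints and per-edge localization weights once;
# shared by build_transition_matrix and build_all_tissues.
.edge_weights_loc <- function(interactions, localization, abundance,
                              floor, permissive) {
  genes <- rownames(abundance)
  if (is.null(genes)) stop("abundance matrix must have gene rownames")
  egenes <- unique(c(interactions$gene_a, interactions$gene_b))
  missing_ab <- setdiff(egenes, genes)
  if (length(missing_ab) > 0) {
    if (!permissive)
      stop("gene ", missing_ab[1], " missing abundance annotation")
    genes <- c(genes, missing_ab)
  }
  i <- match(interactions$gene_a, genes)
  j <- match(interactions$gene_b, genes)
  has_loc_a <- interactions$gene_a %in% names(localization)
  has_loc_b <- interactions$gene_b %in% names(localization)
  if (!permissive && !all(has_loc_a & has_loc_b)) {
    bad <- c(interactions$gene_a[!has_loc_a],
             interactions$gene_b[!has_loc_b])[1]
    stop("gene ", bad, " missing localization annotation")
  }
  lw <- numeric(nrow(interactions))
  for (e in seq_along(lw)) {
    if (has_loc_a[e] && has_loc_b[e]) {
      lw[e] <- localization_weight(localization[[interactions$gene_a[e]]],
                                   localization[[interactions$gene_b[e]]],
                                   floor)
    } else {
      lw[e] <- floor  # permissive mode: unannotated endpoint
    }
  }
  list(genes = genes, i = i, j = j, loc_weight = lw,
       missing_ab = missing_ab)
}

.transition_from_weights <- function(i, j, w, genes) {
  n <- length(genes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(w, 2L),
                            dims = c(n, n), dimnames = list(genes, genes))
  deg <- Matrix::rowSums(W)
  iso <- which(deg == 0)
  if (length(iso) > 0) {
    # isolated genes hold their signal: self-loop of weight 1
    W <- W + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                  dims = c(n, n))
    deg[iso] <- 1
  }
  P <- Matrix::Diagonal(x = 1 / deg) %*% W
  dimnames(P) <- list(genes, genes)
  methods::as(P, "CsparseMatrix")
}

.abundance_column <- function(abundance, tissue, genes, mapping, permissive) {
  lev <- setNames(rep("low", length(genes)), genes)
  present <- intersect(genes, rownames(abundance))
  lev[present] <- abundance[present, tissue]
  v <- mapping[lev]
  if (anyNA(v))
    stop("unmapped abundance level: ",
         paste(unique(lev[is.na(v)]), collapse = ", "))
  setNames(unname(v), genes)
}

#' Build one tissue's transition matrix
#'
#' Combines co-localization and abundance weights into a symmetric edge
#' weight, reintroduces a unit self-loop for otherwise isolated genes, and
#' row-normalizes into a row-stochastic Markov transition matrix for the
#' given tissue.
#'
#' @param interactions an [merge_and_dedupe()] result.
#' @param localization named list of per-gene domain label vectors.
#' @param abundance character matrix of ordinal levels (genes x tissues).
#' @param tissue a tissue column name of `abundance`.
#' @param floor co-localization floor, see [localization_weight()].
#' @param mapping ordinal abundance mapping, see [abundance_factor()].
#' @param permissive if `TRUE`, interacting genes lacking localization get
#'   the floor weight and genes lacking abundance are treated as `low`
#'   (with a message) instead of raising an error.
#' @return a sparse row-stochastic matrix (`Matrix::dgCMatrix`) indexed by
#'   the abundance rownames (plus, in permissive mode, unannotated
#'   interactors).
#' @export
build_transition_matrix <- function(interactions, localization, abundance,
                                    tissue, floor = 0.01,
                                    mapping = default_abundance_mapping(),
                                    permissive = FALSE) {
  if (!tissue %in% colnames(abundance))
    stop("unknown tissue label: ", tissue)
  pre <- .edge_weights_loc(interactions, localization, abundance,
                           floor, permissive)
  if (permissive && length(pre$missing_ab) > 0)
    message("assigning 'low' abundance to ", length(pre$missing_ab),
            " unannotated gene(s)")
  av <- .abundance_column(abundance, tissue, pre$genes, mapping, permissive)
  w <- pre$loc_weight * sqrt(av[pre$i] * av[pre$j])
  .transition_from_weights(pre$i, pre$j, w, pre$genes)
}

#' Build transition matrices for a set of tissues
#'
#' The localization term is computed once and shared; matrices differ only
#' through the tissue-specific abundance factors.
#'
#' @inheritParams build_transition_matrix
#' @param tissues character vector of tissue labels (default: all abundance
#'   columns).
#' @return named list of row-stochastic sparse matrices, one per tissue.
#' @export
build_all_tissues <- function(interactions, localization, abundance,
                              tissues = colnames(abundance), floor = 0.01,
                              mapping = default_abundance_mapping(),
                              permissive = FALSE) {
  unknown <- setdiff(tissues, colnames(abundance))
  if (length(unknown) > 0)
    stop("unknown tissue label: ", paste(unknown, collapse = ", "))
  pre <- .edge_weights_loc(interactions, localization, abundance,
                           floor, permissive)
  if (permissive && length(pre$missing_ab) > 0)
    message("assigning 'low' abundance to ", length(pre$missing_ab),
            " unannotated gene(s)")
  out <- lapply(tissues, function(tis) {
    av <- .abundance_column(abundance, tis, pre$genes, mapping, permissive)
    w <- pre$loc_weight * sqrt(av[pre$i] * av[pre$j])
    .transition_from_weights(pre$i, pre$j, w, pre$genes)
  })
  names(out) <- tissues
  out
}
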