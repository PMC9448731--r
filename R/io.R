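# Plain-text TSV readers and writers: one UTF-8 TSV with a single header row
# per table, sparse matrices as coordinate triples. Every writer's output is
# parsed back by its reader to an equal in-memory value.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

.read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a raw interaction edge list
#'
#' Expects a TSV with header `gene_a`, `gene_b`, `source`. Records are
#' preserved verbatim, including duplicates (deduplication is
#' [merge_and_dedupe()]'s job); malformed rows raise an error naming the
#' line. Windows line endings are accepted.
#'
#' @param path file path.
#' @return data frame with columns `gene_a`, `gene_b`, `source`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("empty edge list file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene_a", "gene_b", "source")
  if (!all(need %in% header))
    stop("edge list header must contain gene_a, gene_b, source")
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad) > 0)
    stop("malformed edge list row at line ", bad[1] + 1L, " of ", path)
  m <- do.call(rbind, fields)
  colnames(m) <- header
  data.frame(gene_a = m[, "gene_a"], gene_b = m[, "gene_b"],
             source = m[, "source"], stringsAsFactors = FALSE)
}

#' Write interaction edge records
#'
#' @param edges a data frame with `gene_a`, `gene_b`, `source` (e.g. a
#'   generator source or a row-bound list of them), or a list of such data
#'   frames which is concatenated.
#' @param path file path.
#' @export
write_edge_list <- function(edges, path) {
  if (!is.data.frame(edges)) edges <- do.call(rbind, edges)
  if (!"source" %in% names(edges)) edges$source <- "unknown"
  .write_tsv(edges[, c("gene_a", "gene_b", "source")], path)
}

#' @rdname localization_io
#' @export
write_localization <- function(localization, path) {
  .write_tsv(data.frame(
    gene = names(localization),
    domains = vapply(localization, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE), path)
}

#' Localization table I/O
#'
#' TSV with columns `gene` and `domains` (semicolon-joined micro-domain
#' labels).
#'
#' @param localization named list of domain label vectors.
#' @param path file path.
#' @return `read_localization` returns the named list.
#' @name localization_io
#' @export
read_localization <- function(path) {
  df <- .read_tsv(path)
  out <- strsplit(df$domains, ";", fixed = TRUE)
  names(out) <- df$gene
  out
}

#' @rdname abundance_io
#' @export
write_abundance <- function(abundance, path) {
  df <- data.frame(gene = rownames(abundance), abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Abundance matrix I/O
#'
#' TSV with a `gene` column followed by one ordinal-level column per tissue.
#'
#' @param abundance character matrix (genes x tissues).
#' @param path file path.
#' @return `read_abundance` returns the character matrix.
#' @name abundance_io
#' @export
read_abundance <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' @rdname evidence_io
#' @export
write_evidence <- function(E, path) {
  long <- expand.grid(gene = rownames(E), layer = colnames(E),
                      stringsAsFactors = FALSE)
  long$hit <- as.integer(E[cbind(long$gene, long$layer)])
  .write_tsv(long, path)
}

#' Evidence matrix I/O
#'
#' Long-format TSV with columns `gene`, `layer`, `hit` (0/1).
#'
#' @param E binary evidence matrix (genes x layers).
#' @param path file path.
#' @return `read_evidence` returns the integer matrix.
#' @name evidence_io
#' @export
read_evidence <- function(path) {
  df <- .read_tsv(path)
  genes <- unique(df$gene)
  layers <- unique(df$layer)
  E <- matrix(0L, length(genes), length(layers),
              dimnames = list(genes, layers))
  E[cbind(df$gene, df$layer)] <- as.integer(df$hit)
  E
}

#' @rdname expression_io
#' @export
write_expression <- function(dev, path_expr, path_samples) {
  df <- data.frame(gene = rownames(dev$expr), dev$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path_expr)
  .write_tsv(dev$samples, path_samples)
}

#' Expression matrix I/O with metadata sidecar
#'
#' The expression matrix is a TSV with a `gene` column plus one column per
#' sample; the sidecar TSV carries `sample_id`, `region`, `stage_bin` (and
#' optionally `replicate`).
#'
#' @param dev list with `expr` and `samples` (see
#'   [generate_dev_expression()]).
#' @param path_expr,path_samples file paths.
#' @return `read_expression` returns a list with `expr` and `samples`.
#' @name expression_io
#' @export
read_expression <- function(path_expr, path_samples) {
  df <- .read_tsv(path_expr)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df$gene
  storage.mode(expr) <- "double"
  samples <- .read_tsv(path_samples)
  out <- list(expr = expr, samples = samples)
  class(out) <- "dev_expression"
  out
}

#' @rdname intensity_io
#' @export
write_intensity <- function(intensity, path) {
  df <- data.frame(gene = rownames(intensity), intensity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Intensity matrix I/O
#'
#' TSV with a `gene` column plus one numeric column per tissue.
#'
#' @param intensity numeric matrix (genes x tissues).
#' @param path file path.
#' @return `read_intensity` returns the numeric matrix.
#' @name intensity_io
#' @export
read_intensity <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname transition_io
#' @export
write_transition_matrix <- function(P, path) {
  tp <- Matrix::summary(methods::as(P, "TsparseMatrix"))
  .write_tsv(data.frame(row_gene = rownames(P)[tp$i],
                        col_gene = colnames(P)[tp$j],
                        probability = tp$x,
                        stringsAsFactors = FALSE), path)
}

#' Transition matrix I/O (sparse coordinate TSV)
#'
#' TSV with columns `row_gene`, `col_gene`, `probability`; genes absent
#' from any triple are not representable, so writers always emit at least
#' one entry per row (self-loops for isolated genes guarantee this).
#'
#' @param P row-stochastic sparse matrix.
#' @param path file path.
#' @param genes gene universe ordering for reconstruction (default: genes
#'   observed in the file, sorted).
#' @return `read_transition_matrix` returns a `dgCMatrix`.
#' @name transition_io
#' @export
read_transition_matrix <- function(path, genes = NULL) {
  df <- .read_tsv(path)
  if (is.null(genes)) genes <- sort(unique(c(df$row_gene, df$col_gene)))
  Matrix::sparseMatrix(i = match(df$row_gene, genes),
                       j = match(df$col_gene, genes),
                       x = df$probability,
                       dims = c(length(genes), length(genes)),
                       dimnames = list(genes, genes))
}

#' @rdname gene_set_io
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
}

#' Gene set I/O (one gene per line)
#'
#' @param genes character vector.
#' @param path file path.
#' @return `read_gene_set` returns the character vector.
#' @name gene_set_io
#' @export
read_gene_set <- function(path) {
  x <- sub("\r$", "", readLines(path))
  x[nzchar(x)]
}

#' Write all inputs of a synthetic study to a directory
#'
#' Materializes a [simulate_study()] result in the standard file layout
#' consumed by [run_pipeline()]: `edges.tsv`, `localization.tsv`,
#' `abundance.tsv`, `evidence.tsv`, `expression.tsv`, `samples.tsv`,
#' `seed_genes.txt` and one `markers_<set>.txt` per marker set.
#'
#' @param sim a `synthetic_study` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(sim$sources, file.path(dir, "edges.tsv"))
  write_localization(sim$localization, file.path(dir, "localization.tsv"))
  write_abundance(sim$abundance, file.path(dir, "abundance.tsv"))
  write_evidence(sim$evidence, file.path(dir, "evidence.tsv"))
  write_expression(sim$dev, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  write_gene_set(sim$module$seed_genes, file.path(dir, "seed_genes.txt"))
  for (s in names(sim$markers))
    write_gene_set(sim$markers[[s]],
                   file.path(dir, sprintf("markers_%s.txt", s)))
  invisible(dir)
}
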