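# Downstream enrichment and differential-expression statistics applied to
# candidate gene sets: annotation proportion maps, pooled two-proportion
# z-tests, hypergeometric (Fisher) overlap tests, argmax tissue assignment,
# prenatal-vs-postnatal Welch t-tests with Benjamini-Hochberg correction,
# and cell-type DE intersections.

#' Annotation proportions of a gene set
#'
#' Counts gene-set members per annotation label combination and expresses
#' each count as a proportion of the gene-set size (a multi-annotated gene
#' contributes to several rows, so proportions need not sum to 1).
#'
#' @param gene_set non-empty character vector.
#' @param annotation data frame whose first column is `gene` and whose
#'   remaining columns are annotation labels (e.g. region, cell type,
#'   micro-domain).
#' @return data frame with the label columns plus `count` and `proportion`,
#'   sorted by decreasing count.
#' @export
enrichment_proportions <- function(gene_set, annotation) {
  if (length(gene_set) == 0) stop("empty gene set")
  if (!"gene" %in% names(annotation))
    stop("annotation needs a 'gene' column")
  label_cols <- setdiff(names(annotation), "gene")
  if (length(label_cols) == 0) stop("annotation has no label columns")
  hit <- annotation[annotation$gene %in% gene_set, , drop = FALSE]
  if (nrow(hit) == 0) {
    out <- annotation[0, label_cols, drop = FALSE]
    out$count <- integer(0)
    out$proportion <- numeric(0)
    return(out)
  }
  key <- interaction(hit[label_cols], drop = TRUE, sep = "\r")
  counts <- vapply(split(hit$gene, key),
                   function(g) length(unique(g)), integer(1))
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- label_cols
  out$count <- as.integer(counts)
  out$proportion <- out$count / length(unique(gene_set))
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled two-proportion z-test
#'
#' Tests equality of two proportions with the pooled-variance z statistic
#' and a two-sided normal p-value. When the pooled proportion is 0 or 1 the
#' statistic is undefined; z is reported as 0 with p = 1 and a degenerate
#' flag.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `z`, `p_value`, `estimate` (the two proportions) and
#'   `degenerate`.
#' @examples
#' two_proportion_ztest(30, 100, 10, 100)
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("both groups need n >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    return(list(z = 0, p_value = 1, estimate = c(p1 = p1, p2 = p2),
                degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)),
       estimate = c(p1 = p1, p2 = p2), degenerate = FALSE)
}

#' Hypergeometric over-enrichment of a set overlap
#'
#' One-sided upper-tail probability that two gene sets drawn from a common
#' universe share at least the observed number of genes (the one-sided
#' Fisher exact test of the 2x2 table), plus the table odds ratio with a 0.5
#' continuity correction when a cell is empty.
#'
#' @param set_a,set_b character vectors of genes.
#' @param universe_size size of the common gene universe (at least
#'   `|set_a U set_b|`).
#' @return list with `overlap`, `odds_ratio`, `p_value` and `corrected`
#'   (`TRUE` when the continuity correction was applied).
#' @export
fisher_overlap <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  n_union <- length(union(set_a, set_b))
  if (universe_size < n_union)
    stop("universe_size (", universe_size,
         ") smaller than the union of the sets (", n_union, ")")
  k <- length(intersect(set_a, set_b))
  a <- length(set_a)
  b <- length(set_b)
  p <- phyper(k - 1, a, universe_size - a, b, lower.tail = FALSE)
  tab <- c(k, a - k, b - k, universe_size - a - b + k)
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  list(overlap = k,
       odds_ratio = (tab[1] * tab[4]) / (tab[2] * tab[3]),
       p_value = p,
       corrected = corrected)
}

#' Assign each gene to its maximal-expression tissue
#'
#' Row argmax of an expression matrix, with a declared first-column
#' tie-break (a warning reports how many rows tied) and exclusion of
#' all-zero rows. Optionally tests a query gene set for over-representation
#' among each tissue's assigned genes via [fisher_overlap()].
#'
#' @param expr numeric genes x tissues matrix.
#' @param query optional character vector of genes to test per tissue.
#' @return list with `assignment` (data frame gene, tissue), `excluded`
#'   (all-zero genes) and, when `query` is given, `enrichment` (data frame
#'   tissue, n_assigned, overlap, odds_ratio, p_value, q_value).
#' @export
max_tissue_assignment <- function(expr, query = NULL) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and tissue colnames")
  zero <- apply(expr, 1L, function(r) all(r == 0))
  if (any(zero))
    warning(sum(zero), " all-zero gene(s) excluded from tissue assignment")
  keep <- expr[!zero, , drop = FALSE]
  if (nrow(keep) == 0) stop("no expressed genes to assign")
  ties <- apply(keep, 1L, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    warning(sum(ties), " tied row(s): first tissue in column order used")
  arg <- colnames(keep)[apply(keep, 1L, which.max)]
  assignment <- data.frame(gene = rownames(keep), tissue = arg,
                           stringsAsFactors = FALSE)
  out <- list(assignment = assignment, excluded = rownames(expr)[zero])
  if (!is.null(query)) {
    uni <- nrow(keep)
    enr <- lapply(colnames(keep), function(tis) {
      assigned <- assignment$gene[assignment$tissue == tis]
      fo <- fisher_overlap(intersect(query, assignment$gene), assigned, uni)
      data.frame(tissue = tis, n_assigned = length(assigned),
                 overlap = fo$overlap, odds_ratio = fo$odds_ratio,
                 p_value = fo$p_value, stringsAsFactors = FALSE)
    })
    enr <- do.call(rbind, enr)
    enr$q_value <- bh_fdr(enr$p_value)
    out$enrichment <- enr
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")` after validating the inputs).
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, order-preserving.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Prenatal-vs-postnatal differential expression in one region
#'
#' Per-gene two-sided Welch t-test between prenatal and postnatal samples of
#' the given region, followed by Benjamini-Hochberg correction across the
#' genes of that region.
#'
#' @param dev a `dev_expression` object ([generate_dev_expression()]) or a
#'   list with `expr` (genes x samples) and `samples` (data frame with
#'   `sample_id`, `region`, `stage_bin`).
#' @param region a region label present in the sample metadata.
#' @param alpha FDR level declaring a gene DE (default 0.05).
#' @return data frame with `gene`, `mean_prenatal`, `mean_postnatal`,
#'   `t_stat`, `p_value`, `q_value`, `de`.
#' @export
prenatal_postnatal_de <- function(dev, region, alpha = 0.05) {
  samples <- dev$samples
  expr <- dev$expr
  in_region <- samples$region == region
  if (!any(in_region)) stop("no samples for region '", region, "'")
  grp <- stage_group(samples$stage_bin[in_region])
  ids <- samples$sample_id[in_region]
  pre_ids <- ids[grp == "prenatal"]
  post_ids <- ids[grp == "postnatal"]
  if (length(pre_ids) < 2 || length(post_ids) < 2)
    stop("region '", region,
         "' needs >= 2 prenatal and >= 2 postnatal samples")
  pre <- expr[, pre_ids, drop = FALSE]
  post <- expr[, post_ids, drop = FALSE]
  res <- vapply(seq_len(nrow(expr)), function(i) {
    tt <- t.test(pre[i, ], post[i, ])
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  out <- data.frame(gene = rownames(expr),
                    mean_prenatal = rowMeans(pre),
                    mean_postnatal = rowMeans(post),
                    t_stat = res[1, ],
                    p_value = res[2, ],
                    stringsAsFactors = FALSE)
  out$q_value <- bh_fdr(out$p_value)
  out$de <- out$q_value < alpha
  rownames(out) <- NULL
  out
}

#' Count DE regions per gene across all regions
#'
#' Runs [prenatal_postnatal_de()] in every region (BH correction within each
#' region) and, for a query gene set, reports the per-gene number of regions
#' in which it is DE and how many query genes are DE in at least one region.
#'
#' @inheritParams prenatal_postnatal_de
#' @param genes character vector of query genes.
#' @return list with `per_gene` (data frame gene, n_de_regions),
#'   `n_de_any` and `n_regions`.
#' @export
count_de_regions <- function(dev, genes, alpha = 0.05) {
  regions <- unique(dev$samples$region)
  counts <- setNames(integer(length(genes)), genes)
  for (r in regions) {
    de_tab <- prenatal_postnatal_de(dev, r, alpha)
    de_genes <- de_tab$gene[de_tab$de]
    hit <- genes %in% de_genes
    counts[hit] <- counts[hit] + 1L
  }
  list(per_gene = data.frame(gene = genes, n_de_regions = unname(counts),
                             stringsAsFactors = FALSE),
       n_de_any = sum(counts > 0),
       n_regions = length(regions))
}

#' Intersect novel candidates with per-cell-type DE gene lists
#'
#' @param candidates character vector of (novel) candidate genes.
#' @param de_lists named list: cell type -> character vector of DE genes.
#' @param classes optional named character vector mapping cell type to a
#'   broader cell class for the summary counts.
#' @return list with `intersections` (named list per cell type) and
#'   `summary` (data frame cell_type, class, n_de, n_overlap), plus
#'   `n_unique` (distinct candidate genes DE in >= 1 cell type).
#' @export
intersect_with_celltype_de <- function(candidates, de_lists,
                                       classes = NULL) {
  inter <- lapply(de_lists, function(de) intersect(candidates, de))
  summary <- data.frame(
    cell_type = names(de_lists) %||% seq_along(de_lists),
    class = if (is.null(classes)) NA_character_
            else unname(classes[names(de_lists)]),
    n_de = vapply(de_lists, length, integer(1)),
    n_overlap = vapply(inter, length, integer(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(intersections = inter,
       summary = summary,
       n_unique = length(unique(unlist(inter))))
}
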