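# End-to-end file-based pipeline: read the standard TSV inputs, fit the
# diffusion model, and write all result tables plus a run manifest. All
# stages are pure functions of the input files and parameters, so two runs
# on identical inputs produce byte-identical outputs.

#' Pipeline configuration
#'
#' Validates paths and parameters before any computation starts.
#'
#' @param input_dir directory holding `edges.tsv`, `localization.tsv`,
#'   `abundance.tsv`, `evidence.tsv` (see [write_simulation()]); optional
#'   `expression.tsv` + `samples.tsv` enable the developmental DE stage.
#' @param output_dir directory for result tables (created if missing).
#' @param brain_tissues non-empty character vector of brain tissue labels.
#' @param floor,mapping,tol,max_t,permissive model parameters, see
#'   [tissue_diffusion()].
#' @param alpha FDR level for the developmental DE stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, brain_tissues,
                            floor = 0.01,
                            mapping = default_abundance_mapping(),
                            tol = 1e-3, max_t = 50L, alpha = 0.05,
                            permissive = FALSE) {
  if (length(brain_tissues) == 0)
    stop("invalid config: empty brain tissue set")
  if (!dir.exists(input_dir))
    stop("invalid config: input_dir does not exist: ", input_dir)
  need <- c("edges.tsv", "localization.tsv", "abundance.tsv",
            "evidence.tsv")
  missing <- need[!file.exists(file.path(input_dir, need))]
  if (length(missing) > 0)
    stop("invalid config: missing input file(s): ",
         paste(missing, collapse = ", "))
  if (floor <= 0 || floor > 1)
    stop("invalid config: floor must lie in (0, 1]")
  if (tol <= 0 || max_t < 1)
    stop("invalid config: need tol > 0 and max_t >= 1")
  if (alpha <= 0 || alpha >= 1)
    stop("invalid config: alpha must lie in (0, 1)")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 brain_tissues = brain_tissues, floor = floor,
                 mapping = mapping, tol = tol, max_t = as.integer(max_t),
                 alpha = alpha, permissive = permissive),
            class = "pipeline_config")
}

#' Run the full pipeline on a directory of inputs
#'
#' Stages: merge and deduplicate the edge records, build per-tissue
#' transition matrices, diffuse the evidence signal to convergence, select
#' brain-high candidates, and compute summary statistics. Writes
#' `candidates.tsv`, `intensity.tsv`, `convergence.tsv`,
#' `signal_distribution.tsv`, `domain_enrichment.tsv`, optionally
#' `dev_de.tsv`, and `manifest.tsv` (parameter echo, package version,
#' per-tissue convergence times) into the output directory.
#'
#' @param config a [pipeline_config()].
#' @return the fitted [tissue_diffusion()] object, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ind <- config$input_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  edges <- stage("read", read_edge_list(file.path(ind, "edges.tsv")))
  localization <- stage("read",
                        read_localization(file.path(ind, "localization.tsv")))
  abundance <- stage("read", read_abundance(file.path(ind, "abundance.tsv")))
  evidence <- stage("read", read_evidence(file.path(ind, "evidence.tsv")))
  if (!all(config$brain_tissues %in% colnames(abundance)))
    stop("pipeline stage 'validate' failed: brain tissue(s) absent from ",
         "abundance columns")
  # align evidence rows to the abundance universe
  universe <- rownames(abundance)
  E <- matrix(0L, length(universe), ncol(evidence),
              dimnames = list(universe, colnames(evidence)))
  common <- intersect(rownames(evidence), universe)
  E[common, ] <- evidence[common, , drop = FALSE]

  interactions <- stage("merge", merge_and_dedupe(edges, universe = universe))
  fit <- stage("diffuse", tissue_diffusion(
    interactions, localization, abundance, E,
    brain_tissues = config$brain_tissues, floor = config$floor,
    mapping = config$mapping, tol = config$tol, max_t = config$max_t,
    permissive = config$permissive))

  outd <- config$output_dir
  if (!dir.exists(outd)) dir.create(outd, recursive = TRUE)
  stage("write", {
    .write_tsv(fit$candidates, file.path(outd, "candidates.tsv"))
    write_intensity(fit$intensity, file.path(outd, "intensity.tsv"))
    sm <- summary(fit)
    .write_tsv(sm$convergence, file.path(outd, "convergence.tsv"))
    .write_tsv(sm$signal_distribution,
               file.path(outd, "signal_distribution.tsv"))
  })

  # micro-domain proportion map of the candidate set
  stage("enrich", {
    ann <- data.frame(
      gene = rep(names(localization), lengths(localization)),
      domain = unlist(localization, use.names = FALSE),
      stringsAsFactors = FALSE)
    if (nrow(fit$candidates) > 0) {
      enr <- enrichment_proportions(fit$candidates$gene, ann)
      .write_tsv(enr, file.path(outd, "domain_enrichment.tsv"))
    }
  })

  expr_path <- file.path(ind, "expression.tsv")
  samp_path <- file.path(ind, "samples.tsv")
  if (file.exists(expr_path) && file.exists(samp_path)) {
    stage("devde", {
      dev <- read_expression(expr_path, samp_path)
      tabs <- lapply(unique(dev$samples$region), function(r) {
        tab <- prenatal_postnatal_de(dev, r, config$alpha)
        tab$region <- r
        tab
      })
      .write_tsv(do.call(rbind, tabs), file.path(outd, "dev_de.tsv"))
    })
  }

  stage("manifest", {
    ts <- vapply(fit$profiles, function(p) p$t, numeric(1))
    manifest <- data.frame(
      key = c("package_version", "n_genes", "n_edges", "n_tissues",
              "brain_tissues", "floor", "tol", "max_t", "alpha",
              "permissive",
              sprintf("t_%s", names(fit$profiles))),
      value = c(as.character(packageVersion("netdiffuse")),
                nrow(fit$intensity), nrow(fit$interactions),
                ncol(fit$intensity),
                paste(config$brain_tissues, collapse = ";"),
                config$floor, config$tol, config$max_t, config$alpha,
                config$permissive, ts),
      stringsAsFactors = FALSE)
    .write_tsv(manifest, file.path(outd, "manifest.tsv"))
  })
  invisible(fit)
}
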