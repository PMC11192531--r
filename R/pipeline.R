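# End-to-end orchestration: matrices -> curves -> fits -> partition/sharing
# -> diversity, with all artifacts written to an output directory. Outputs
# are deterministic for fixed inputs and thresholds (no timestamps).

#' Run configuration for the full pipeline
#'
#' @param presence path to a presence TSV, or a `presence_matrix` (one of
#'   `presence`/`counts` is required).
#' @param counts path to a counts TSV, or a `count_matrix`; presence is then
#'   derived with `min_reads`.
#' @param populations path to the populations TSV (ignored when matrix
#'   objects are passed).
#' @param vcf,exon_table optional paths for the diversity stage.
#' @param scopes population labels to analyse; `"ALL"` adds the pooled scope.
#' @param min_reads presence-call threshold on counts.
#' @param core_threshold,cloud_threshold occupancy class cutoffs.
#' @param q capture fractions for the saturation quantiles.
#' @param out_dir output directory (created if needed).
#' @return a `run_config` list.
#' @export
run_config <- function(presence = NULL, counts = NULL, populations = NULL,
                       vcf = NULL, exon_table = NULL,
                       scopes = NULL, min_reads = 1L,
                       core_threshold = 0.80, cloud_threshold = 0.20,
                       q = 0.9, out_dir = tempfile("pansat_run_")) {
  if (is.null(presence) && is.null(counts))
    stop("one of presence/counts is required", call. = FALSE)
  stopifnot(min_reads >= 1, all(q > 0 & q < 1),
            cloud_threshold > 0, cloud_threshold < core_threshold,
            core_threshold <= 1)
  structure(list(presence = presence, counts = counts,
                 populations = populations, vcf = vcf,
                 exon_table = exon_table, scopes = scopes,
                 min_reads = min_reads, core_threshold = core_threshold,
                 cloud_threshold = cloud_threshold, q = q,
                 out_dir = out_dir),
            class = "run_config")
}

load_stage <- function(obj, kind, populations, what) {
  if (is.null(obj)) return(NULL)
  if (inherits(obj, "pan_matrix")) return(obj)
  if (!file.exists(obj))
    stop(what, " file not found: ", obj, call. = FALSE)
  if (is.null(populations) || (!inherits(populations, "character")))
    stop("populations file required with ", what, " path", call. = FALSE)
  if (!file.exists(populations))
    stop("populations file not found: ", populations, call. = FALSE)
  read_matrix(obj, kind, populations)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full saturation-analysis pipeline
#'
#' Reads (or accepts) the matrices, derives presence from counts if needed,
#' computes per-scope accumulation curves, fits the saturation model,
#' evaluates limits and capture quantiles, partitions genes into
#' core/shell/cloud, tallies cross-population sharing, computes per-exon
#' diversity when a VCF is supplied, and writes every table plus a summary
#' JSON under `config$out_dir`.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with all in-memory results (`presence`,
#'   `curves`, `fits`, `quantiles`, `partition`, `sharing`, `diversity`,
#'   `summary_path`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  counts <- load_stage(config$counts, "counts", config$populations, "counts")
  presence <- load_stage(config$presence, "presence", config$populations,
                         "presence")
  if (is.null(presence))
    presence <- presence_from_counts(counts, config$min_reads)

  pops <- unique(unname(populations(presence)))
  scopes <- if (is.null(config$scopes)) c(pops, "ALL") else config$scopes

  curves <- list(); fits <- list(); quants <- list()
  for (sc in scopes) {
    cur <- accumulation_curve(presence, sc)
    curves[[sc]] <- cur
    write_tsv(cur, file.path(config$out_dir,
                             sprintf("curve_%s.tsv", sc)))
    fit <- try(fit_saturation(cur), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("saturation fit failed for scope ", sc, call. = FALSE)
      next
    }
    fits[[sc]] <- fit
    quants[[sc]] <- fit_quantiles(fit, config$q)
  }

  fit_tab <- do.call(rbind, lapply(names(fits), function(sc) {
    f <- fits[[sc]]
    qd <- quants[[sc]]
    data.frame(scope = sc, alpha = f$alpha, beta = f$beta,
               closed = f$closed,
               limit = if (is.finite(f$limit)) f$limit else Inf,
               q = qd$q,
               x_q = qd$x_q,
               residual_norm = f$residual_norm, converged = f$converged)
  }))
  if (!is.null(fit_tab))
    write_tsv(fit_tab, file.path(config$out_dir, "fits.tsv"))

  part <- classify_occupancy(presence, "ALL",
                             config$core_threshold, config$cloud_threshold)
  write_tsv(part$class_of, file.path(config$out_dir, "partition.tsv"))

  sharing <- if (length(pops) >= 2L) population_sharing(presence, pops)
             else NULL
  if (!is.null(sharing))
    write_tsv(sharing$detection, file.path(config$out_dir, "sharing.tsv"))

  diversity <- NULL
  if (!is.null(config$vcf)) {
    if (!file.exists(config$vcf))
      stop("vcf file not found: ", config$vcf, call. = FALSE)
    tabs <- read_genotypes(config$vcf, config$exon_table,
                           config$populations)
    diversity <- diversity_table(tabs)
    write_tsv(diversity, file.path(config$out_dir, "diversity.tsv"))
  }

  summary <- list(
    n_genes = length(gene_ids(presence)),
    n_individuals = length(individual_ids(presence)),
    populations = pops,
    thresholds = list(min_reads = config$min_reads,
                      core = config$core_threshold,
                      cloud = config$cloud_threshold, q = config$q),
    pan_size = pan_size(occupancy(presence, "ALL")),
    genes_per_individual = unname(colSums(presence$data)),
    fits = lapply(fits, function(f)
      list(scope = f$scope, alpha = f$alpha, beta = f$beta,
           closed = f$closed,
           limit = if (is.finite(f$limit)) f$limit else "open",
           residual_norm = f$residual_norm, converged = f$converged)),
    quantiles = lapply(quants, function(qd)
      lapply(seq_len(nrow(qd)), function(i)
        list(q = qd$q[i],
             x_q = if (is.na(qd$x_q[i])) "undefined (open)" else qd$x_q[i]))),
    partition = as.list(part$counts),
    partition_fractions = as.list(part$fractions),
    sharing_by_cardinality = if (!is.null(sharing))
      as.list(sharing$by_cardinality) else NULL,
    venn_cells = if (!is.null(sharing)) as.list(sharing$venn_cells) else NULL
  )
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(presence = presence, curves = curves, fits = fits,
                 quantiles = quants, partition = part, sharing = sharing,
                 diversity = diversity, summary_path = summary_path))
}
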