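# Pan-repertoire membership structure: occupancy classes and sharing.

#' Core / shell / cloud occupancy classification
#'
#' Genes detected in the scope are classified by the fraction of individuals
#' carrying them: *core* if found in at least `core_threshold` of the sample,
#' *cloud* if in less than `cloud_threshold`, *shell* in between (the
#' half-open remainder, so the three classes partition the detected genes).
#' Genes never detected in scope are labelled *absent* and excluded from the
#' class fractions.
#'
#' @param x a `presence_matrix` or `occupancy_vector`.
#' @param scope population label or `"ALL"` (ignored for occupancy input).
#' @param core_threshold inclusive core cutoff, default 0.80.
#' @param cloud_threshold exclusive cloud cutoff, default 0.20.
#' @return a `partition_result`: list with per-gene `class_of` (data frame of
#'   gene_id, occupancy_fraction, class), per-class `counts` and `fractions`,
#'   `n`, `scope` and the thresholds.
#' @export
classify_occupancy <- function(x, scope = "ALL",
                               core_threshold = 0.80,
                               cloud_threshold = 0.20) {
  if (!(cloud_threshold > 0 && cloud_threshold < core_threshold &&
        core_threshold <= 1))
    stop("need 0 < cloud_threshold < core_threshold <= 1", call. = FALSE)
  occ <- if (inherits(x, "occupancy_vector")) x else occupancy(x, scope)
  if (occ$n < 1L) stop("scope has no individuals", call. = FALSE)
  frac <- occ$m / occ$n
  cls <- ifelse(occ$m == 0L, "absent",
         ifelse(frac >= core_threshold, "core",
         ifelse(frac < cloud_threshold, "cloud", "shell")))
  detected <- cls != "absent"
  counts <- c(core = sum(cls == "core"), shell = sum(cls == "shell"),
              cloud = sum(cls == "cloud"))
  structure(
    list(class_of = data.frame(gene_id = occ$gene_ids,
                               occupancy_fraction = frac,
                               class = cls),
         counts = counts,
         fractions = if (sum(detected)) counts / sum(detected) else counts * NA,
         n = occ$n, scope = occ$scope,
         core_threshold = core_threshold,
         cloud_threshold = cloud_threshold),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "<partition (%s, n = %d): core %d (%.1f%%), shell %d (%.1f%%), cloud %d (%.1f%%)>\n",
    x$scope, x$n,
    x$counts["core"], 100 * x$fractions["core"],
    x$counts["shell"], 100 * x$fractions["shell"],
    x$counts["cloud"], 100 * x$fractions["cloud"]))
  invisible(x)
}

#' Cross-population sharing of genes
#'
#' For every gene, the set of populations in which it was detected in at
#' least one individual; tallied by how many populations share it and by the
#' exact combination (the cells of a Venn diagram).
#'
#' @param x a `presence_matrix`.
#' @param pops population labels to compare (at least two, all present in the
#'   matrix); defaults to all labels in the matrix.
#' @return a `sharing_result`: list with `detection` (data frame gene_id,
#'   detection_set with labels joined by ";"), `by_cardinality` (named counts
#'   over 0..k populations), and `venn_cells` (named counts per combination).
#' @export
population_sharing <- function(x, pops = NULL) {
  stopifnot(inherits(x, "presence_matrix"))
  all_pops <- unique(unname(populations(x)))
  if (is.null(pops)) pops <- all_pops
  unknown <- setdiff(pops, all_pops)
  if (length(unknown))
    stop("unknown label: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(pops) < 2L) stop("need at least 2 populations", call. = FALSE)

  det <- sapply(pops, function(p) occupancy(x, p)$m >= 1L)
  det <- matrix(det, ncol = length(pops), dimnames = list(NULL, pops))
  sets <- apply(det, 1L, function(row) paste(pops[row], collapse = ";"))
  card <- rowSums(det)

  by_card <- vapply(0:length(pops), function(k) sum(card == k), numeric(1))
  names(by_card) <- as.character(0:length(pops))
  cells <- table(sets[card > 0])
  structure(
    list(populations = pops,
         detection = data.frame(gene_id = gene_ids(x), detection_set = sets,
                                n_populations = card),
         by_cardinality = by_card,
         venn_cells = stats::setNames(as.integer(cells), names(cells))),
    class = "sharing_result"
  )
}

#' @export
print.sharing_result <- function(x, ...) {
  k <- length(x$populations)
  cat(sprintf("<sharing across %d populations (%s)>\n", k,
              paste(x$populations, collapse = ", ")))
  cat("  genes by number of populations:",
      paste(sprintf("%s:%d", names(x$by_cardinality), x$by_cardinality),
            collapse = "  "), "\n")
  invisible(x)
}
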