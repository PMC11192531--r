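# ---- constructors -----------------------------------------------------------

new_pan_matrix <- function(data, population, kind = c("presence", "counts")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(data))
  validate_pan_matrix(data, population, kind)
  structure(
    list(data = data, population = population),
    class = c(if (kind == "presence") "presence_matrix" else "count_matrix",
              "pan_matrix")
  )
}

validate_pan_matrix <- function(data, population, kind) {
  gid <- rownames(data)
  iid <- colnames(data)
  if (is.null(gid) && nrow(data) > 0L)
    stop("gene ids (rownames) are required", call. = FALSE)
  if (is.null(iid) && ncol(data) > 0L)
    stop("individual ids (colnames) are required", call. = FALSE)
  if (anyDuplicated(gid)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(iid)) stop("duplicate individual ids", call. = FALSE)
  if (anyNA(data)) stop("missing cells are not allowed", call. = FALSE)
  if (kind == "presence") {
    if (!all(data %in% c(0L, 1L)))
      stop("presence values must be 0 or 1", call. = FALSE)
  } else {
    if (any(data < 0)) stop("counts must be nonnegative", call. = FALSE)
    if (any(data != round(data))) stop("non-integer count", call. = FALSE)
  }
  if (!is.character(population))
    stop("population must be a named character vector", call. = FALSE)
  missing_pop <- setdiff(iid, names(population))
  if (length(missing_pop))
    stop("individual missing a population label: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Construct a presence or count matrix in memory
#'
#' @param data integer matrix, genes as rows (rownames = gene ids),
#'   individuals as columns (colnames = individual ids); 0/1 for presence,
#'   nonnegative integers for counts.
#' @param population named character vector mapping individual id to
#'   population label (must cover every column).
#' @return a `presence_matrix` / `count_matrix`.
#' @export
presence_matrix <- function(data, population) {
  if (any(data != round(data))) stop("presence values must be 0 or 1",
                                     call. = FALSE)
  storage.mode(data) <- "integer"
  new_pan_matrix(data, population, "presence")
}

#' @rdname presence_matrix
#' @export
count_matrix <- function(data, population) {
  if (any(data != round(data))) stop("non-integer count", call. = FALSE)
  storage.mode(data) <- "integer"
  new_pan_matrix(data, population, "counts")
}

#' Gene, individual and population accessors
#'
#' @param x a `presence_matrix` or `count_matrix`.
#' @return character vectors of ids, or the individual -> population map.
#' @export
gene_ids <- function(x) rownames(x$data)

#' @rdname gene_ids
#' @export
individual_ids <- function(x) colnames(x$data)

#' @rdname gene_ids
#' @export
populations <- function(x) x$population[colnames(x$data)]

#' @export
print.pan_matrix <- function(x, ...) {
  kind <- if (inherits(x, "presence_matrix")) "presence" else "read-count"
  cat(sprintf("<%s matrix: %d genes x %d individuals, %d population(s)>\n",
              kind, nrow(x$data), ncol(x$data),
              length(unique(populations(x)))))
  invisible(x)
}

# ---- I/O --------------------------------------------------------------------

#' Read a gene x individual matrix with population labels
#'
#' Reads a tab-separated matrix whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns are one per individual, together
#' with a two-column populations table (`individual_id`, `population`)
#' assigning every individual to a population. Presence matrices must contain
#' only 0/1; count matrices only nonnegative integers. Row and column order of
#' the file is preserved.
#'
#' @param path path to the matrix TSV.
#' @param kind `"presence"` or `"counts"`.
#' @param populations path to the populations TSV.
#' @return a `presence_matrix` or `count_matrix` object.
#' @export
read_matrix <- function(path, kind = c("presence", "counts"), populations) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 1L || names(raw)[1L] != "gene_id")
    stop("matrix file must start with a 'gene_id' column", call. = FALSE)
  gid <- raw[[1L]]
  iid <- names(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (any(vals == "" | is.na(vals)))
    stop("missing cells are not allowed", call. = FALSE)
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) stop("non-numeric cell in matrix", call. = FALSE)
  if (any(num != round(num))) stop("non-integer count", call. = FALSE)
  mat <- matrix(as.integer(round(num)), nrow = length(gid),
                ncol = length(iid), dimnames = list(gid, iid))
  pop <- read_populations(populations)
  new_pan_matrix(mat, pop, kind)
}

read_populations <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("individual_id", "population")
  if (!all(need %in% names(tab)))
    stop("populations file needs columns individual_id, population",
         call. = FALSE)
  if (anyDuplicated(tab$individual_id))
    stop("duplicate individual in populations file", call. = FALSE)
  stats::setNames(tab$population, tab$individual_id)
}

#' Write a matrix back to canonical TSV
#'
#' Emits UTF-8, tab-delimited, LF-terminated lines with no trailing
#' whitespace; reading the result back with [read_matrix()] round-trips.
#'
#' @param x a `presence_matrix` or `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "pan_matrix"))
  header <- paste(c("gene_id", individual_ids(x)), collapse = "\t")
  body <- apply(cbind(gene_ids(x), x$data), 1L, paste, collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---- derivations ------------------------------------------------------------

#' Call gene presence from read counts
#'
#' A gene is called present in an individual when at least `min_reads` reads
#' map to it. The default of 1 read treats any mapped evidence as presence of
#' at least one gene copy; raising the threshold makes calls conservative and
#' can only remove presences (monotonicity).
#'
#' @param counts a `count_matrix`.
#' @param min_reads positive integer threshold (inclusive).
#' @return a `presence_matrix` with the same genes, individuals and labels.
#' @export
presence_from_counts <- function(counts, min_reads = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(min_reads) != 1L || is.na(min_reads) || min_reads < 1)
    stop("min_reads must be a positive integer", call. = FALSE)
  pres <- matrix(as.integer(counts$data >= min_reads),
                 nrow = nrow(counts$data),
                 dimnames = dimnames(counts$data))
  new_pan_matrix(pres, counts$population, "presence")
}

#' Per-individual copy proportions
#'
#' For each individual, the fraction of its family-aligned reads assigned to
#' each gene: `count(g, i) / sum_g count(g, i)`. Columns therefore sum to one.
#' A darker cell (larger fraction) suggests the gene is present in multiple
#' copies in that individual. Individuals with zero total reads yield an
#' all-zero column and a warning.
#'
#' @param counts a `count_matrix`.
#' @return numeric matrix of fractions, genes x individuals.
#' @export
copy_proportions <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- colSums(counts$data)
  if (all(totals == 0))
    stop("at least one individual must have a nonzero total", call. = FALSE)
  if (any(totals == 0))
    warning("individual(s) with zero total reads: ",
            paste(colnames(counts$data)[totals == 0], collapse = ", "),
            call. = FALSE)
  prop <- sweep(counts$data, 2L, pmax(totals, 1), "/")
  prop[, totals == 0] <- 0
  prop
}

#' Display filter: genes with strong support in at least one individual
#'
#' Keeps genes for which some individual has at least `min_max_reads` mapped
#' reads; used to restrict heatmap-style displays to well-supported genes.
#'
#' @param counts a `count_matrix`.
#' @param min_max_reads positive integer (inclusive).
#' @return character vector of gene ids, input order preserved.
#' @export
display_filter <- function(counts, min_max_reads = 10L) {
  stopifnot(inherits(counts, "count_matrix"), min_max_reads >= 1)
  keep <- apply(counts$data, 1L, max) >= min_max_reads
  gene_ids(counts)[keep]
}

# ---- occupancy --------------------------------------------------------------

scope_individuals <- function(x, scope = "ALL") {
  iid <- individual_ids(x)
  if (identical(scope, "ALL")) return(iid)
  pop <- populations(x)
  if (!scope %in% pop)
    stop("unknown population label: ", scope, call. = FALSE)
  iid[pop == scope]
}

#' Gene occupancy within a scope
#'
#' Counts, for every gene, the number `m_g` of in-scope individuals carrying
#' it, together with the scope size `n`. This (m, n) summary is all the
#' accumulation-curve machinery needs.
#'
#' @param x a `presence_matrix`.
#' @param scope a population label, or `"ALL"` for the pooled sample.
#' @return an `occupancy_vector`: list with `gene_ids`, `m`, `n`, `scope`.
#' @export
occupancy <- function(x, scope = "ALL") {
  stopifnot(inherits(x, "presence_matrix"))
  ids <- scope_individuals(x, scope)
  sub <- x$data[, ids, drop = FALSE]
  structure(
    list(gene_ids = gene_ids(x),
         m = as.integer(rowSums(sub)),
         n = length(ids),
         scope = scope),
    class = "occupancy_vector"
  )
}

#' @export
print.occupancy_vector <- function(x, ...) {
  cat(sprintf("<occupancy: %d genes, n = %d individuals (%s), pan size %d>\n",
              length(x$m), x$n, x$scope, sum(x$m >= 1L)))
  invisible(x)
}

#' Observed pan-repertoire size in scope
#'
#' @param occ an `occupancy_vector`.
#' @return number of genes present in at least one in-scope individual.
#' @export
pan_size <- function(occ) {
  stopifnot(inherits(occ, "occupancy_vector"))
  sum(occ$m >= 1L)
}
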