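# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except files the tests themselves write.

# presence matrix from a plain 0/1 matrix; one population unless pops given
toy_presence <- function(mat, pops = NULL) {
  if (nrow(mat) > 0 && is.null(rownames(mat)))
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  if (is.null(pops)) pops <- rep("P1", ncol(mat))
  presence_matrix(mat, setNames(pops, colnames(mat)))
}

toy_counts <- function(mat, pops = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  if (is.null(pops)) pops <- rep("P1", ncol(mat))
  count_matrix(mat, setNames(pops, colnames(mat)))
}

# random presence matrix with n individuals for oracle tests
random_presence <- function(n_genes, n_ind, p = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(p)) p <- runif(n_genes)
    mat <- matrix(as.integer(runif(n_genes * n_ind) <
                               rep(p, n_ind)), n_genes, n_ind)
    toy_presence(mat)
  })
}

# write matrix + population TSVs for I/O tests; returns the paths
write_fixture_tsvs <- function(mat_lines, pop_lines, dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  mpath <- file.path(dir, "matrix.tsv")
  ppath <- file.path(dir, "populations.tsv")
  writeLines(mat_lines, mpath)
  writeLines(pop_lines, ppath)
  list(matrix = mpath, populations = ppath)
}

default_pop_lines <- function(ids, pops = rep("P1", length(ids))) {
  c("individual_id\tpopulation", paste(ids, pops, sep = "\t"))
}
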