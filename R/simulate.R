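# Synthetic-data generators.
#
# Two tiers, deliberately distinct:
#  * simulate_model_curve() draws data exactly from the saturation model
#    y = alpha * H(x, beta) (plus optional increment noise) and is the
#    harness for parameter-recovery tests of the fitting stage;
#  * simulate_presence() draws presence/absence matrices from a carrier-
#    frequency spectrum. Its expected accumulation curve is NOT exactly
#    alpha * H(x, beta) (no closed-form inverse exists), so matrix-level
#    tests assert qualitative regime properties, not exact parameters.
# All generators are deterministic given (config, seed).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles the seeds and distributional parameters of the generator. The
#' defaults emulate the scales of a wild zebrafish NLR survey: a pool of
#' 1500 genes, three wild populations of 20 fish, a rare-heavy occupancy
#' spectrum giving roughly 150--350 genes per fish and a core fraction of a
#' few percent, and neutral SNPs on exons of 1761 bp (FISNA-NACHT class) and
#' 540 bp (B30.2 class).
#'
#' @param seed integer master seed.
#' @param populations character vector of population labels.
#' @param n_individuals individuals per population (recycled).
#' @param gene_pool_size total genes in the simulated pool.
#' @param occupancy_model list; either
#'   `list(model = "beta_mixture", a, b, rare_weight)` (carrier frequency
#'   drawn from `rare_weight`-mixture of Beta(0.5, 10) (rare) and Beta(a, b))
#'   or `list(model = "fixed_spectrum", m = <occupancy counts>)` giving exact
#'   per-gene occupancy within each population.
#' @param mean_depth,dispersion read-count model (negative binomial).
#' @param snp_model list with `n_exons`, `l` and `theta` per exon class.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       populations = c("W1", "W2", "W3"),
                       n_individuals = 20L,
                       gene_pool_size = 1500L,
                       occupancy_model = list(model = "beta_mixture",
                                              a = 0.8, b = 1.2,
                                              rare_weight = 0.65),
                       mean_depth = 20, dispersion = 0.5,
                       snp_model = list(
                         n_exons = c(`FISNA-NACHT` = 60L, `B30.2` = 40L),
                         l = c(`FISNA-NACHT` = 1761L, `B30.2` = 540L),
                         theta = c(`FISNA-NACHT` = 0.004, `B30.2` = 0.006))) {
  stopifnot(gene_pool_size >= 1, all(n_individuals >= 1),
            all(snp_model$theta > 0 & snp_model$theta < 0.1))
  n_individuals <- rep_len(n_individuals, length(populations))
  structure(list(seed = as.integer(seed), populations = populations,
                 n_individuals = n_individuals,
                 gene_pool_size = as.integer(gene_pool_size),
                 occupancy_model = occupancy_model,
                 mean_depth = mean_depth, dispersion = dispersion,
                 snp_model = snp_model),
            class = "sim_config")
}

#' Simulate an exact saturation-model curve with optional noise
#'
#' Generates `y(x) = alpha * H(x, beta)` for `x = 1..n`. Noise of standard
#' deviation `noise_sd` is applied to the *increments* and truncated at zero,
#' so the curve stays a valid nondecreasing accumulation curve.
#'
#' @param alpha,beta model parameters (positive).
#' @param n number of points (>= 3).
#' @param noise_sd Gaussian increment noise, >= 0.
#' @param seed integer seed.
#' @param scope label stored in the curve.
#' @return an `accumulation_curve` data frame.
#' @export
simulate_model_curve <- function(alpha, beta, n, noise_sd = 0, seed = 1L,
                                 scope = "sim") {
  stopifnot(alpha > 0, beta > 0, n >= 3, noise_sd >= 0)
  inc <- alpha * seq_len(n)^(-beta)
  if (noise_sd > 0)
    inc <- with_seed(seed, pmax(inc + stats::rnorm(n, 0, noise_sd), 0))
  structure(
    data.frame(scope = rep(scope, n), x = seq_len(n), G = cumsum(inc),
               delta = inc),
    class = c("accumulation_curve", "data.frame"))
}

#' Simulate a presence/absence matrix from a carrier-frequency spectrum
#'
#' Under the `beta_mixture` model every gene receives a carrier probability
#' `p_g` (rare-heavy mixture), and every individual carries the gene
#' independently with probability `p_g`. Optionally each gene is restricted
#' to a random subset of populations (`restrict_prob` is the chance of being
#' unavailable in any given population), which creates population-specific
#' genes for sharing analyses. Under `fixed_spectrum`, each gene is placed in
#' exactly `m` individuals per population (sampled without replacement),
#' giving exact occupancies for closed-form tests.
#'
#' @param config a `sim_config`.
#' @param restrict_prob per-population unavailability probability, default 0.
#' @return a `presence_matrix`; the true carrier probabilities are attached
#'   as attribute `"p"` (beta_mixture) or `"m"` (fixed_spectrum).
#' @export
simulate_presence <- function(config, restrict_prob = 0) {
  stopifnot(inherits(config, "sim_config"))
  om <- config$occupancy_model
  pops <- config$populations
  npp <- config$n_individuals
  iid <- unlist(lapply(seq_along(pops), function(k)
    sprintf("%s_%02d", pops[k], seq_len(npp[k]))))
  popmap <- stats::setNames(rep(pops, npp), iid)
  ng <- config$gene_pool_size
  gid <- sprintf("g%04d", seq_len(ng))

  with_seed(config$seed, {
    if (identical(om$model, "beta_mixture")) {
      rare <- stats::runif(ng) < om$rare_weight
      p <- ifelse(rare, stats::rbeta(ng, 0.5, 10), stats::rbeta(ng, om$a, om$b))
      avail <- matrix(stats::runif(ng * length(pops)) >= restrict_prob,
                      ng, length(pops), dimnames = list(gid, pops))
      mat <- matrix(0L, ng, length(iid), dimnames = list(gid, iid))
      for (i in seq_along(iid)) {
        ok <- avail[, popmap[iid[i]]]
        mat[, i] <- as.integer(ok & stats::runif(ng) < p)
      }
      truth <- p
      truth_attr <- "p"
    } else if (identical(om$model, "fixed_spectrum")) {
      m <- as.integer(om$m)
      stopifnot(length(m) == ng, all(m >= 0), all(m <= npp))
      mat <- matrix(0L, ng, length(iid), dimnames = list(gid, iid))
      for (k in seq_along(pops)) {
        cols <- which(popmap[iid] == pops[k])
        for (g in seq_len(ng)) {
          if (m[g] > 0L) mat[g, sample(cols, m[g])] <- 1L
        }
      }
      truth <- m
      truth_attr <- "m"
    } else stop("unknown occupancy model: ", om$model, call. = FALSE)
    out <- new_pan_matrix(mat, popmap, "presence")
    attr(out, truth_attr) <- truth
    out
  })
}

#' Simulate overdispersed read counts on a presence matrix
#'
#' Present cells receive `max(1, NB(mu = mean_depth * thinning_i,
#' size = 1/dispersion))` reads (Poisson in the `dispersion = 0` limit), so a
#' present gene always retains at least one read and presence is recoverable
#' at `min_reads = 1`; absent cells receive 0. Per-individual `thinning`
#' factors mimic low-coverage samples.
#'
#' @param presence a `presence_matrix`.
#' @param mean_depth expected reads per present gene copy.
#' @param dispersion negative-binomial overdispersion (0 = Poisson limit).
#' @param thinning optional named (or positionally recycled) per-individual
#'   depth multipliers in (0, 1].
#' @param seed integer seed.
#' @return a `count_matrix`.
#' @export
simulate_read_counts <- function(presence, mean_depth = 20, dispersion = 0.5,
                                 thinning = NULL, seed = 1L) {
  stopifnot(inherits(presence, "presence_matrix"), mean_depth > 0,
            dispersion >= 0)
  iid <- individual_ids(presence)
  th <- rep_len(1, length(iid))
  names(th) <- iid
  if (!is.null(thinning)) {
    if (!is.null(names(thinning))) th[names(thinning)] <- thinning
    else th <- rep_len(thinning, length(iid))
    stopifnot(all(th > 0), all(th <= 1))
  }
  with_seed(seed, {
    cnt <- matrix(0L, nrow(presence$data), ncol(presence$data),
                  dimnames = dimnames(presence$data))
    for (i in seq_along(iid)) {
      on <- presence$data[, i] == 1L
      k <- sum(on)
      if (!k) next
      mu <- mean_depth * th[i]
      draw <- if (dispersion == 0) stats::rpois(k, mu)
              else stats::rnbinom(k, mu = mu, size = 1 / dispersion)
      cnt[on, i] <- pmax(1L, as.integer(draw))
    }
    new_pan_matrix(cnt, presence$population, "counts")
  })
}

#' Simulate neutral-model SNP genotypes for a set of exons
#'
#' For each exon the number of segregating sites is drawn as
#' `S ~ Poisson(theta * H(n_hap - 1, 1) * l)` (the Watterson relation
#' inverted), each site gets a derived-allele haplotype count `i` in
#' `1..n_hap-1` with probability proportional to `1/i` (the neutral site
#' frequency spectrum), derived alleles are assigned to haplotypes uniformly
#' at random, and haplotypes are paired into diploid genotypes. Individuals
#' carry population labels as metadata; the model itself is panmictic, and an
#' exchangeable subsample of a neutral sample is again neutral, so
#' per-population estimators stay calibrated.
#'
#' @param config a `sim_config` (uses `snp_model`, `populations`,
#'   `n_individuals`, `seed`).
#' @return list of `genotype_table` objects; attribute `"theta"` carries the
#'   per-class true theta.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sm <- config$snp_model
  pops <- config$populations
  npp <- config$n_individuals
  iid <- unlist(lapply(seq_along(pops), function(k)
    sprintf("%s_%02d", pops[k], seq_len(npp[k]))))
  popmap <- stats::setNames(rep(pops, npp), iid)
  n_ind <- length(iid)
  n_hap <- 2L * n_ind

  with_seed(config$seed + 1L, {
    tables <- list()
    for (cls in names(sm$n_exons)) {
      l <- sm$l[[cls]]
      theta <- sm$theta[[cls]]
      for (e in seq_len(sm$n_exons[[cls]])) {
        exon_id <- sprintf("%s_exon%03d", gsub("[^A-Za-z0-9]", "", cls), e)
        S <- stats::rpois(1L, theta * gharmonic(max(n_hap - 1L, 1L), 1) * l)
        S <- min(S, l)
        pos <- sort(sample.int(l, S))
        gt <- matrix(0, S, n_ind, dimnames = list(NULL, iid))
        if (S > 0L) {
          sfs_p <- (1 / seq_len(n_hap - 1L))
          sfs_p <- sfs_p / sum(sfs_p)
          for (s in seq_len(S)) {
            i_derived <- sample.int(n_hap - 1L, 1L, prob = sfs_p)
            hap <- sample.int(n_hap, i_derived)
            # haplotypes 2j-1, 2j belong to individual j
            gt[s, ] <- tabulate((hap + 1L) %/% 2L, nbins = n_ind)
          }
        }
        tables[[exon_id]] <- new_genotype_table(
          exon_id, l, cls, pos, gt, popmap)
      }
    }
    attr(tables, "theta") <- sm$theta
    tables
  })
}

#' Write simulated genotype tables as a minimal VCF
#'
#' Emits a plain-text VCF 4.2 with one contig per exon and diploid GT-only
#' genotype columns, readable back with [read_genotypes()].
#'
#' @param tables list of `genotype_table` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(tables, path) {
  stopifnot(length(tables) >= 1L)
  samples <- colnames(tables[[1L]]$gt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>",
            vapply(tables, `[[`, character(1), "exon_id"),
            vapply(tables, `[[`, numeric(1), "length")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_string <- c("0/0", "0/1", "1/1")
  body <- unlist(lapply(tables, function(tab) {
    if (!length(tab$pos)) return(character(0))
    vapply(seq_along(tab$pos), function(s) {
      calls <- gt_string[tab$gt[s, ] + 1L]
      paste(c(tab$exon_id, tab$pos[s], ".", "A", "G", ".", "PASS", ".",
              "GT", calls), collapse = "\t")
    }, character(1))
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the population map of a simulated object
#'
#' @param x a `pan_matrix` or list of `genotype_table`s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_populations <- function(x, path) {
  pop <- if (inherits(x, "pan_matrix")) populations(x)
         else x[[1L]]$population
  lines <- c("individual_id\tpopulation",
             paste(names(pop), pop, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write an exon table for simulated genotype tables
#'
#' @param tables list of `genotype_table`s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_exon_table <- function(tables, path) {
  lines <- c("exon_id\tlength\tclass",
             vapply(tables, function(t)
               paste(t$exon_id, t$length, t$class, sep = "\t"),
               character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
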