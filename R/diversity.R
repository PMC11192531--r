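# Per-exon, per-population nucleotide diversity from diploid SNP genotypes.
#
# theta_pi: sum over sites of the unbiased per-site pairwise diversity
#   2 * n_ref * n_alt / (n * (n - 1)), divided by the full exon length l.
# theta_w (Watterson): S / (H(n_hap - 1, 1) * l), with H(., 1) the classic
#   harmonic number and S the number of sites segregating *within the
#   population*. Under neutrality and constant population size the two
#   estimators have the same expectation, so theta_pi / theta_w ~ 1; ratios
#   below 1 indicate an excess of rare alleles.

#' Per-site pairwise diversity from allele counts
#'
#' The probability that two distinct alleles drawn without replacement from
#' the site differ: `2 * n_i * n_j / (n * (n - 1))` for a biallelic site with
#' allele counts `n_i`, `n_j` (`n = n_i + n_j`).
#'
#' @param n_i,n_j nonnegative allele counts; `n_i + n_j >= 2`.
#' @return fraction in \[0, 1\].
#' @export
site_pi <- function(n_i, n_j) {
  n <- n_i + n_j
  if (any(n < 2)) stop("need at least 2 sampled alleles", call. = FALSE)
  2 * n_i * n_j / (n * (n - 1))
}

#' Watterson's estimator of the scaled mutation rate
#'
#' `theta_w = S / (H(n_hap - 1, 1) * l)`: segregating sites normalised by the
#' harmonic number of the number of sampled sequences minus one, per base
#' pair.
#'
#' @param S number of segregating sites (nonnegative integer).
#' @param n_hap number of sampled sequences (haplotypes), at least 2.
#' @param l sequence length in base pairs.
#' @return per-site theta_w.
#' @export
watterson_theta <- function(S, n_hap, l) {
  stopifnot(S >= 0, l >= 1)
  if (n_hap < 2) stop("need at least 2 haplotypes", call. = FALSE)
  S / (gharmonic(n_hap - 1, 1) * l)
}

# ---- genotype tables --------------------------------------------------------

new_genotype_table <- function(exon_id, length, class, pos, gt, population) {
  stopifnot(length >= 1, all(pos >= 1), all(pos <= length),
            !anyDuplicated(pos))
  structure(
    list(exon_id = exon_id, length = length, class = class,
         pos = pos, gt = gt, population = population),
    class = "genotype_table"
  )
}

#' Read per-exon diploid SNP genotypes from a VCF
#'
#' Parses a VCF whose contigs are exon sequences, keeps biallelic SNP records
#' only (multiallelic sites, indels and other non-SNP records are skipped and
#' counted), and groups the genotypes per exon using an exon table mapping
#' contig name to exon id, length and exon class. Genotypes are coded as
#' alternate-allele dosage 0/1/2 with `NA` for missing calls.
#'
#' @param vcf_path path to a VCF (plain or bgzipped).
#' @param exon_table_path TSV with columns `exon_id`, `length`, `class`.
#' @param populations_path TSV mapping `individual_id` to `population`.
#' @return list of `genotype_table` objects, one per exon in the exon table
#'   (exons without any retained variant get zero sites); the number of
#'   skipped records is attached as attribute `"skipped"`.
#' @export
read_genotypes <- function(vcf_path, exon_table_path, populations_path) {
  exons <- utils::read.delim(exon_table_path, colClasses = c(
    exon_id = "character", length = "integer", class = "character"))
  stopifnot(all(c("exon_id", "length", "class") %in% names(exons)))
  pop <- read_populations(populations_path)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  n_rec <- nrow(fix)
  if (is.null(n_rec)) n_rec <- 0L
  if (n_rec > 0L) {
    chrom <- fix[, "CHROM"]
    unknown <- setdiff(unique(chrom), exons$exon_id)
    if (length(unknown))
      stop("contig absent from exon table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
      !grepl(",", fix[, "ALT"], fixed = TRUE) &
      fix[, "REF"] %in% c("A", "C", "G", "T") &
      fix[, "ALT"] %in% c("A", "C", "G", "T")
    skipped <- sum(!snp)
    gt_raw <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = n_rec)
    dose <- gt_to_dosage(gt_raw)
    pos <- as.integer(fix[, "POS"])
  } else {
    skipped <- 0L
    snp <- logical(0)
    dose <- matrix(NA_real_, 0, 0)
    chrom <- character(0)
    pos <- integer(0)
  }
  samples <- colnames(vcf@gt)[-1L]
  missing_pop <- setdiff(samples, names(pop))
  if (length(missing_pop))
    stop("individual missing a population label: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)

  tables <- lapply(seq_len(nrow(exons)), function(i) {
    keep <- if (n_rec > 0L) snp & chrom == exons$exon_id[i] else logical(0)
    sub <- if (any(keep)) dose[keep, , drop = FALSE]
           else matrix(NA_real_, 0L, length(samples))
    colnames(sub) <- samples
    new_genotype_table(
      exon_id = exons$exon_id[i], length = exons$length[i],
      class = exons$class[i],
      pos = pos[keep],
      gt = sub,
      population = pop[samples])
  })
  names(tables) <- exons$exon_id
  attr(tables, "skipped") <- skipped
  tables
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean %in% "0/0"] <- 0
  d[clean %in% c("0/1", "1/0")] <- 1
  d[clean %in% "1/1"] <- 2
  bad <- !is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(bad))
    stop("malformed GT: ", clean[bad][1L], call. = FALSE)
  d
}

# ---- estimators -------------------------------------------------------------

#' Per-exon nucleotide diversity within a population
#'
#' Computes segregating sites `S`, per-site `theta_pi` and Watterson's
#' `theta_w` for one exon restricted to the individuals of one population.
#' Missing genotypes are excluded per site; sites with fewer than two
#' surviving haplotypes are dropped. Segregation is population-relative: a
#' site fixed for the alternate allele within the population does not count
#' towards `S`. `theta_pi` sums per-site pairwise diversity over retained
#' sites and divides by the full exon length; `theta_w` uses the minimum
#' per-site haplotype count across retained sites (or twice the number of
#' individuals when the exon has no sites).
#'
#' @param table a `genotype_table`.
#' @param population population label.
#' @return one-row data frame: exon_id, class, population, n_hap, S, l,
#'   theta_pi, theta_w, ratio (`NA` when S = 0), monomorphic.
#' @export
exon_diversity <- function(table, population) {
  stopifnot(inherits(table, "genotype_table"))
  in_pop <- names(table$population)[table$population == population]
  if (!length(in_pop)) stop("no data for population: ", population,
                            call. = FALSE)
  gt <- table$gt[, in_pop, drop = FALSE]
  l <- table$length

  pi_sum <- 0
  S <- 0L
  n_haps <- integer(0)
  for (s in seq_len(nrow(gt))) {
    row <- gt[s, ]
    ok <- !is.na(row)
    n_hap_s <- 2L * sum(ok)
    if (n_hap_s < 2L) next
    n_alt <- sum(row[ok])
    n_ref <- n_hap_s - n_alt
    n_haps <- c(n_haps, n_hap_s)
    if (n_alt > 0 && n_ref > 0) {
      S <- S + 1L
      pi_sum <- pi_sum + site_pi(n_ref, n_alt)
    }
  }
  n_hap <- if (length(n_haps)) min(n_haps) else 2L * length(in_pop)
  theta_pi <- pi_sum / l
  theta_w <- if (n_hap >= 2L) watterson_theta(S, n_hap, l) else 0
  data.frame(
    exon_id = table$exon_id, class = table$class, population = population,
    n_hap = n_hap, S = S, l = l,
    theta_pi = theta_pi, theta_w = theta_w,
    ratio = if (S >= 1L) theta_pi / theta_w else NA_real_,
    monomorphic = S == 0L)
}

#' Diversity table over exons and populations
#'
#' @param tables list of `genotype_table` objects (as from
#'   [read_genotypes()]).
#' @param populations labels to compute for; default all labels present.
#' @return data frame with one row per exon x population.
#' @export
diversity_table <- function(tables, populations = NULL) {
  stopifnot(length(tables) >= 1L)
  if (is.null(populations))
    populations <- unique(unname(tables[[1L]]$population))
  rows <- lapply(tables, function(tab)
    do.call(rbind, lapply(populations, function(p) exon_diversity(tab, p))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of exons without any polymorphism
#'
#' @param records a diversity table (rows from [exon_diversity()]).
#' @param population label to restrict to.
#' @return fraction of assessed exons with `S = 0` in that population.
#' @export
monomorphic_fraction <- function(records, population) {
  sub <- records[records$population == population, , drop = FALSE]
  if (!nrow(sub)) stop("no exon records for population: ", population,
                       call. = FALSE)
  mean(sub$S == 0L)
}
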