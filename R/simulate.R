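#' Simulation configuration for a two-gene-pool germplasm cohort
#'
#' Describes a synthetic cohort with the stratification of a structured
#' germplasm collection: two diverged gene pools (Andean, Mesoamerican), each
#' containing landraces and diversity-narrowed breeding lines. Defaults
#' reproduce the composition of the CAAS common-bean collection: 628
#' accessions = 484 landraces (223 Andean + 261 Mesoamerican) + 144 breeding
#' lines (60 Andean + 84 Mesoamerican) on 11 chromosomes.
#'
#' @param n_landrace_an,n_landrace_m,n_breeding_an,n_breeding_m non-negative
#'   stratum sizes (Andean/Mesoamerican landraces and breeding lines).
#' @param n_markers positive number of biallelic SNP markers.
#' @param n_chromosomes positive number of chromosomes; markers are assigned
#'   to chromosomes in contiguous, near-equal blocks.
#' @param fst between-pool divergence in `[0, 1)` under the Balding-Nichols
#'   model. The default 0.4 reflects the strong differentiation between the
#'   two bean gene pools.
#' @param h2 default narrow-sense heritability for simulated traits, in
#'   `[0, 1]`.
#' @param n_qtl number of causal markers per trait (`<= n_markers`).
#' @param founder_fraction fraction in `(0, 1]` controlling how narrow the
#'   breeding-line diversity is: breeding lines of a pool are drawn from the
#'   allele frequencies of a founder subset of size
#'   `max(2, round(founder_fraction * n_breeding_pool))` rather than from the
#'   pool frequencies directly. Smaller values give breeding lines that are
#'   mutually closer than they are to the landraces.
#' @param missing_rate probability in `[0, 1)` that any genotype call is
#'   masked as missing, completely at random.
#' @param seed integer RNG seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_landrace_an = 223, n_landrace_m = 261,
                       n_breeding_an = 60, n_breeding_m = 84,
                       n_markers = 10000, n_chromosomes = 11,
                       fst = 0.4, h2 = 0.5, n_qtl = min(100, n_markers),
                       founder_fraction = 0.5, missing_rate = 0,
                       seed = 1) {
  counts <- c(n_landrace_an, n_landrace_m, n_breeding_an, n_breeding_m)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("stratum sizes must be non-negative and sum to a positive total")
  }
  if (n_markers < 1) stop("n_markers must be positive")
  if (n_chromosomes < 1) stop("n_chromosomes must be positive")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (n_qtl < 1 || n_qtl > n_markers) stop("n_qtl must lie in [1, n_markers]")
  if (founder_fraction <= 0 || founder_fraction > 1) {
    stop("founder_fraction must lie in (0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  structure(list(
    n_landrace_an = as.integer(n_landrace_an),
    n_landrace_m = as.integer(n_landrace_m),
    n_breeding_an = as.integer(n_breeding_an),
    n_breeding_m = as.integer(n_breeding_m),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    fst = fst, h2 = h2, n_qtl = as.integer(n_qtl),
    founder_fraction = founder_fraction,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Balding-Nichols draw of pool allele frequencies around ancestral p at
# divergence F; F = 0 collapses to the ancestral frequency.
bn_pool_freq <- function(p_anc, fst) {
  if (fst == 0) return(p_anc)
  shape <- (1 - fst) / fst
  stats::rbeta(length(p_anc), p_anc * shape, (1 - p_anc) * shape)
}

#' Simulate a structured two-gene-pool cohort
#'
#' Generates inbred-coded genotypes (values 0/1, two homozygote classes) for
#' a stratified germplasm cohort. Per marker, an ancestral allele frequency
#' is drawn uniformly on `[0.05, 0.95]`; each gene pool's frequency is then
#' drawn from the Balding-Nichols Beta distribution around the ancestral
#' value at divergence `fst`, and each inbred accession's genotype is a
#' Bernoulli draw from its pool frequency. Breeding lines are drawn from
#' drifted founder-subset frequencies (see [sim_config()]), which narrows
#' their diversity relative to the landraces of the same pool. Markers are
#' independent given pool frequencies (no linkage), assigned to chromosomes
#' in contiguous blocks. Missing calls are masked completely at random.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `metadata` (data.frame with columns `accession_id`,
#'   `pool` in `{Andean, Mesoamerican}`, `class` in `{landrace, breeding}`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_markers = 200, seed = 7))
#' table(cohort$metadata$pool, cohort$metadata$class)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_markers

  p_anc <- stats::runif(m, 0.05, 0.95)
  p_an <- bn_pool_freq(p_anc, config$fst)
  p_m <- bn_pool_freq(p_anc, config$fst)

  draw_stratum <- function(n, p) {
    if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = m))
    matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), nrow = n, ncol = m)
  }
  draw_breeding <- function(n, p, frac) {
    if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = m))
    n_founders <- max(2L, as.integer(round(frac * n)))
    founders <- draw_stratum(n_founders, p)
    # each breeding line is a selfed inbred progeny of a biparental cross
    # between two founders; lines sharing a parent are mutually closer than
    # unrelated pool members, giving the heterogeneous kinship that narrow
    # breeding programs produce
    out <- matrix(0, nrow = n, ncol = m)
    for (i in seq_len(n)) {
      parents <- sample.int(n_founders, 2L)
      p_line <- (founders[parents[1L], ] + founders[parents[2L], ]) / 2
      out[i, ] <- stats::rbinom(m, 1L, p_line)
    }
    out
  }

  g_lan_an <- draw_stratum(config$n_landrace_an, p_an)
  g_lan_m <- draw_stratum(config$n_landrace_m, p_m)
  g_bre_an <- draw_breeding(config$n_breeding_an, p_an, config$founder_fraction)
  g_bre_m <- draw_breeding(config$n_breeding_m, p_m, config$founder_fraction)

  values <- rbind(g_lan_an, g_lan_m, g_bre_an, g_bre_m)
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(values)) < config$missing_rate,
                   nrow = nrow(values))
    values[mask] <- NA_real_
  }

  n_total <- nrow(values)
  ids <- sprintf("acc%04d", seq_len(n_total))
  metadata <- data.frame(
    accession_id = ids,
    pool = c(rep("Andean", config$n_landrace_an),
             rep("Mesoamerican", config$n_landrace_m),
             rep("Andean", config$n_breeding_an),
             rep("Mesoamerican", config$n_breeding_m)),
    class = c(rep("landrace", config$n_landrace_an + config$n_landrace_m),
              rep("breeding", config$n_breeding_an + config$n_breeding_m)),
    stringsAsFactors = FALSE
  )

  chrom_sizes <- diff(floor(seq(0, m, length.out = config$n_chromosomes + 1)))
  chrom <- rep(sprintf("Chr%02d", seq_len(config$n_chromosomes)), chrom_sizes)
  pos <- unlist(lapply(chrom_sizes, function(k) seq_len(k) * 1000L),
                use.names = FALSE)
  map <- data.frame(
    chrom = chrom, pos = pos,
    id = sprintf("snp%05d", seq_len(m)),
    ref = "A", alt = "T", stringsAsFactors = FALSE
  )

  list(genotypes = genotype_matrix(values, map, ids), metadata = metadata)
}

#' Simulate an additive trait on a genotype matrix
#'
#' Samples `n_qtl` causal markers, draws i.i.d. standard-normal effects, and
#' builds the genetic value as the centered (mean-imputed) genotype matrix
#' times the effects at the causal markers. Environmental noise is scaled to
#' the realized genetic variance so that `var(g)/var(y) = h2` in expectation.
#' Markers with no variation among the non-missing calls are excluded from
#' the causal draw (their centered column is identically zero). With
#' `h2 = 0` the phenotype is pure standard-normal noise; with `h2 = 1` it is
#' the genetic value itself.
#'
#' @param G a [genotype_matrix()].
#' @param h2 heritability in `[0, 1]`.
#' @param n_qtl number of causal markers.
#' @param seed integer RNG seed.
#' @return A list with `phenotype` (named numeric vector), and
#'   `architecture`: a list with `qtl_indices`, `qtl_effects`, `h2`, and the
#'   realized `genetic_values`.
#' @export
simulate_phenotypes <- function(G, h2 = 0.5, n_qtl = 100, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (n_qtl < 1 || n_qtl > ncol(G$values)) {
    stop("n_qtl must lie in [1, ncol(G)]")
  }
  set.seed(seed)
  n <- nrow(G$values)

  col_means <- colMeans(G$values, na.rm = TRUE)
  informative <- which(!is.na(col_means) &
                         apply(G$values, 2, function(v) {
                           v <- v[!is.na(v)]
                           length(v) > 0 && stats::var(v) > 0
                         }))
  if (length(informative) < n_qtl) {
    stop("fewer informative markers than n_qtl")
  }
  qtl <- sort(sample(informative, n_qtl))
  effects <- stats::rnorm(n_qtl)

  W <- G$values[, qtl, drop = FALSE]
  for (j in seq_len(ncol(W))) {
    miss <- is.na(W[, j])
    if (any(miss)) W[miss, j] <- col_means[qtl[j]]
    W[, j] <- W[, j] - mean(W[, j])
  }
  g <- drop(W %*% effects)

  if (h2 == 0) {
    y <- stats::rnorm(n)
  } else if (h2 == 1) {
    y <- g
  } else {
    var_g <- stats::var(g)
    y <- g + stats::rnorm(n, sd = sqrt(var_g * (1 - h2) / h2))
  }
  names(y) <- rownames(G$values)
  list(
    phenotype = y,
    architecture = list(qtl_indices = qtl, qtl_effects = effects,
                        h2 = h2, genetic_values = g)
  )
}

#' Simulate a panel of independent additive traits
#'
#' Calls [simulate_phenotypes()] once per trait with trait-specific seeds
#' derived from `seed`, emulating a multi-trait evaluation (the bean study
#' scores 15 agronomic traits on one cohort). Traits share the genotypes
#' but draw independent causal markers and effects.
#'
#' @param G a [genotype_matrix()].
#' @param n_traits number of traits.
#' @param h2 heritability, recycled across traits.
#' @param n_qtl causal markers per trait.
#' @param seed integer base seed.
#' @return A list with `phenotypes` (accessions x traits matrix, columns
#'   `trait1..traitT`) and `architectures` (list of per-trait
#'   architectures).
#' @export
simulate_trait_panel <- function(G, n_traits = 15, h2 = 0.5,
                                 n_qtl = min(100, ncol(G$values)),
                                 seed = 1) {
  h2 <- rep_len(h2, n_traits)
  res <- lapply(seq_len(n_traits), function(t) {
    seed_t <- as.integer((as.double(seed) * 7919 + t) %% 2147483647)
    simulate_phenotypes(G, h2 = h2[t], n_qtl = n_qtl, seed = seed_t)
  })
  Y <- vapply(res, function(r) r$phenotype, numeric(nrow(G$values)))
  dimnames(Y) <- list(rownames(G$values), paste0("trait", seq_len(n_traits)))
  list(phenotypes = Y, architectures = lapply(res, `[[`, "architecture"))
}

#' Write a cohort to a VCF file and a phenotype/metadata table
#'
#' Writes the genotypes as a minimal VCF 4.2 file (biallelic SNPs, GT-only
#' FORMAT, inbred genotypes `0/0` / `1/1`, missing as `./.`) and the
#' metadata plus any phenotypes as a tab-separated table with header
#' `accession_id pool class trait...`. Reading the VCF back with
#' [read_vcf()] reproduces the genotype matrix exactly, including the
#' missing mask.
#'
#' @param G a [genotype_matrix()].
#' @param metadata data.frame with columns `accession_id`, `pool`, `class`,
#'   rows aligned with `G`.
#' @param phenotypes optional named numeric vector or data.frame of trait
#'   values aligned with `G` (one column per trait).
#' @param vcf_path,pheno_path output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_cohort <- function(G, metadata, phenotypes = NULL,
                         vcf_path, pheno_path) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- accessions(G)
  if (!identical(as.character(metadata$accession_id), ids)) {
    stop("metadata accession ids must match the genotype matrix rows in order")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=structgp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  m <- ncol(G$values)
  lines <- header
  if (m > 0L) {
    gt <- matrix("./.", nrow = m, ncol = length(ids))
    v <- t(G$values)
    gt[!is.na(v) & v == 0] <- "0/0"
    gt[!is.na(v) & v == 1] <- "1/1"
    # fractional dosages (heterozygote-coded data) are not representable in
    # the inbred writer
    if (any(!is.na(v) & v != 0 & v != 1)) {
      stop("write_cohort only writes inbred {0,1} genotypes")
    }
    records <- paste(
      G$map$chrom, G$map$pos, G$map$id, G$map$ref, G$map$alt,
      ".", "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    lines <- c(lines, records)
  }
  writeLines(lines, vcf_path)

  tab <- data.frame(accession_id = ids,
                    pool = metadata$pool, class = metadata$class,
                    stringsAsFactors = FALSE)
  if (!is.null(phenotypes)) {
    ph <- if (is.data.frame(phenotypes)) phenotypes else
      stats::setNames(data.frame(phenotypes), "trait1")
    if (nrow(ph) != length(ids)) stop("phenotype rows must match accessions")
    tab <- cbind(tab, ph)
  }
  utils::write.table(tab, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(vcf = vcf_path, phenotypes = pheno_path))
}

#' Read a phenotype/metadata table written by [write_cohort()]
#'
#' @param path tab-separated file with header
#'   `accession_id pool class trait...`.
#' @return A data.frame; trait columns (if any) are numeric.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("accession_id", "pool", "class")
  if (!all(required %in% names(tab))) {
    stop("phenotype table must have columns accession_id, pool, class")
  }
  tab
}
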