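#' Read a VCF file into a genotype matrix
#'
#' Parses the GT field of a VCF 4.x file (via the vcfR parser) into the
#' inbred-coded [genotype_matrix()] used throughout the package:
#' `0/0 -> 0`, `1/1 -> 1`, `./. -> NA`. The coding reflects fully inbred
#' material, where only the two homozygote classes occur; how heterozygous
#' calls are handled is controlled by `het`:
#' \describe{
#'   \item{`"missing"` (default)}{`0/1` is treated as a missing call, the
#'     conservative choice for selfing species where heterozygotes are
#'     most likely genotyping artifacts.}
#'   \item{`"dosage"`}{genotypes are coded as alt-allele dosage over ploidy,
#'     so `0/1 -> 0.5`; downstream encoding and the mixed model accept this.}
#' }
#' Only biallelic SNP records are usable; others are skipped with a warning
#' or raise an error depending on `multiallelic`.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @param het heterozygote policy, `"missing"` or `"dosage"`.
#' @param multiallelic `"skip"` (drop non-biallelic/non-SNP records with a
#'   warning) or `"error"`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, het = c("missing", "dosage"),
                     multiallelic = c("skip", "error")) {
  het <- match.arg(het)
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_samples <- ncol(vcf@gt) - 1L
  if (is.na(n_samples) || n_samples < 1L) stop("VCF contains no samples")

  if (nrow(fix) == 0L) {
    map <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
    vals <- matrix(numeric(0), nrow = n_samples, ncol = 0)
    return(genotype_matrix(vals, map, colnames(vcf@gt)[-1L]))
  }

  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & !grepl(",", fix$ALT) & nchar(fix$ALT) == 1L
  if (any(!is_snp)) {
    if (multiallelic == "error") {
      stop("VCF contains multiallelic or non-SNP records")
    }
    warning(sum(!is_snp), " multiallelic/non-SNP record(s) skipped")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  gt <- sub("\\|", "/", gt)

  vals <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  vals[gt == "0/0"] <- 0
  vals[gt == "1/1"] <- 1
  if (het == "dosage") {
    vals[gt %in% c("0/1", "1/0")] <- 0.5
  }

  ids <- fix$ID
  if (anyNA(ids) || any(ids == ".")) {
    fill <- is.na(ids) | ids == "."
    ids[fill] <- paste0(fix$CHROM[fill], "_", fix$POS[fill])
  }
  map <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = ids, ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  genotype_matrix(t(vals), map, colnames(gt))
}

#' Filter markers on minor allele frequency and missingness
#'
#' Applies the two marker-quality filters jointly on the input matrix:
#' a marker is retained only if its minor allele frequency (computed from
#' non-missing calls, allele frequency = mean of the 0/1 entries) is
#' strictly greater than `maf_min` and its missing fraction is strictly
#' below `max_missing`. Both thresholds are strict inequalities; the
#' defaults retain markers with MAF > 5% and missingness < 50%. Column
#' order is preserved, and the operation is idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum (exclusive) minor allele frequency.
#' @param max_missing maximum (exclusive) fraction of missing calls.
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report`: counts `n_input`, `n_failed_maf`, `n_failed_missing`,
#'   `n_retained` (a marker can fail both filters; `n_retained` is
#'   `n_input` minus the size of the union of failures).
#' @export
filter_markers <- function(G, maf_min = 0.05, max_missing = 0.50) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$values) == 0L) stop("genotype matrix has zero accessions")
  n_input <- ncol(G$values)
  miss_frac <- colMeans(is.na(G$values))
  freq <- colMeans(G$values, na.rm = TRUE)
  maf <- pmin(freq, 1 - freq)
  # fully-missing markers have undefined MAF; they fail the MAF filter too
  fail_maf <- is.na(maf) | maf <= maf_min
  fail_missing <- miss_frac >= max_missing
  keep <- !(fail_maf | fail_missing)
  report <- list(
    n_input = n_input,
    n_failed_maf = sum(fail_maf),
    n_failed_missing = sum(fail_missing),
    n_retained = sum(keep)
  )
  list(genotypes = G[, which(keep)], report = report)
}

# Largest-remainder apportionment of `target` among categories with counts
# `counts`; quotas sum exactly to `target` and never exceed the counts.
largest_remainder <- function(counts, target) {
  stopifnot(target >= 0, target <= sum(counts))
  exact <- target * counts / sum(counts)
  quota <- floor(exact)
  remainder <- exact - quota
  short <- target - sum(quota)
  if (short > 0) {
    # ties in remainder broken by category order (stable)
    ord <- order(-remainder, seq_along(counts))
    bump <- ord[seq_len(short)]
    quota[bump] <- quota[bump] + 1
  }
  # a quota can exceed its count only when another category is saturated;
  # reassign the excess to categories with slack, largest remainder first
  over <- quota > counts
  while (any(over)) {
    excess <- sum(quota[over] - counts[over])
    quota[over] <- counts[over]
    slack <- which(quota < counts)
    ord <- slack[order(-remainder[slack], slack)]
    for (i in ord) {
      if (excess == 0) break
      add <- min(excess, counts[i] - quota[i])
      quota[i] <- quota[i] + add
      excess <- excess - add
    }
    over <- quota > counts
  }
  as.integer(quota)
}

#' Subsample markers proportionally by chromosome
#'
#' Draws `target_n` markers, apportioning the per-chromosome quotas by the
#' largest-remainder rule applied to the chromosome marker counts (quotas
#' sum exactly to `target_n`), then sampling uniformly without replacement
#' within each chromosome. The retained markers keep their original column
#' order. The quota computation is deterministic; only the within-chromosome
#' draw uses the seed.
#'
#' @param G a [genotype_matrix()].
#' @param target_n number of markers to retain, `0 < target_n <= ncol(G)`.
#' @param seed integer RNG seed.
#' @return A [genotype_matrix()] with `target_n` markers.
#' @export
subsample_markers <- function(G, target_n, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$values)
  if (target_n <= 0 || target_n > m) {
    stop("target_n must lie in (0, number of markers]")
  }
  if (target_n == m) return(G)
  chrom <- factor(G$map$chrom, levels = unique(G$map$chrom))
  counts <- as.integer(table(chrom))
  quota <- largest_remainder(counts, target_n)
  set.seed(seed)
  idx_by_chrom <- split(seq_len(m), chrom)
  chosen <- unlist(mapply(function(idx, q) {
    if (q == 0L) return(integer(0))
    sort(sample(idx, q))
  }, idx_by_chrom, quota, SIMPLIFY = FALSE), use.names = FALSE)
  G[, sort(chosen)]
}

#' Fit a genotype encoder (imputation and centering constants)
#'
#' Computes, from a reference (training) set of accessions, the per-marker
#' non-missing means used both to impute missing calls and to center the
#' columns. Encoding any accessions with the same encoder puts them on the
#' training-set scale, which is what genomic prediction requires: test-set
#' accessions must be imputed and centered with training constants, never
#' their own.
#'
#' @param G a [genotype_matrix()] (typically already filtered).
#' @param rows accession selector (indices or ids) defining the reference
#'   set; default all accessions.
#' @return An object of class `genotype_encoder` holding the marker ids and
#'   centering constants.
#' @export
genotype_encoder <- function(G, rows = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  vals <- G$values
  if (!is.null(rows)) {
    if (is.character(rows)) rows <- match(rows, rownames(vals))
    vals <- vals[rows, , drop = FALSE]
  }
  centers <- colMeans(vals, na.rm = TRUE)
  if (anyNA(centers)) {
    stop("a marker has zero non-missing calls in the reference set; ",
         "filter markers before encoding")
  }
  structure(list(marker_ids = G$map$id, centers = centers),
            class = "genotype_encoder")
}

#' Encode genotypes as a model-ready matrix
#'
#' Replaces missing calls by the encoder's per-marker mean and subtracts
#' that same mean from every column, producing a dense, centered numeric
#' matrix with no missing values — the Z matrix of the mixed model.
#'
#' @param encoder a [genotype_encoder()].
#' @param G a [genotype_matrix()] with the same markers, in the same order.
#' @param rows optional accession selector (indices or ids).
#' @return A numeric matrix, accessions x markers, centered on the encoder's
#'   reference scale.
#' @export
encode_genotypes <- function(encoder, G, rows = NULL) {
  stopifnot(inherits(encoder, "genotype_encoder"),
            inherits(G, "genotype_matrix"))
  if (!identical(encoder$marker_ids, G$map$id)) {
    stop("marker set of G does not match the encoder")
  }
  vals <- G$values
  if (!is.null(rows)) {
    if (is.character(rows)) rows <- match(rows, rownames(vals))
    vals <- vals[rows, , drop = FALSE]
  }
  centers <- encoder$centers
  na_idx <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(na_idx)) vals[na_idx] <- centers[na_idx[, 2L]]
  sweep(vals, 2L, centers, "-")
}
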