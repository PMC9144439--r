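#' Genotype matrix container
#'
#' Bundles an accessions x markers genotype matrix (inbred homozygote coding,
#' values 0/1 with `NA` for missing calls) with its marker map and accession
#' identifiers. This is the object every downstream step (filtering,
#' subsampling, encoding, model fitting, PCA) consumes.
#'
#' @param values numeric matrix, accessions in rows and markers in columns.
#'   Allowed values are 0, 1 and `NA`; with heterozygote dosage coding (see
#'   [read_vcf()]) 0.5 may also appear.
#' @param map data.frame with one row per marker and columns `chrom`, `pos`,
#'   `id`, `ref`, `alt`. Positions must be non-decreasing within chromosome.
#' @param accession_ids character vector of unique accession identifiers,
#'   one per row of `values`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values` (the matrix, with accession ids as rownames and marker ids as
#'   colnames) and `map`.
#' @seealso [read_vcf()], [filter_markers()], [subsample_markers()],
#'   [genotype_encoder()]
#' @export
genotype_matrix <- function(values, map, accession_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(accession_ids)) {
    stop("accession_ids must be supplied or present as rownames(values)")
  }
  accession_ids <- as.character(accession_ids)
  if (length(accession_ids) != nrow(values)) {
    stop("length(accession_ids) must equal nrow(values)")
  }
  if (anyDuplicated(accession_ids)) {
    stop("accession ids must be unique")
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) {
    stop("marker map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(map) != ncol(values)) {
    stop("marker map must have one row per marker column")
  }
  if (nrow(map) > 1L) {
    by_chr <- split(map$pos, factor(map$chrom, levels = unique(map$chrom)))
    if (any(vapply(by_chr, is.unsorted, logical(1)))) {
      stop("marker positions must be non-decreasing within each chromosome")
    }
  }
  rownames(values) <- accession_ids
  colnames(values) <- map$id
  structure(list(values = values, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf(
    "genotype_matrix: %d accessions x %d markers (%d chromosome(s), %.2f%% missing)\n",
    nrow(x$values), ncol(x$values), length(unique(x$map$chrom)),
    100 * nmiss / max(1L, length(x$values))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix
#'
#' Row (accession) and column (marker) subsetting that keeps the marker map
#' in register with the genotype columns.
#'
#' @param x a [genotype_matrix()].
#' @param i accession selector (indices, logical, or accession ids).
#' @param j marker selector (indices, logical, or marker ids).
#' @param ... ignored.
#' @return A `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  vals <- x$values
  map <- x$map
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, map$id)
    vals <- vals[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
    rownames(map) <- NULL
  }
  if (!missing(i)) {
    vals <- vals[i, , drop = FALSE]
  }
  genotype_matrix(vals, map, rownames(vals))
}

#' Accession identifiers of a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @return Character vector of accession ids, in row order.
#' @export
accessions <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  rownames(G$values)
}
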