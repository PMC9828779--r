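#' Genotype dosage matrix
#'
#' Container for biallelic genotype dosages (individuals x sites, coded
#' 0/1/2 with `NA` for missing), with optional per-entry depth and per-site
#' quality summaries as produced by upstream genotype callers.
#'
#' @param dosages Integer matrix, individuals x sites, values in {0,1,2,NA}.
#' @param sample_ids,site_ids Character vectors naming rows and columns.
#' @param depth Optional matrix of per-entry read depths (same shape), or
#'   `NULL`.
#' @param qual Optional numeric vector of per-site genotype-quality summaries
#'   (mean GQ across samples), or `NULL`.
#' @param n_alleles Optional integer vector of allele counts per site (2 for
#'   biallelic); defaults to 2 everywhere.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            site_ids = colnames(dosages), depth = NULL,
                            qual = NULL, n_alleles = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(nrow(dosages)))
  if (is.null(site_ids)) site_ids <- sprintf("site_%d", seq_len(ncol(dosages)))
  if (length(sample_ids) != nrow(dosages) || length(site_ids) != ncol(dosages))
    stop("sample/site id lengths inconsistent with dosage matrix dimensions")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(sample_ids, site_ids)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(dosages)))
      stop("depth matrix dimensions must match dosages")
  }
  if (!is.null(qual) && length(qual) != ncol(dosages))
    stop("qual must have one entry per site")
  if (is.null(n_alleles)) n_alleles <- rep(2L, ncol(dosages))
  structure(list(dosages = dosages, sample_ids = as.character(sample_ids),
                 site_ids = as.character(site_ids), depth = depth,
                 qual = qual, n_alleles = as.integer(n_alleles)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d sites, %.1f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from VCF or a dosage matrix
#'
#' For `format = "vcf"`, genotypes are parsed from the GT field (diploid
#' calls only); per-entry DP and GQ are read when present in FORMAT,
#' otherwise left unset. Dosage is the count of non-reference alleles;
#' missing calls (`./.`) become `NA`. Site and sample order are preserved.
#' For `format = "matrix"`, a CSV with a `specimen_id` column and one column
#' per site is expected.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"matrix"`.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"specimen_id" %in% names(df))
      stop("matrix format requires a specimen_id column")
    m <- as.matrix(df[setdiff(names(df), "specimen_id")])
    return(genotype_matrix(m, sample_ids = df$specimen_id))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")    # sites x samples
  if (is.null(gt) || nrow(gt) == 0L) stop("VCF contains no GT genotypes")
  alleles <- gsub("\\|", "/", gt)
  parts <- strsplit(as.vector(alleles), "/", fixed = TRUE)
  nall <- lengths(parts)
  if (any(!is.na(as.vector(gt)) & nall != 2L))
    stop("non-diploid GT encountered; only diploid calls are supported")
  dos <- vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".")) return(NA_integer_)
    sum(p != "0")
  }, integer(1))
  dos <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  # vcfR returns sites x samples; transpose to individuals x sites
  dosages <- t(dos)
  site_ids <- paste(vcf@fix[, "CHROM"], vcf@fix[, "POS"], sep = ":")
  n_alleles <- 1L + vapply(strsplit(vcf@fix[, "ALT"], ","), function(a)
    sum(!is.na(a) & a != "."), integer(1))
  fmt <- vcf@gt[, 1]
  depth <- NULL
  if (all(grepl("DP", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    depth <- t(dp)
  }
  qual <- NULL
  if (all(grepl("GQ", fmt))) {
    gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
    qual <- rowMeans(gq, na.rm = TRUE)   # per-site mean GQ
  }
  genotype_matrix(dosages, sample_ids = colnames(gt), site_ids = site_ids,
                  depth = depth, qual = qual, n_alleles = n_alleles)
}
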