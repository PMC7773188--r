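#' Parse a reference-free VCF into metavariant records
#'
#' Reads a multi-sample VCF produced by a reference-free variant caller and
#' extracts, for every retained biallelic SNV, the per-sample read counts
#' supporting the two alleles from an `AD`-style `ref,alt` depth field.
#'
#' Records are dropped (with a message giving the counts) when they are
#' multiallelic, when they are not single-nucleotide substitutions, or when
#' their source sequence carries more than one variant — bubbles calling
#' several close SNVs are uninformative for clustering, so only loci
#' producing a single metavariant are kept. Missing per-sample data is
#' encoded as `(0, 0)`.
#'
#' @param path Path to a VCF (v4.x) file with per-sample allele depths.
#' @param dialect `"discosnp"` treats each `CHROM` (one de Bruijn bubble
#'   path per variant) as the locus and drops `CHROM`s with several
#'   records; `"generic_allele_depth"` accepts any VCF carrying an `AD`
#'   FORMAT field and identifies loci as `CHROM_POS`.
#' @return A long tibble with columns `locus_id`, `sample`, `count_a`,
#'   `count_b`, suitable for [filter_loci()]. The number of dropped
#'   records is attached as attribute `"dropped"`.
#' @export
read_metavar_vcf <- function(path, dialect = c("discosnp", "generic_allele_depth")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse VCF '", path, "': ",
                                     conditionMessage(e))))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(structure(
      tibble(locus_id = character(), sample = character(),
             count_a = numeric(), count_b = numeric()),
      dropped = c(multiallelic = 0L, non_snv = 0L, multi_variant_locus = 0L)))
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multiallelic <- grepl(",", alt, fixed = TRUE)
  non_snv <- !multiallelic & (nchar(ref) != 1L | nchar(alt) != 1L |
                                !ref %in% c("A", "C", "G", "T") |
                                !alt %in% c("A", "C", "G", "T"))
  locus <- if (dialect == "discosnp") {
    fix[, "CHROM"]
  } else {
    paste0(fix[, "CHROM"], "_", fix[, "POS"])
  }
  dup <- locus %in% locus[duplicated(locus)]
  multi_locus <- !multiallelic & !non_snv & dup
  keep <- !(multiallelic | non_snv | multi_locus)

  dropped <- c(multiallelic = sum(multiallelic), non_snv = sum(non_snv),
               multi_variant_locus = sum(multi_locus))
  if (any(dropped > 0)) {
    inform(sprintf(
      "dropped %d multiallelic, %d non-SNV and %d multi-variant-locus record(s)",
      dropped[[1]], dropped[[2]], dropped[[3]]))
  }

  ad <- tryCatch(
    vcfR::extract.gt(vcf, element = "AD"),
    error = function(e) abort(paste0(
      "no per-sample AD (allele depth) field in '", path,
      "'; unknown depth encoding for dialect '", dialect, "'")))
  if (is.null(ad)) {
    abort(paste0("no per-sample AD (allele depth) field in '", path, "'"))
  }
  ad <- ad[keep, , drop = FALSE]
  locus <- locus[keep]
  samples <- colnames(ad)

  ad[!is.na(ad) & ad %in% c(".", "")] <- NA  # explicit missing markers
  bad <- !is.na(ad) & !grepl("^[0-9]+,[0-9]+$", ad)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "malformed AD value '%s' at record '%s', sample '%s': expected 'ref,alt'",
      ad[bad][1], locus[i[1]], samples[i[2]]))
  }
  ca <- suppressWarnings(as.numeric(sub(",.*", "", ad)))
  cb <- suppressWarnings(as.numeric(sub(".*,", "", ad)))
  ca[is.na(ca)] <- 0
  cb[is.na(cb)] <- 0

  out <- tibble(
    locus_id = rep(locus, times = length(samples)),
    sample = factor(rep(samples, each = length(locus)), levels = samples),
    count_a = as.vector(ca),
    count_b = as.vector(cb))
  structure(out, dropped = dropped)
}

#' Write a dataset as a toy reference-free VCF
#'
#' Serialises the allele counts of a synthetic dataset (or matrix set) as a
#' minimal VCF v4.2 file in the dialect that [read_metavar_vcf()] parses:
#' one contig (`CHROM = locus_id`) per biallelic SNV, with a per-sample
#' `AD` field holding `count_a,count_b`. Round-tripping through
#' [read_metavar_vcf()] and [filter_loci()] with open filters reproduces
#' the original matrices.
#'
#' @param x An `mvs_sim` dataset or `mvs_matrices` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_toy_vcf <- function(x, path) {
  if (inherits(x, "mvs_sim")) x <- x$matrices
  stopifnot(inherits(x, "mvs_matrices"))
  a <- tibble_to_matrix(x$counts_a)
  b <- tibble_to_matrix(x$counts_b)
  samples <- colnames(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mvspop-toy",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nrow(a) > 0) {
    geno <- matrix(paste0("./.:", a, ",", b), nrow = nrow(a))
    lines <- paste(rownames(a), "1", ".", "A", "C", ".", "PASS", ".", "GT:AD",
                   apply(geno, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
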