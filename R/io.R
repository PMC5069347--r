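# Tabular readers/writers for the pipeline's on-disk formats. All outputs are
# UTF-8 with a header row and NA for missing values.

#' Write / read a genotype matrix as TSV
#'
#' Rows are lines, columns markers, values 0/1/2 or NA; the first column holds
#' the line id.
#'
#' @param G a [genotypes()] object.
#' @param path file path.
#' @export
write_genotypes_tsv <- function(G, path) {
  df <- data.frame(line_id = rownames(G$dosage), G$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param map optional marker map to attach (data.frame or CSV path).
#' @export
read_genotypes_tsv <- function(path, map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (is.character(map)) map <- read_map_csv(map)
  genotypes(m, map)
}

#' Write / read the genetic map as CSV (`marker`, `chrom`, `pos_cM`)
#' @param map map data.frame.
#' @param path file path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(map[, c("marker", "chrom", "pos_cM")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the pedigree as CSV
#' (`id`, `parent1`, `parent2`, `selfing_x`, `cycle`)
#' @param ped pedigree data.frame.
#' @param path file path.
#' @export
write_pedigree_csv <- function(ped, path) {
  utils::write.csv(ped, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character",
                                        parent1 = "character",
                                        parent2 = "character"))
  validate_pedigree(ped)
  ped
}

#' Write / read plot-level phenotype records as long-format CSV
#' @param plots plot records data.frame.
#' @param path file path.
#' @export
write_plots_csv <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_plots_csv
#' @export
read_plots_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a relationship matrix as square TSV
#'
#' Line ids appear as both the header row and the first column; the reader
#' validates symmetry.
#'
#' @param K matrix with dimnames.
#' @param path file path.
#' @param flavor flavor attribute to restore on read.
#' @export
write_kinship_tsv <- function(K, path) {
  df <- data.frame(line_id = rownames(K), K, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path, flavor = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  if (!identical(rownames(K), colnames(K)))
    stop("kinship TSV row and column ids differ")
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix is not symmetric")
  if (!is.null(flavor)) attr(K, "flavor") <- flavor
  K
}

#' Read genotypes from a VCF file
#'
#' Maps diploid GT fields to reference-allele dosage (phasing is ignored;
#' missing GT becomes NA). Requires the optional vcfR package.
#'
#' @param path VCF file path.
#' @param map optional marker map.
#' @return A [genotypes()] object.
#' @export
read_vcf_genotypes <- function(path, map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == "." | al == ""))
        NA_real_ else sum(al != "0")
    }, numeric(1))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                       dimnames = list(rownames(gt), colnames(gt)))
  # dosage convention: counted allele = ALT; rows lines x cols markers
  m <- t(dos)
  colnames(m) <- rownames(gt)
  if (is.character(map)) map <- read_map_csv(map)
  genotypes(m, map)
}

#' Write genotypes as a minimal unphased diploid VCF
#'
#' Emits a well-formed VCFv4.2 file with dosages encoded as unphased GT
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.). Marker positions come from the
#' map when available (cM scaled to integer bp), otherwise the column index.
#'
#' @param G a [genotypes()] object.
#' @param path file path.
#' @export
write_vcf_genotypes <- function(G, path) {
  markers <- colnames(G$dosage)
  if (!is.null(G$map) && all(markers %in% G$map$marker)) {
    mi <- match(markers, G$map$marker)
    chrom <- G$map$chrom[mi]
    pos <- as.integer(round(G$map$pos_cM[mi] * 1e4)) + 1L
  } else {
    chrom <- rep("un", length(markers))
    pos <- seq_along(markers)
  }
  gt_code <- c("0/0", "0/1", "1/1")
  lines_out <- c("##fileformat=VCFv4.2",
                 "##source=ryegp",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(G$dosage)),
                       collapse = "\t"))
  body <- vapply(seq_along(markers), function(j) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    paste(c(chrom[j], pos[j], markers[j], "A", "G", ".", "PASS", ".", "GT",
            gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines_out, body), path, useBytes = TRUE)
  invisible(path)
}
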