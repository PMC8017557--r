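#' Read and write the pipeline's plain-text formats
#'
#' Pedigree, phenotype, marker-map and truth tables are tab-separated with a
#' header row; unknown parents are coded 0.  Genotypes travel as PLINK-RAW
#' additive codes (columns `FID IID PAT MAT SEX PHENOTYPE` then one
#' `<marker>_<allele>` column per marker, values 0/1/2/NA) or as VCF with GT
#' fields.  Positions are 1-based; genomic windows are closed intervals.
#'
#' @name pleioscan-io
NULL

#' @rdname pleioscan-io
#' @param ped `ped_table`
#' @param file path
#' @export
write_pedigree <- function(ped, file) {
  out <- data.frame(animal = ped$animal, sire = ped$sire, dam = ped$dam,
                    birth_year = ped$birth_year,
                    breed_fraction = ped$breed_fraction)
  data.table::fwrite(out, file, sep = "\t")
  invisible(file)
}

#' @rdname pleioscan-io
#' @export
read_pedigree <- function(file) {
  ped <- as.data.frame(data.table::fread(file))
  class(ped) <- c("ped_table", "data.frame")
  ped
}

#' @rdname pleioscan-io
#' @param traits `trait_table`
#' @export
write_phenotypes <- function(traits, file) {
  data.table::fwrite(as.data.frame(traits), file, sep = "\t", na = "NA")
  invisible(file)
}

#' @rdname pleioscan-io
#' @export
read_phenotypes <- function(file) {
  tr <- as.data.frame(data.table::fread(file))
  class(tr) <- c("trait_table", "data.frame")
  tr
}

#' @rdname pleioscan-io
#' @param geno `geno_matrix`
#' @export
write_marker_map <- function(geno, file) {
  data.table::fwrite(geno$map, file, sep = "\t")
  invisible(file)
}

#' @rdname pleioscan-io
#' @export
read_marker_map <- function(file) as.data.frame(data.table::fread(file))

#' @rdname pleioscan-io
#' @param counted_allele allele letter appended to marker names in the
#'   PLINK-RAW header (the allele whose dosage the codes count)
#' @export
write_plink_raw <- function(geno, file, counted_allele = "A") {
  codes <- geno$codes
  out <- data.frame(FID = geno$ids, IID = geno$ids, PAT = 0L, MAT = 0L,
                    SEX = 0L, PHENOTYPE = -9L)
  dose <- as.data.frame(codes)
  names(dose) <- paste0(geno$map$marker, "_", counted_allele)
  data.table::fwrite(cbind(out, dose), file, sep = " ", na = "NA", quote = FALSE)
  invisible(file)
}

#' @rdname pleioscan-io
#' @param map marker map data.frame (`marker`, `chrom`, `bp`) matching the
#'   PLINK-RAW marker columns
#' @export
read_plink_raw <- function(file, map) {
  dt <- data.table::fread(file)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  stopifnot(all(meta %in% names(dt)))
  snpcols <- setdiff(names(dt), meta)
  markers <- sub("_[ACGT0-9]+$", "", snpcols)
  map <- as.data.frame(map)
  if (!all(markers == map$marker))
    stop("PLINK-RAW marker columns do not match the map")
  codes <- as.matrix(dt[, snpcols, with = FALSE])
  storage.mode(codes) <- "integer"
  ids <- as.character(dt$IID)
  dimnames(codes) <- list(ids, map$marker)
  structure(list(codes = codes, map = map, ids = ids), class = "geno_matrix")
}

#' @rdname pleioscan-io
#' @details `write_vcf` emits a minimal VCFv4.2 with unphased GT fields
#'   (REF=A, ALT=B; codes count the ALT allele).  `read_vcf` parses GT
#'   through \pkg{vcfR} and returns ALT-allele dosages.
#' @export
write_vcf <- function(geno, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$ids), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$codes))) {
    g <- geno$codes[, j] + 1L
    calls <- ifelse(is.na(g), "./.", gt[g])
    writeLines(paste(c(geno$map$chrom[j], geno$map$bp[j], geno$map$marker[j],
                       "A", "B", ".", "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(file)
}

#' @rdname pleioscan-io
#' @export
read_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  codes <- matrix(NA_integer_, ncol(gt), nrow(gt))
  clean <- gsub("\\|", "/", gt)
  codes[] <- t(ifelse(clean == "0/0", 0L,
                      ifelse(clean %in% c("0/1", "1/0"), 1L,
                             ifelse(clean == "1/1", 2L, NA_integer_))))
  fix <- vcfR::getFIX(v)
  map <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                    bp = as.integer(fix[, "POS"]))
  ids <- colnames(gt)
  dimnames(codes) <- list(ids, map$marker)
  structure(list(codes = codes, map = map, ids = ids), class = "geno_matrix")
}

#' @rdname pleioscan-io
#' @param state `genetic_state`
#' @param bv_file,qtl_file output paths (the QTL table is only written when
#'   a path is given)
#' @export
write_truth <- function(state, bv_file, qtl_file = NULL) {
  bv <- data.frame(animal = rownames(state$breeding_values),
                   state$breeding_values, check.names = FALSE)
  data.table::fwrite(bv, bv_file, sep = "\t")
  if (!is.null(qtl_file)) data.table::fwrite(state$qtl, qtl_file, sep = "\t")
  invisible(bv_file)
}

#' Read gene annotation as 1-based closed intervals
#'
#' Accepts BED (0-based half-open, converted) or GFF3 (`gene` features kept
#' when a `type` column is present), via \pkg{rtracklayer}.
#'
#' @param file annotation path (`.bed`, `.gff`, `.gff3`)
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`
#' @export
read_annotation <- function(file) {
  gr <- rtracklayer::import(file)
  md <- as.data.frame(gr)
  if ("type" %in% names(md)) {
    keep <- md$type == "gene"
    if (any(keep)) { gr <- gr[keep]; md <- md[keep, , drop = FALSE] }
  }
  gene_id <- if (!is.null(md$gene_id)) md$gene_id
  else if (!is.null(md$ID)) md$ID
  else if (!is.null(md$Name)) md$Name
  else if (!is.null(md$name)) md$name
  else paste0("gene", seq_along(gr))
  data.frame(gene_id = as.character(gene_id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}
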