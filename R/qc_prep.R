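#' Collapse sparse high-end score levels
#'
#' Scores at the dark/coarse/soft extremes are too rare to estimate, so the
#' recording scales are collapsed before analysis: COLOR 8 -> 7, TEXT 6 and
#' 7 -> 5, FIRM 5 -> 4.  All other values are unchanged.
#'
#' @param traits `trait_table` (or plain data.frame) holding COLOR, TEXT,
#'   FIRM on their original scales
#' @return the table with collapsed scores
#' @export
collapse_scores <- function(traits) {
  rules <- list(COLOR = c(max = 8L, to = 7L), TEXT = c(max = 7L, to = 5L),
                FIRM = c(max = 5L, to = 4L))
  for (tr in intersect(names(rules), names(traits))) {
    x <- traits[[tr]]
    bad <- !is.na(x) & (x < 1 | x > rules[[tr]]["max"])
    if (any(bad))
      stop(sprintf("%s scores outside 1-%d", tr, rules[[tr]]["max"]))
    collapse_from <- if (tr == "TEXT") 5 else rules[[tr]]["to"]
    x[!is.na(x) & x > collapse_from] <- rules[[tr]][["to"]]
    traits[[tr]] <- x
  }
  traits
}

#' Average sensory panel scores per steak
#'
#' Each steak is scored by several trained panelists; the analysis input is
#' the arithmetic mean per steak and trait.
#'
#' @param panel data.frame with a `steak` id column, optionally a `panelist`
#'   column, and one column per sensory trait
#' @return data.frame, one row per steak, with per-trait means
#' @export
average_panel_scores <- function(panel) {
  stopifnot("steak" %in% names(panel))
  traits <- setdiff(names(panel), c("steak", "panelist"))
  if (!nrow(panel)) stop("empty panel table")
  out <- stats::aggregate(panel[traits], by = panel["steak"],
                          FUN = mean, na.rm = TRUE)
  out[order(out$steak), , drop = FALSE]
}

#' Per-marker counted-allele frequencies
#'
#' `p_i = mean(code)/2` over non-missing calls at marker *i* — the allele
#' frequencies "of the current population" used to scale G.
#'
#' @param geno `geno_matrix`
#' @return named numeric vector, one frequency per marker
#' @export
allele_frequencies <- function(geno) {
  cm <- colMeans(geno$codes, na.rm = TRUE)
  if (anyNA(cm)) stop("marker(s) with no non-missing calls: ",
                      paste(head(geno$map$marker[is.na(cm)], 5), collapse = ", "))
  stats::setNames(cm / 2, geno$map$marker)
}

#' Marker quality control
#'
#' Removes markers on sex chromosomes (when `autosomes_only`), with minor
#' allele frequency below `maf_min`, or with call rate below `callrate_min`.
#' Survivor order is preserved.
#'
#' @param geno `geno_matrix`
#' @param maf_min minor-allele-frequency threshold (the conventional 1%
#'   default; the literal printed value of the source filter is ambiguous)
#' @param callrate_min minimum fraction of non-missing calls per marker
#' @param autosomes_only drop sex-chromosome/mitochondrial markers?
#' @param sex_chroms chromosome labels treated as non-autosomal
#' @param animal_callrate_min optional per-animal call-rate filter (applied
#'   after the marker filters); `NULL` disables it
#' @return filtered `geno_matrix`
#' @export
filter_markers <- function(geno, maf_min = 0.01, callrate_min = 0.90,
                           autosomes_only = TRUE,
                           sex_chroms = c("X", "Y", "XY", "MT"),
                           animal_callrate_min = NULL) {
  if (maf_min < 0 || maf_min > 1 || callrate_min < 0 || callrate_min > 1)
    stop("thresholds must lie in [0, 1]")
  codes <- geno$codes
  callrate <- colMeans(!is.na(codes))
  p <- colMeans(codes, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  keep <- callrate >= callrate_min & maf >= maf_min
  if (autosomes_only) keep <- keep & !(geno$map$chrom %in% sex_chroms)
  out <- structure(list(codes = codes[, keep, drop = FALSE],
                        map = geno$map[keep, , drop = FALSE], ids = geno$ids),
                   class = "geno_matrix")
  rownames(out$map) <- NULL
  if (!is.null(animal_callrate_min)) {
    ok <- rowMeans(!is.na(out$codes)) >= animal_callrate_min
    out$codes <- out$codes[ok, , drop = FALSE]
    out$ids <- out$ids[ok]
  }
  out
}

#' Mean-impute and center genotype codes
#'
#' Missing codes are replaced by their marker mean `2 p_i`, and every code
#' is centered by `2 p_i`, so imputed entries contribute exactly zero and
#' fully observed columns sum to zero.  The result is the centered incidence
#' matrix Z used throughout the genomic machinery.
#'
#' @param geno `geno_matrix`
#' @param freqs per-marker frequencies; computed from `geno` when omitted
#' @return numeric matrix (animals x markers) with a `"freqs"` attribute
#' @export
center_genotypes <- function(geno, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(geno)
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies outside [0, 1]")
  stopifnot(length(freqs) == ncol(geno$codes))
  Zc <- sweep(geno$codes, 2L, 2 * freqs, `-`)
  Zc[is.na(Zc)] <- 0
  attr(Zc, "freqs") <- freqs
  Zc
}
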