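#' Classify genomic windows by variance share
#'
#' Windows explaining more than `assoc_thr` percent of the direct additive
#' genetic variance are associated with the trait; windows inside
#' `sugg_band` form the suggestive band; the rest are background.
#'
#' @param results `window_result` for one trait, or a list of them (one per
#'   trait, each carrying a `trait` column)
#' @param assoc_thr association threshold, percent (default 1)
#' @param sugg_band lower/upper bounds of the suggestive band (default
#'   0.9-1)
#' @return one data.frame with a `category` column
#'   (`associated`/`suggestive`/`background`)
#' @export
classify_windows <- function(results, assoc_thr = 1, sugg_band = c(0.9, 1)) {
  if (assoc_thr < 0 || any(sugg_band < 0)) stop("thresholds must be non-negative")
  if (is.data.frame(results)) results <- list(results)
  all <- do.call(rbind, lapply(results, as.data.frame))
  all$category <- ifelse(all$pct_var > assoc_thr, "associated",
                         ifelse(all$pct_var >= sugg_band[1] &
                                  all$pct_var <= sugg_band[2],
                                "suggestive", "background"))
  all
}

#' Detect pleiotropic regions from cross-trait window overlaps
#'
#' Overlapping associated windows from two or more traits merge into a
#' pleiotropic region; an associated window overlapping only a
#' suggestive-band window of a *different* trait yields a suggestive
#' region.  Region bounds are the intersection of the windows that define
#' the call (associated members for pleiotropic regions; associated plus
#' band members for suggestive ones); the union is kept alongside.
#'
#' @param classified output of [classify_windows()] covering >= 2 traits
#' @param assoc_thr,sugg_band thresholds used for classification (for the
#'   per-trait pct bookkeeping)
#' @return data.frame of class `pleiotropy_call`: `chrom`, `region_start`,
#'   `region_end`, `union_start`, `union_end`, `status`, `n_traits`,
#'   `traits` (comma-separated `trait:pct`), plus a list column `members`
#'   of the member windows
#' @export
find_pleiotropic_regions <- function(classified, assoc_thr = 1,
                                     sugg_band = c(0.9, 1)) {
  if (length(unique(classified$trait)) < 2)
    stop("pleiotropy detection needs windows from >= 2 traits")
  cand <- classified[classified$category != "background", , drop = FALSE]
  empty <- data.frame(chrom = character(), region_start = numeric(),
                      region_end = numeric(), union_start = numeric(),
                      union_end = numeric(), status = character(),
                      n_traits = integer(), traits = character())
  if (!nrow(cand)) return(structure(empty, class = c("pleiotropy_call", "data.frame")))

  gr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start_bp, cand$end_bp))
  loci <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, loci)
  cand$locus <- NA_integer_
  cand$locus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)

  out <- list()
  for (lc in unique(cand$locus)) {
    mw <- cand[cand$locus == lc, , drop = FALSE]
    assoc_traits <- unique(mw$trait[mw$category == "associated"])
    band_traits <- setdiff(unique(mw$trait[mw$category == "suggestive"]),
                           assoc_traits)
    if (length(assoc_traits) >= 2) {
      status <- "pleiotropic"
      def <- mw[mw$category == "associated", , drop = FALSE]
    } else if (length(assoc_traits) == 1 && length(band_traits) >= 1) {
      status <- "suggestive"
      def <- mw[mw$trait %in% c(assoc_traits, band_traits), , drop = FALSE]
    } else next
    rs <- max(def$start_bp); re <- min(def$end_bp)
    if (rs > re) { rs <- min(def$start_bp); re <- max(def$end_bp) }
    pct <- tapply(mw$pct_var, mw$trait, max)
    pct <- pct[order(-pct)]
    out[[length(out) + 1L]] <- data.frame(
      chrom = mw$chrom[1], region_start = rs, region_end = re,
      union_start = min(mw$start_bp), union_end = max(mw$end_bp),
      status = status, n_traits = length(assoc_traits) + length(band_traits),
      traits = paste(sprintf("%s:%.2f", names(pct), pct), collapse = ","),
      members = I(list(mw[, setdiff(names(mw), "locus")])))
  }
  res <- if (length(out)) do.call(rbind, out) else cbind(empty, members = I(list()))
  structure(res, class = c("pleiotropy_call", "data.frame"))
}

#' Flag candidate genes inside a pleiotropic region
#'
#' Markers inside the region are ranked by their largest standardized
#' absolute effect (|a|/sd(a) per trait) across the member traits; the top
#' 20 are kept (ties at the cut broken by bp order) and a hit is emitted
#' only when a marker's position falls inside a gene span.
#'
#' @param region one row of a `pleiotropy_call`
#' @param effects list of `snp_effects` (with `chrom`/`bp`) for the member
#'   traits
#' @param annotation gene table (`gene_id`, `chrom`, `start`, `end`), e.g.
#'   from [read_annotation()]
#' @param top number of top-ranked markers considered
#' @return data.frame of class `gene_hits`: `gene_id`, `marker`, `bp`,
#'   `rank`, `traits` (trait attaining the marker's top score)
#' @export
flag_candidate_genes <- function(region, effects, annotation, top = 20) {
  chrom <- as.character(region$chrom)
  ann <- annotation[as.character(annotation$chrom) == chrom, , drop = FALSE]
  if (!nrow(ann)) {
    warning("no annotation on chromosome ", chrom, "; region skipped")
    return(NULL)
  }
  if (inherits(effects, "snp_effects")) effects <- list(effects)
  base <- effects[[1]]
  inreg <- base$chrom == chrom & base$bp >= region$region_start &
    base$bp <= region$region_end
  if (!any(inreg)) return(structure(data.frame(), class = c("gene_hits", "data.frame")))
  std <- vapply(effects, function(e) abs(e$effect) / stats::sd(e$effect),
                numeric(nrow(base)))
  std <- as.matrix(std)[inreg, , drop = FALSE]
  score <- apply(std, 1L, max)
  best <- apply(std, 1L, which.max)
  tnames <- vapply(effects, function(e) attr(e, "trait") %||% "trait", "")
  cand <- data.frame(marker = base$marker[inreg], bp = base$bp[inreg],
                     score = score, top_trait = tnames[best])
  cand <- cand[order(-cand$score, cand$bp), , drop = FALSE]
  cand <- utils::head(cand, top)
  cand$rank <- seq_len(nrow(cand))

  mg <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(cand$bp, cand$bp)),
    GenomicRanges::GRanges(chrom, IRanges::IRanges(ann$start, ann$end)))
  hits <- data.frame(
    gene_id = ann$gene_id[S4Vectors::subjectHits(mg)],
    marker = cand$marker[S4Vectors::queryHits(mg)],
    bp = cand$bp[S4Vectors::queryHits(mg)],
    rank = cand$rank[S4Vectors::queryHits(mg)],
    traits = cand$top_trait[S4Vectors::queryHits(mg)])
  structure(hits[order(hits$rank), , drop = FALSE],
            class = c("gene_hits", "data.frame"))
}

#' Full conditional pleiotropy scan
#'
#' Drives the whole pipeline on one dataset: marker QC, variance-component
#' estimation per trait, the iterative weighted single-step scan with all
#' other traits as covariates, 1-Mb window variance shares, cross-trait
#' classification, and (when an annotation is supplied) candidate-gene
#' flagging.
#'
#' @param ped `ped_table`
#' @param geno raw `geno_matrix`; animals flagged genotyped in `ped` (or
#'   all of them, if none are flagged) are used
#' @param traits `trait_table` (scores already collapsed/averaged)
#' @param trait_names traits to scan; default: every trait column
#' @param conditional condition each trait on all the others?
#' @param n_iterations weighting rounds
#' @param scheme window scheme (`"grid"` or `"adjacent"`)
#' @param assoc_thr,sugg_band classification thresholds (percent)
#' @param annotation optional gene table for candidate-gene flagging
#' @param maf_min,callrate_min QC thresholds
#' @param verbose print per-stage progress?
#' @return list of class `pleio_scan`: `vc`, `fits`, `windows`,
#'   `classified`, `regions`, `genes`, `qc`
#' @export
run_pleiotropy_scan <- function(ped, geno, traits, trait_names = NULL,
                                conditional = TRUE, n_iterations = 3,
                                scheme = "grid", assoc_thr = 1,
                                sugg_band = c(0.9, 1), annotation = NULL,
                                maf_min = 0.01, callrate_min = 0.90,
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(trait_names))
    trait_names <- setdiff(names(traits), c("animal", "birth_year", "age",
                                            "sex", "generation", "genotyped"))
  gids <- if ("genotyped" %in% names(ped) && any(ped$genotyped))
    as.character(ped$animal[ped$genotyped]) else geno$ids
  say("QC: ", ncol(geno$codes), " markers in")
  geno_qc <- filter_markers(subset_genotypes(geno, gids),
                            maf_min = maf_min, callrate_min = callrate_min)
  say("QC: ", ncol(geno_qc$codes), " markers retained")
  data <- prepare_ssgblup(ped, geno_qc, traits)

  fits <- list(); vcs <- list(); winlist <- list()
  windows <- make_windows(geno_qc$map, scheme)
  for (tr in trait_names) {
    say("scanning ", tr)
    fits[[tr]] <- run_wssgblup(data, tr, n_iterations = n_iterations,
                               conditional = conditional)
    vcs[[tr]] <- fits[[tr]]$vc
    winlist[[tr]] <- wssg_windows(fits[[tr]], data, windows = windows)
  }
  classified <- classify_windows(winlist, assoc_thr, sugg_band)
  regions <- find_pleiotropic_regions(classified, assoc_thr, sugg_band)
  genes <- NULL
  if (!is.null(annotation) && nrow(regions)) {
    genes <- list()
    for (k in seq_len(nrow(regions))) {
      mtr <- unique(regions$members[[k]]$trait)
      effs <- lapply(fits[mtr], function(f) f$effects[[length(f$effects)]])
      genes[[k]] <- flag_candidate_genes(regions[k, ], effs, annotation)
    }
  }
  structure(list(vc = vcs, fits = fits, windows = winlist,
                 classified = classified, regions = regions, genes = genes,
                 qc = list(n_markers = ncol(geno_qc$codes),
                           n_genotyped = length(gids))),
            class = "pleio_scan")
}

#' @export
print.pleio_scan <- function(x, ...) {
  cat(sprintf("<pleio_scan: %d traits, %d markers, %d genotyped animals>\n",
              length(x$fits), x$qc$n_markers, x$qc$n_genotyped))
  if (nrow(x$regions)) {
    cat("regions:\n")
    print(as.data.frame(x$regions[, c("chrom", "region_start", "region_end",
                                      "status", "traits")]))
  } else cat("no pleiotropic regions called\n")
  invisible(x)
}

#' @rdname pleioscan-io
#' @param regions `pleiotropy_call`
#' @export
write_regions <- function(regions, file) {
  data.table::fwrite(as.data.frame(regions)[, setdiff(names(regions), "members")],
                     file, sep = "\t")
  invisible(file)
}

#' Manhattan-style plot of window variance shares
#'
#' @param windows `window_result` (one trait)
#' @param assoc_thr,sugg_band horizontal reference lines (percent)
#' @param ... passed to [plot()]
#' @export
plot_windows <- function(windows, assoc_thr = 1, sugg_band = c(0.9, 1), ...) {
  chroms <- unique(windows$chrom)
  off <- stats::setNames(cumsum(c(0, vapply(chroms, function(cc)
    max(windows$end_bp[windows$chrom == cc]), 0)))[seq_along(chroms)], chroms)
  x <- off[as.character(windows$chrom)] + (windows$start_bp + windows$end_bp) / 2
  plot(x, windows$pct_var, pch = 16, cex = 0.6,
       col = (match(windows$chrom, chroms) %% 2) + 1,
       xlab = "genome position", ylab = "% additive genetic variance", ...)
  graphics::abline(h = assoc_thr, lty = 4, col = "red")
  graphics::abline(h = sugg_band[1], lty = 3, col = "purple")
  invisible(NULL)
}
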