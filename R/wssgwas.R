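#' Backsolve marker effects from GEBVs
#'
#' Converts the GEBVs of genotyped animals into allele-substitution effects:
#' `a_hat = lambda D Z' Gstar^-1 u_hat`, with `lambda = 1/(2 sum p(1-p))`
#' (the proportionality constant of the GEBV-to-marker map, chosen so that
#' `Z a_hat = u_hat` exactly in the unblended full-rank case), `D` the
#' current marker weights and `Gstar` the (blended) weighted genomic matrix
#' the GEBVs were predicted under.
#'
#' @param u_hat named GEBV vector for the genotyped animals, in `Zc` row
#'   order
#' @param Zc centered genotype matrix of the genotyped animals
#' @param D per-marker weights
#' @param Ginv_star `relmat` of kind `"Ginv"` built by
#'   [blend_and_invert_G()] from the same `Zc` and `D`
#' @param freqs per-marker frequencies (for `lambda`); taken from
#'   `attr(Zc, "freqs")` when omitted
#' @return data.frame of class `snp_effects`: marker, chrom, bp columns when
#'   a map is attached later, plus `effect` and `weight`
#' @export
backsolve_snp_effects <- function(u_hat, Zc, D, Ginv_star, freqs = NULL) {
  if (is.null(freqs)) freqs <- attr(Zc, "freqs")
  m <- ncol(Zc)
  if (length(D) == 1L) D <- rep(D, m)
  stopifnot(length(u_hat) == nrow(Zc), length(D) == m,
            identical(dim(Ginv_star$values), c(nrow(Zc), nrow(Zc))))
  lam <- vanraden_lambda(freqs)
  a <- lam * D * drop(crossprod(Zc, Ginv_star$values %*% u_hat))
  structure(data.frame(marker = colnames(Zc), effect = a, weight = D,
                       row.names = NULL),
            class = c("snp_effects", "data.frame"))
}

#' nonlinearA marker weights
#'
#' `d_i = CT^(|a_i|/sd(a) - 2)` with `CT = 1.05` (departure from normality),
#' capped at `cap` (the maximum change in marker variance), then normalized
#' so the weights sum to the marker count, keeping the additive genetic
#' variance constant.
#'
#' @param effects `snp_effects` (or anything with an `effect` column)
#' @param CT departure-from-normality constant
#' @param cap maximum raw weight before normalization
#' @return numeric weight vector summing to the marker count
#' @export
nonlinear_a_weights <- function(effects, CT = 1.05, cap = 10) {
  a <- effects$effect
  s <- stats::sd(a)
  if (!is.finite(s) || s == 0) {
    warning("all marker effects are zero; weights reset to 1")
    return(rep(1, length(a)))
  }
  d <- CT^(abs(a) / s - 2)
  d <- pmin(d, cap)
  d * length(d) / sum(d)
}

#' Genomic windows over a marker map
#'
#' Two schemes: `"grid"` tiles each chromosome with fixed 1-Mb bins
#' (1-based, closed: 1..1e6, 1e6+1..2e6, ...); `"adjacent"` forms
#' non-overlapping windows of adjacent markers, each spanning at most
#' `size_bp` from its first marker — the span then depends on the marker
#' set under analysis.
#'
#' @param map marker map (`marker`, `chrom`, `bp`), sorted
#' @param scheme `"grid"` or `"adjacent"`
#' @param size_bp window size in bp
#' @return data.frame `chrom`, `start_bp`, `end_bp`, plus a list column
#'   `marker_idx` of marker positions (into `map`) per window
#' @export
make_windows <- function(map, scheme = c("grid", "adjacent"), size_bp = 1e6) {
  scheme <- match.arg(scheme)
  out <- list()
  for (cc in unique(map$chrom)) {
    j <- which(map$chrom == cc)
    bp <- map$bp[j]
    if (scheme == "grid") {
      bin <- (bp - 1) %/% size_bp
      for (b in sort(unique(bin))) {
        sel <- j[bin == b]
        out[[length(out) + 1L]] <- data.frame(
          chrom = cc, start_bp = b * size_bp + 1, end_bp = (b + 1) * size_bp,
          n_markers = length(sel), marker_idx = I(list(sel)))
      }
    } else {
      k <- 1L
      while (k <= length(j)) {
        lo <- bp[k]
        inw <- which(bp >= lo & bp <= lo + size_bp - 1)
        inw <- inw[inw >= k]
        sel <- j[inw]
        out[[length(out) + 1L]] <- data.frame(
          chrom = cc, start_bp = lo, end_bp = bp[max(inw)],
          n_markers = length(sel), marker_idx = I(list(sel)))
        k <- max(inw) + 1L
      }
    }
  }
  do.call(rbind, out)
}

#' Window variance shares
#'
#' For each window, the additive genetic value `w = sum_j Zc_j a_j` over the
#' genotyped individuals is computed from the member markers, and the window
#' is scored as `Var(w)/sigma_u2 * 100`, the percentage of direct additive
#' genetic variance it explains.  `Var` is the population variance (divide
#' by n), matching the variance-share interpretation.
#'
#' @param effects `snp_effects` with one row per column of `Zc`
#' @param Zc centered genotypes of the genotyped animals
#' @param map marker map matching `Zc` columns
#' @param sigma_u2 additive genetic variance of the trait (> 0)
#' @param windows optional precomputed [make_windows()] table
#' @param scheme,size_bp passed to [make_windows()] when `windows` is NULL
#' @return data.frame of class `window_result`: `chrom`, `start_bp`,
#'   `end_bp`, `n_markers`, `pct_var`
#' @export
window_variances <- function(effects, Zc, map, sigma_u2,
                             windows = NULL, scheme = "grid", size_bp = 1e6) {
  stopifnot(sigma_u2 > 0, nrow(effects) == ncol(Zc))
  if (is.null(windows)) windows <- make_windows(map, scheme, size_bp)
  n <- nrow(Zc)
  pct <- vapply(windows$marker_idx, function(sel) {
    if (!length(sel)) return(0)
    w <- Zc[, sel, drop = FALSE] %*% effects$effect[sel]
    v <- sum((w - mean(w))^2) / n
    100 * v / sigma_u2
  }, 0)
  out <- data.frame(chrom = windows$chrom, start_bp = windows$start_bp,
                    end_bp = windows$end_bp, n_markers = windows$n_markers,
                    pct_var = pct)
  class(out) <- c("window_result", "data.frame")
  out
}

#' Prepare the single-step machinery for one dataset
#'
#' Bundles the QC'd genotypes with the pedigree structures the weighted
#' scan reuses across traits and iterations: A^-1, the genotyped block A22
#' and its inverse, centered genotypes and allele frequencies.
#'
#' @param ped `ped_table`
#' @param geno `geno_matrix` holding the genotyped animals only (subset
#'   with [subset_genotypes()] if needed)
#' @param traits `trait_table`
#' @return list of class `ssg_data`
#' @export
prepare_ssgblup <- function(ped, geno, traits) {
  Ainv <- build_Ainv(ped)
  gidx <- match(geno$ids, Ainv$labels)
  if (anyNA(gidx)) stop("genotyped animals missing from the pedigree")
  A22 <- subset_relmat(build_A(ped), gidx)
  A22inv <- relmat(chol2inv(chol(A22$values)), A22$labels, "A22inv")
  Zc <- center_genotypes(geno)
  structure(list(ped = ped, geno = geno, traits = traits, Ainv = Ainv,
                 A22 = A22, A22inv = A22inv, Zc = Zc,
                 freqs = attr(Zc, "freqs"), genotyped_index = gidx),
            class = "ssg_data")
}

#' Iterative weighted single-step GWAS for one trait
#'
#' The weighted ssGBLUP loop: iteration 1 uses identity weights; each
#' iteration builds the weighted blended genomic matrix, assembles H^-1,
#' re-solves the mixed-model equations at the supplied variance components,
#' backsolves marker effects from the genotyped animals' GEBVs and updates
#' the nonlinearA weights for the next round.  Variance components stay
#' fixed at their REML estimates throughout.
#'
#' @param data `ssg_data` from [prepare_ssgblup()]
#' @param target_trait trait to scan
#' @param vc `varcomp` for the trait; estimated on the spot (unconditional
#'   model against H^-1 with identity weights) when omitted
#' @param n_iterations weighting rounds (the scan design uses 3)
#' @param conditional include the other traits as covariates?
#' @param CT,cap nonlinearA parameters
#' @param tau,omega G blending weights
#' @return list of class `wssg_fit`: `effects` (list of `snp_effects` per
#'   iteration, each carrying the marker map), `u_hat`, `vc`, `design`
#' @export
run_wssgblup <- function(data, target_trait, vc = NULL, n_iterations = 3,
                         conditional = FALSE, CT = 1.05, cap = 10,
                         tau = 0.95, omega = 0.05) {
  stopifnot(inherits(data, "ssg_data"), n_iterations >= 1)
  design <- build_design(data$traits, target_trait, conditional = conditional)
  m <- ncol(data$Zc)
  D <- rep(1, m)
  if (is.null(vc)) {
    G0 <- build_G(data$Zc, data$freqs)
    Ginv0 <- blend_and_invert_G(G0, data$A22, tau, omega)
    H0 <- build_Hinv(data$Ainv, data$A22inv, Ginv0, data$genotyped_index)
    vc <- aireml_single(design, H0, tol = 1e-8)
  }
  effects <- vector("list", n_iterations)
  u_hat <- NULL
  for (it in seq_len(n_iterations)) {
    G <- build_G(data$Zc, data$freqs, D)
    Ginv <- blend_and_invert_G(G, data$A22, tau, omega)
    Hinv <- build_Hinv(data$Ainv, data$A22inv, Ginv, data$genotyped_index)
    fit <- solve_mme(design, vc, Hinv)
    u_hat <- fit$u[data$geno$ids]
    eff <- backsolve_snp_effects(u_hat, data$Zc, D, Ginv, data$freqs)
    eff$chrom <- data$geno$map$chrom
    eff$bp <- data$geno$map$bp
    attr(eff, "iteration") <- it
    attr(eff, "trait") <- target_trait
    attr(eff, "sigma_u2") <- vc$sigma_u2
    effects[[it]] <- eff
    if (it < n_iterations) D <- nonlinear_a_weights(eff, CT, cap)
  }
  structure(list(effects = effects, u_hat = u_hat, vc = vc, design = design,
                 trait = target_trait, conditional = conditional),
            class = "wssg_fit")
}

#' Window variance shares from a weighted-scan fit
#'
#' @param fit `wssg_fit`
#' @param data the `ssg_data` it was fitted on
#' @param iteration which weighting round to report (default: the last)
#' @inheritParams window_variances
#' @export
wssg_windows <- function(fit, data, iteration = NULL, windows = NULL,
                         scheme = "grid", size_bp = 1e6) {
  if (is.null(iteration)) iteration <- length(fit$effects)
  eff <- fit$effects[[iteration]]
  out <- window_variances(eff, data$Zc, data$geno$map, fit$vc$sigma_u2,
                          windows = windows, scheme = scheme, size_bp = size_bp)
  out$trait <- fit$trait
  out
}

#' @rdname pleioscan-io
#' @param fit `wssg_fit`
#' @export
write_snp_effects <- function(fit, file) {
  rows <- do.call(rbind, lapply(seq_along(fit$effects), function(it) {
    e <- fit$effects[[it]]
    data.frame(marker = e$marker, chrom = e$chrom, bp = e$bp,
               effect = e$effect, weight = e$weight, iteration = it)
  }))
  data.table::fwrite(rows, file, sep = "\t")
  invisible(file)
}

#' @rdname pleioscan-io
#' @param windows `window_result`
#' @export
write_windows <- function(windows, file) {
  data.table::fwrite(as.data.frame(windows), file, sep = "\t")
  invisible(file)
}
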