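#' Relationship matrices for single-step evaluation
#'
#' A `relmat` is a dense symmetric matrix of relationship coefficients with
#' an ordered vector of animal labels and a `kind` tag (`"A"`, `"Ainv"`,
#' `"A22"`, `"A22inv"`, `"G"`, `"Gblend"`, `"Ginv"`, `"Hinv"`).  All builders
#' below keep animals in pedigree order; genotyped animals are addressed by
#' an index vector into that order, never reordered.
#'
#' @param values symmetric numeric matrix
#' @param labels animal labels, one per row/column
#' @param kind character tag
#' @param F optional vector of inbreeding coefficients
#' @return an object of class `relmat`
#' @export
relmat <- function(values, labels, kind, F = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(labels) == nrow(values))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = as.character(labels), kind = kind, F = F),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat kind=%s, %d animals>\n", x$kind, length(x$labels)))
  invisible(x)
}

#' @export
dim.relmat <- function(x) dim(x$values)

## pedigree sorted + recoded to integer parents (0 = unknown); shared by
## builders below
.ped_recode <- function(ped) {
  ped <- as.data.frame(ped)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns animal, sire, dam")
  n <- nrow(ped)
  if (anyDuplicated(ped$animal)) stop("duplicated animal ids in pedigree")
  idx <- seq_len(n)
  names(idx) <- as.character(ped$animal)
  code <- function(p) {
    p <- as.character(p)
    out <- unname(idx[p])
    out[is.na(out) | p %in% c("0", "NA", "", ".")] <- 0L
    as.integer(out)
  }
  s <- code(ped$sire)
  d <- code(ped$dam)
  if (any(s == seq_len(n) & s > 0) || any(d == seq_len(n) & d > 0))
    stop("animal recorded as its own parent")
  if (any(s > seq_len(n)) || any(d > seq_len(n)))
    stop("pedigree not sorted: parents must precede offspring")
  list(animal = as.character(ped$animal), sire = s, dam = d, n = n)
}

#' Pedigree relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix **A** by the tabular
#' method: `a_ii = 1 + 0.5 a_sd`, `a_ij = 0.5 (a_js + a_jd)`, with unknown
#' parents contributing zero.  Inbreeding coefficients are `F = diag(A) - 1`.
#'
#' @param ped pedigree data.frame with columns `animal`, `sire`, `dam`
#'   (parents must precede offspring; 0/NA = unknown parent)
#' @return `relmat` of kind `"A"` with an `F` component
#' @export
build_A <- function(ped) {
  pr <- .ped_recode(ped)
  n <- pr$n
  A <- matrix(0, n, n)
  s <- pr$sire; d <- pr$dam
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si > 0L) row <- row + 0.5 * A[j, si]
      if (di > 0L) row <- row + 0.5 * A[j, di]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  relmat(A, pr$animal, "A", F = diag(A) - 1)
}

#' Inbreeding coefficients from a pedigree
#'
#' @inheritParams build_A
#' @return named numeric vector of F, one per animal
#' @export
inbreeding <- function(ped) {
  A <- build_A(ped)
  stats::setNames(A$F, A$labels)
}

#' Inverse pedigree relationship matrix with inbreeding
#'
#' Henderson's rules with Meuwissen-Luo accounting for parental inbreeding:
#' each animal contributes `alpha = 1/d` at \{(i,i): alpha, (i,parent):
#' -alpha/2, (parent,parent'): alpha/4\}, where the Mendelian-sampling
#' variance is `d = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, and 1 with none.
#'
#' @inheritParams build_A
#' @return `relmat` of kind `"Ainv"` with an `F` component
#' @export
build_Ainv <- function(ped) {
  pr <- .ped_recode(ped)
  n <- pr$n
  Fv <- inbreeding(ped)
  s <- pr$sire; d <- pr$dam
  Ai <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    dd <- if (si > 0L && di > 0L) 0.5 - 0.25 * (Fv[si] + Fv[di])
          else if (si > 0L)       0.75 - 0.25 * Fv[si]
          else if (di > 0L)       0.75 - 0.25 * Fv[di]
          else                    1
    a <- 1 / dd
    Ai[i, i] <- Ai[i, i] + a
    for (p in c(si, di)) if (p > 0L) {
      Ai[i, p] <- Ai[i, p] - a / 2
      Ai[p, i] <- Ai[p, i] - a / 2
    }
    pp <- c(si, di); pp <- pp[pp > 0L]
    for (p1 in pp) for (p2 in pp) Ai[p1, p2] <- Ai[p1, p2] + a / 4
  }
  relmat(Ai, pr$animal, "Ainv", F = unname(Fv))
}

#' Genomic relationship matrix
#'
#' `G = Z D Z' / (2 sum p_i (1 - p_i))` with `Z` the column-centered genotype
#' matrix, `p_i` the counted-allele frequencies, and `D` optional positive
#' per-marker weights (identity gives the unweighted matrix).
#'
#' @param Zc centered genotype matrix (animals x markers), as returned by
#'   [center_genotypes()]
#' @param freqs per-marker counted-allele frequencies in (0, 1)
#' @param D per-marker weights (default 1), recycled to the marker count
#' @return `relmat` of kind `"G"`
#' @export
build_G <- function(Zc, freqs, D = NULL) {
  Zc <- as.matrix(Zc)
  m <- ncol(Zc)
  stopifnot(length(freqs) == m)
  if (is.null(D)) D <- rep(1, m)
  if (length(D) == 1L) D <- rep(D, m)
  stopifnot(length(D) == m, all(D > 0))
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all markers fixed: scaling parameter 2*sum(p(1-p)) is zero")
  G <- tcrossprod(sweep(Zc, 2L, D, `*`), Zc) / denom
  labs <- rownames(Zc)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(Zc)))
  relmat(G, labs, "G")
}

#' VanRaden scaling parameter
#'
#' `lambda = 1 / (2 sum p_i (1 - p_i))`, the constant relating marker
#' (co)variances to the additive genetic variance.
#'
#' @inheritParams build_G
#' @return scalar
#' @export
vanraden_lambda <- function(freqs) {
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all markers fixed")
  1 / denom
}

#' Blend G with A22 and invert
#'
#' Returns `(tau G + omega A22)^-1`; the default 0.95/0.05 blend guards
#' against a singular genomic matrix.
#'
#' @param G `relmat` of kind `"G"` (or `"Gblend"`)
#' @param A22 `relmat` for the same animals in the same order
#' @param tau,omega blending weights
#' @return `relmat` of kind `"Ginv"`; the blended (uninverted) matrix is kept
#'   in attribute `"blend"`
#' @export
blend_and_invert_G <- function(G, A22, tau = 0.95, omega = 0.05) {
  stopifnot(inherits(G, "relmat"))
  Gm <- G$values
  Bm <- if (omega == 0) Gm else {
    stopifnot(inherits(A22, "relmat"), identical(dim(A22$values), dim(Gm)))
    tau * Gm + omega * A22$values
  }
  ch <- tryCatch(chol(Bm), error = function(e)
    stop("blended genomic matrix is numerically singular"))
  out <- relmat(chol2inv(ch), G$labels, "Ginv")
  attr(out, "blend") <- Bm
  attr(out, "logdet") <- 2 * sum(log(diag(ch)))
  out
}

#' Inverse joint pedigree-genomic relationship matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, the genomic correction added into
#' the block of genotyped animals; all other entries equal `A^-1` exactly.
#'
#' @param Ainv `relmat` of kind `"Ainv"` over all animals
#' @param A22inv `relmat`: inverse of the genotyped sub-block of A
#' @param Ginv `relmat`: (blended) inverse genomic relationship matrix
#' @param genotyped_index positions of the genotyped animals within
#'   `Ainv$labels`, in the row order of `Ginv`
#' @return `relmat` of kind `"Hinv"`
#' @export
build_Hinv <- function(Ainv, A22inv, Ginv, genotyped_index) {
  stopifnot(inherits(Ainv, "relmat"))
  n <- nrow(Ainv$values)
  gi <- as.integer(genotyped_index)
  if (length(gi) && (min(gi) < 1L || max(gi) > n)) stop("genotyped_index out of range")
  H <- Ainv$values
  if (length(gi)) {
    q <- length(gi)
    if (!identical(dim(Ginv$values), c(q, q)) || !identical(dim(A22inv$values), c(q, q)))
      stop("dimension mismatch between Ginv/A22inv and genotyped_index")
    H[gi, gi] <- H[gi, gi] + (Ginv$values - A22inv$values)
  }
  relmat(H, Ainv$labels, "Hinv", F = Ainv$F)
}

#' Sub-block of a relationship matrix
#'
#' Extracts (and optionally inverts) the sub-matrix for a set of animals,
#' e.g. `A22` and `A22inv` for the genotyped subset.
#'
#' @param rm `relmat`
#' @param index positions of the animals to keep
#' @param invert invert the extracted block?
#' @export
subset_relmat <- function(rm, index, invert = FALSE) {
  stopifnot(inherits(rm, "relmat"))
  M <- rm$values[index, index, drop = FALSE]
  kind <- if (rm$kind == "A") "A22" else rm$kind
  if (invert) {
    M <- chol2inv(chol(M))
    kind <- paste0(kind, "inv")
  }
  relmat(M, rm$labels[index], kind)
}

#' Write a relationship matrix as whitespace-separated text
#'
#' @param rm `relmat`
#' @param file output path; first row holds the animal labels
#' @export
write_relmat <- function(rm, file) {
  stopifnot(inherits(rm, "relmat"))
  dt <- data.table::as.data.table(rm$values)
  data.table::setnames(dt, rm$labels)
  data.table::fwrite(dt, file, sep = "\t")
  invisible(file)
}
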