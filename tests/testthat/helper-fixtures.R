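# shared fixtures and independent oracles, built in code

# founders-only pedigree
founder_ped <- function(n) {
  data.frame(animal = seq_len(n), sire = 0L, dam = 0L, birth_year = 2000L)
}

# two founders, their two offspring (full sibs), one inbred offspring of the sibs
fullsib_ped <- function() {
  data.frame(animal = 1:5,
             sire = c(0L, 0L, 1L, 1L, 3L),
             dam  = c(0L, 0L, 2L, 2L, 4L),
             birth_year = c(2000L, 2000L, 2001L, 2001L, 2002L))
}

# a small random but valid pedigree (parents precede offspring)
random_ped <- function(n, n_founders = 4, seed = 1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    pars <- sample(seq_len(i - 1), 2)
    sire[i] <- pars[1]; dam[i] <- pars[2]
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam, birth_year = 2000L)
}

# geno_matrix from a raw code matrix
as_geno <- function(codes, chrom = NULL, bp = NULL) {
  n <- nrow(codes); m <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq(1e5, by = 1e6, length.out = m)
  map <- data.frame(marker = sprintf("M%03d", seq_len(m)), chrom = chrom, bp = bp)
  rownames(codes) <- as.character(seq_len(n))
  colnames(codes) <- map$marker
  structure(list(codes = codes, map = map, ids = rownames(codes)),
            class = "geno_matrix")
}

# Monte-Carlo kinship by dropping labelled founder alleles down the pedigree
gene_drop_kinship <- function(ped, nrep = 1e5, seed = 99) {
  set.seed(seed)
  n <- nrow(ped)
  A1 <- matrix(0L, nrep, n); A2 <- matrix(0L, nrep, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    A1[, i] <- if (s > 0) ifelse(stats::rbinom(nrep, 1, 0.5) == 1, A1[, s], A2[, s])
               else 2L * i - 1L
    A2[, i] <- if (d > 0) ifelse(stats::rbinom(nrep, 1, 0.5) == 1, A1[, d], A2[, d])
               else 2L * i
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    f <- (mean(A1[, i] == A1[, j]) + mean(A1[, i] == A2[, j]) +
            mean(A2[, i] == A1[, j]) + mean(A2[, i] == A2[, j])) / 4
    if (i == j) A[i, i] <- 1 + mean(A1[, i] == A2[, i])
    else A[i, j] <- A[j, i] <- 2 * f
  }
  A
}

# brute-force Mendelian consistency of additive codes: the offspring code
# must be attainable from some pair of parental gametes
mendel_violations <- function(geno, ped) {
  bad <- 0L
  gam <- list(`0` = 0L, `1` = 0:1, `2` = 1L)   # gametes producible per code
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0 || d == 0) next
    for (j in seq_len(ncol(geno$codes))) {
      ok <- outer(gam[[as.character(geno$codes[s, j])]],
                  gam[[as.character(geno$codes[d, j])]], `+`)
      if (!(geno$codes[i, j] %in% ok)) bad <- bad + 1L
    }
  }
  bad
}
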