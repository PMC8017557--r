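## one top-level seed, deterministically split per stage
.split_seed <- function(seed, key) {
  as.integer(((seed %% 2147483647) * 48271 + key * 16807) %% 2147483647)
}

#' Default trait names of the meat-quality panel
#' @export
meat_quality_traits <- function() {
  c("MARB", "REA", "TEND", "JUIC", "FLAV", "COLOR", "TEXT", "FIRM")
}

#' Traits whose models carry the age-at-slaughter covariate
#' @export
age_adjusted_traits <- function() {
  setdiff(meat_quality_traits(), c("TEND", "FLAV"))
}

#' Simulate a multibreed pedigree
#'
#' Founders (unknown parents) are created in the first year of `year_span`
#' with Brahman fractions spanning \[0, 1\] including both purebred
#' endpoints.  Each later generation mates animals of the previous
#' generation only (so parent-offspring matings cannot occur): sexes are
#' balanced, `floor(n/2)` random pairs are formed and each pair produces
#' `offspring_per_mating` offspring whose breed fraction is the parental
#' mean.  Birth years step evenly through `year_span` by generation.
#'
#' @param n_founders number of founders (>= 2)
#' @param n_generations number of descendant generations (>= 1)
#' @param offspring_per_mating offspring per mating pair
#' @param year_span two integers, first and last birth year
#' @param seed integer seed
#' @param genotyped_rate fraction of animals flagged genotyped (the study
#'   design genotyped roughly 44% of the herd)
#' @return data.frame of class `ped_table` with columns `animal`, `sire`,
#'   `dam`, `birth_year`, `breed_fraction`, `sex`, `generation`, `genotyped`
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              offspring_per_mating = 2,
                              year_span = c(1989, 2018), seed = 1,
                              genotyped_rate = 0.44) {
  if (n_founders < 2 || n_generations < 1 || offspring_per_mating < 1)
    stop("n_founders >= 2, n_generations >= 1, offspring_per_mating >= 1 required")
  set.seed(.split_seed(seed, 1))
  years <- round(seq(year_span[1], year_span[2], length.out = n_generations + 1))

  bf <- stats::runif(n_founders)
  pure <- stats::runif(n_founders) < 0.15
  bf[pure] <- round(bf[pure])
  bf[1] <- 0; bf[2] <- 1   # both purebred endpoints always present
  sex <- sample(rep_len(c("M", "F"), n_founders))
  ped <- data.frame(animal = seq_len(n_founders), sire = 0L, dam = 0L,
                    birth_year = years[1], breed_fraction = bf,
                    sex = sex, generation = 0L)

  nid <- n_founders
  for (g in seq_len(n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    sires <- sample(prev$animal[prev$sex == "M"])
    dams  <- sample(prev$animal[prev$sex == "F"])
    nmat <- min(length(sires), length(dams))
    if (nmat == 0L) stop("generation died out: no mating pairs available")
    noff <- nmat * offspring_per_mating
    off_sire <- rep(sires[seq_len(nmat)], each = offspring_per_mating)
    off_dam  <- rep(dams[seq_len(nmat)],  each = offspring_per_mating)
    kid_bf <- (ped$breed_fraction[off_sire] + ped$breed_fraction[off_dam]) / 2
    ped <- rbind(ped, data.frame(
      animal = nid + seq_len(noff), sire = off_sire, dam = off_dam,
      birth_year = years[g + 1], breed_fraction = kid_bf,
      sex = sample(rep_len(c("M", "F"), noff)), generation = g))
    nid <- nid + noff
  }
  ped$genotyped <- stats::runif(nrow(ped)) < genotyped_rate
  class(ped) <- c("ped_table", "data.frame")
  ped
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn per marker with counted-allele frequencies
#' uniform on `founder_maf_range`; descendants receive recombinant parental
#' gametes.  Recombination between adjacent markers follows a Haldane map at
#' 1 cM/Mb (`r = 0.5 (1 - exp(-2d))`, `d` in Morgans from the bp distance);
#' chromosomes assort independently.
#'
#' @param ped `ped_table` (parents before offspring)
#' @param n_markers total marker count, split evenly across chromosomes
#' @param n_chromosomes number of autosomes
#' @param founder_maf_range interval for founder allele frequencies
#' @param seed integer seed
#' @param chrom_length_bp chromosome length in bp (positions drawn uniformly)
#' @param map optional pre-built marker map (data.frame marker/chrom/bp,
#'   sorted); overrides `n_markers`/`n_chromosomes`/`chrom_length_bp`
#' @return object of class `geno_matrix`: list with `codes` (animals x
#'   markers, 0/1/2), `map` (marker, chrom, bp) and `ids`
#' @export
simulate_genotypes <- function(ped, n_markers, n_chromosomes = 10,
                               founder_maf_range = c(0.05, 0.5), seed = 1,
                               chrom_length_bp = 1e8, map = NULL) {
  if (nrow(ped) == 0L) stop("empty pedigree")
  set.seed(.split_seed(seed, 2))
  if (is.null(map)) {
    per <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
    map <- do.call(rbind, lapply(seq_len(n_chromosomes), function(cc) {
      data.frame(chrom = as.character(cc),
                 bp = sort(sample.int(chrom_length_bp, per[cc])))
    }))
    map <- data.frame(marker = sprintf("M%05d", seq_len(nrow(map))),
                      chrom = map$chrom, bp = map$bp)
  } else {
    map <- as.data.frame(map)
    ord <- order(map$chrom, map$bp)
    if (!identical(ord, seq_len(nrow(map)))) stop("marker map must be sorted by (chrom, bp)")
  }
  m <- nrow(map)
  n <- nrow(ped)
  pr <- .ped_recode(ped)

  p <- stats::runif(m, founder_maf_range[1], founder_maf_range[2])
  ## per-interval recombination fractions; 0.5 at each chromosome start
  d <- c(0, diff(map$bp)) * 1e-8            # Morgans, 1 cM/Mb
  r <- 0.5 * (1 - exp(-2 * d))
  newchrom <- c(TRUE, map$chrom[-1] != map$chrom[-m])
  r[newchrom] <- 0.5

  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  gamete <- function(pa) {
    sw <- stats::rbinom(m, 1L, r)
    hap <- cumsum(sw) %% 2L                  # 0/1 choice along the genome
    ifelse(hap == 0L, H1[pa, ], H2[pa, ])
  }
  for (i in seq_len(n)) {
    si <- pr$sire[i]; di <- pr$dam[i]
    H1[i, ] <- if (si > 0L) gamete(si) else stats::rbinom(m, 1L, p)
    H2[i, ] <- if (di > 0L) gamete(di) else stats::rbinom(m, 1L, p)
  }
  codes <- H1 + H2
  rownames(codes) <- pr$animal
  colnames(codes) <- map$marker
  structure(list(codes = codes, map = map, ids = pr$animal),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix %d animals x %d markers, %d chromosome(s)>\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  invisible(x)
}

#' Subset a genotype matrix by animal id
#' @param geno `geno_matrix`
#' @param ids animal ids to keep (in the given order)
#' @export
subset_genotypes <- function(geno, ids) {
  ids <- as.character(ids)
  stopifnot(all(ids %in% geno$ids))
  structure(list(codes = geno$codes[ids, , drop = FALSE], map = geno$map, ids = ids),
            class = "geno_matrix")
}

.check_cov <- function(M, name) {
  M <- as.matrix(M)
  if (!isSymmetric(unname(M), tol = 1e-8)) stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, sum(abs(diag(M)))))
    stop(name, " is not positive semi-definite")
  M
}

## symmetric PSD square root (tolerates singular covariance)
.cov_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate correlated traits down a pedigree
#'
#' Breeding values follow the animal model: founders are multivariate normal
#' with covariance `T_true`; a non-founder is the parental mean plus a
#' Mendelian-sampling deviation with covariance `T_true * d`, where
#' `d = 0.5 - 0.25 (F_s + F_d)` (adjusted when a parent is unknown) uses the
#' parental inbreeding coefficients.  Phenotypes add a year-of-birth class
#' effect, an age-at-slaughter covariate, and a residual with covariance
#' `R_true`.
#'
#' @param ped `ped_table`
#' @param T_true additive genetic (co)variance matrix (traits x traits)
#' @param R_true residual (co)variance matrix, same dimension
#' @param year_effects optional matrix (years x traits, rownames = years) of
#'   class effects; by default drawn N(0, (0.3 sd_P)^2) per year and trait
#' @param age_slope per-trait regression on age at slaughter (days); default 0
#' @param seed integer seed
#' @param trait_names trait labels; defaults to the meat-quality panel when
#'   8 traits are simulated
#' @param age_mean,age_sd age-at-slaughter distribution (days)
#' @param missing_rate per-trait probability a record is missing
#' @return list with `traits` (a `trait_table` data.frame: animal,
#'   birth_year, age, one column per trait) and `state` (a `genetic_state`:
#'   breeding values, QTL table, `T_true`, `R_true`)
#' @export
simulate_traits <- function(ped, T_true, R_true, year_effects = NULL,
                            age_slope = NULL, seed = 1, trait_names = NULL,
                            age_mean = 550, age_sd = 60, missing_rate = 0) {
  T_true <- .check_cov(T_true, "T_true")
  R_true <- .check_cov(R_true, "R_true")
  nt <- nrow(T_true)
  stopifnot(identical(dim(T_true), dim(R_true)))
  if (is.null(trait_names))
    trait_names <- if (nt == 8) meat_quality_traits() else paste0("T", seq_len(nt))
  dimnames(T_true) <- dimnames(R_true) <- list(trait_names, trait_names)
  if (is.null(age_slope)) age_slope <- rep(0, nt)
  if (length(age_slope) == 1L) age_slope <- rep(age_slope, nt)
  missing_rate <- rep_len(missing_rate, nt)

  set.seed(.split_seed(seed, 3))
  n <- nrow(ped)
  pr <- .ped_recode(ped)
  Fv <- inbreeding(ped)
  Lt <- .cov_sqrt(T_true)

  u <- matrix(0, n, nt)
  zs <- matrix(stats::rnorm(n * nt), n, nt) %*% t(Lt)   # pre-scaled deviations
  for (i in seq_len(n)) {
    si <- pr$sire[i]; di <- pr$dam[i]
    pm <- numeric(nt); dscl <- 1
    if (si > 0L && di > 0L) {
      pm <- (u[si, ] + u[di, ]) / 2
      dscl <- 0.5 - 0.25 * (Fv[si] + Fv[di])
    } else if (si > 0L) {
      pm <- u[si, ] / 2; dscl <- 0.75 - 0.25 * Fv[si]
    } else if (di > 0L) {
      pm <- u[di, ] / 2; dscl <- 0.75 - 0.25 * Fv[di]
    }
    u[i, ] <- pm + sqrt(dscl) * zs[i, ]
  }
  rownames(u) <- pr$animal
  colnames(u) <- trait_names

  years <- sort(unique(ped$birth_year))
  if (is.null(year_effects)) {
    sdP <- sqrt(diag(T_true) + diag(R_true))
    year_effects <- matrix(stats::rnorm(length(years) * nt, 0, rep(0.3 * sdP, each = length(years))),
                           length(years), nt, dimnames = list(years, trait_names))
  }
  age <- round(stats::rnorm(n, age_mean, age_sd))
  e <- matrix(stats::rnorm(n * nt), n, nt) %*% t(.cov_sqrt(R_true))
  y <- year_effects[as.character(ped$birth_year), , drop = FALSE] +
    outer(age, age_slope) + u + e
  for (k in seq_len(nt)) if (missing_rate[k] > 0)
    y[stats::runif(n) < missing_rate[k], k] <- NA

  traits <- data.frame(animal = ped$animal, birth_year = ped$birth_year, age = age)
  traits[trait_names] <- as.data.frame(y)
  class(traits) <- c("trait_table", "data.frame")
  state <- structure(list(breeding_values = u,
                          qtl = data.frame(marker = character(), trait = character(),
                                           effect = numeric()),
                          T_true = T_true, R_true = R_true,
                          trait_names = trait_names,
                          year_effects = year_effects, age_slope = age_slope),
                     class = "genetic_state")
  list(traits = traits, state = state)
}

#' Plant a QTL into simulated breeding values
#'
#' Picks the most variable marker inside a genomic window and assigns it an
#' allele-substitution effect sized so the population variance of its
#' genotypic values equals `target_pct`% of the trait's additive variance;
#' the polygenic part is rescaled so total additive variance is unchanged.
#' Phenotypes are not touched; apply [update_phenotypes()] to carry the new
#' breeding values into an existing `trait_table`.
#'
#' @param geno `geno_matrix` covering the same animals as `state` (all
#'   pedigree animals, in order)
#' @param window list or vector with `chrom`, `start`, `end` (1-based,
#'   closed)
#' @param target_pct percentage of additive genetic variance, in (0, 100)
#' @param traits trait names receiving the effect
#' @param state `genetic_state` from [simulate_traits()]
#' @param seed integer seed (effect sign)
#' @return updated `genetic_state`
#' @export
plant_qtl <- function(geno, window, target_pct, traits, state, seed = 1) {
  if (target_pct <= 0 || target_pct >= 100) stop("target_pct must be in (0, 100)")
  stopifnot(all(traits %in% state$trait_names))
  idx <- which(geno$map$chrom == as.character(window$chrom) &
                 geno$map$bp >= window$start & geno$map$bp <= window$end)
  if (!length(idx)) stop("window contains no markers")
  if (!identical(rownames(state$breeding_values), geno$ids))
    stop("genotypes and genetic state cover different animals")
  set.seed(.split_seed(seed, 4))
  n <- nrow(geno$codes)
  vj <- apply(geno$codes[, idx, drop = FALSE], 2L, function(z) mean(z^2) - mean(z)^2)
  j <- idx[which.max(vj)]
  vq <- max(vj)
  if (vq <= 0) stop("no segregating marker in window")
  z <- geno$codes[, j] - mean(geno$codes[, j])
  t <- target_pct / 100
  for (tr in traits) {
    su2 <- state$T_true[tr, tr]
    a <- sample(c(-1, 1), 1) * sqrt(t * su2 / vq)
    state$breeding_values[, tr] <- sqrt(1 - t) * state$breeding_values[, tr] + z * a
    state$qtl <- rbind(state$qtl,
                       data.frame(marker = geno$map$marker[j], trait = tr, effect = a))
  }
  state
}

#' Propagate updated breeding values into phenotypes
#'
#' Replaces the additive genetic part of each phenotype, keeping year, age
#' and residual parts (and the missingness pattern) fixed: a null change of
#' breeding values leaves phenotypes bit-identical.
#'
#' @param traits `trait_table` produced together with `state_old`
#' @param state_old,state_new `genetic_state` before/after [plant_qtl()]
#' @export
update_phenotypes <- function(traits, state_old, state_new) {
  for (tr in state_old$trait_names) {
    delta <- state_new$breeding_values[, tr] - state_old$breeding_values[, tr]
    traits[[tr]] <- traits[[tr]] + delta
  }
  traits
}

#' Discretize liabilities to the recorded ordinal scales
#'
#' Rounds and clamps the score-scale traits to their pre-collapse recording
#' scales (MARB 100-999, COLOR 1-8, TEXT 1-7, FIRM 1-5).  Only cosmetic for
#' fixtures: the analyses treat scores as continuous.
#'
#' @param traits `trait_table`
#' @export
discretize_scores <- function(traits) {
  scales <- list(MARB = c(100, 999), COLOR = c(1, 8), TEXT = c(1, 7),
                 FIRM = c(1, 5), TEND = c(1, 8), JUIC = c(1, 8), FLAV = c(1, 8))
  for (tr in intersect(names(scales), names(traits))) {
    s <- scales[[tr]]
    traits[[tr]] <- pmin(pmax(round(traits[[tr]]), s[1]), s[2])
  }
  traits
}

#' Simulate a complete multibreed dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()], [simulate_genotypes()]
#' and [simulate_traits()], optionally planting QTL windows with known
#' variance shares.  All randomness derives from the one `seed`.
#'
#' @inheritParams simulate_pedigree
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_traits
#' @param qtl optional list of QTL specs, each a list with `window` (chrom,
#'   start, end), `target_pct`, `traits`
#' @return list with `ped`, `geno`, `traits`, `state`
#' @export
simulate_dataset <- function(seed = 1, n_founders = 100, n_generations = 4,
                             offspring_per_mating = 2, year_span = c(1989, 2018),
                             n_markers = 2000, n_chromosomes = 10,
                             chrom_length_bp = 1e8,
                             founder_maf_range = c(0.05, 0.5),
                             T_true, R_true, age_slope = NULL,
                             trait_names = NULL, genotyped_rate = 0.44,
                             missing_rate = 0, qtl = NULL) {
  ped <- simulate_pedigree(n_founders, n_generations, offspring_per_mating,
                           year_span, seed = .split_seed(seed, 11),
                           genotyped_rate = genotyped_rate)
  geno <- simulate_genotypes(ped, n_markers, n_chromosomes, founder_maf_range,
                             seed = .split_seed(seed, 12),
                             chrom_length_bp = chrom_length_bp)
  sim <- simulate_traits(ped, T_true, R_true, seed = .split_seed(seed, 13),
                         age_slope = age_slope, trait_names = trait_names,
                         missing_rate = missing_rate)
  if (!is.null(qtl)) {
    state0 <- sim$state
    state <- state0
    for (k in seq_along(qtl))
      state <- plant_qtl(geno, qtl[[k]]$window, qtl[[k]]$target_pct,
                         qtl[[k]]$traits, state, seed = .split_seed(seed, 20 + k))
    sim$traits <- update_phenotypes(sim$traits, state0, state)
    sim$state <- state
  }
  list(ped = ped, geno = geno, traits = sim$traits, state = sim$state)
}
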