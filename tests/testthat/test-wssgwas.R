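# small all-genotyped dataset the scan tests share
scan_fixture <- function(seed = 1, n_founders = 60, n_markers = 120,
                         qtl_pct = NULL, n_traits = 1) {
  ped <- simulate_pedigree(n_founders, 2, 2, seed = seed, genotyped_rate = 1)
  geno <- simulate_genotypes(ped, n_markers, 4, seed = seed + 1,
                             chrom_length_bp = 3e7)
  sim <- simulate_traits(ped, diag(n_traits), diag(n_traits) * 1.5,
                         seed = seed + 2)
  if (!is.null(qtl_pct)) {
    st <- plant_qtl(geno, list(chrom = "2", start = 1, end = 3e7), qtl_pct,
                    colnames(sim$state$breeding_values), sim$state,
                    seed = seed + 3)
    sim$traits <- update_phenotypes(sim$traits, sim$state, st)
    sim$state <- st
  }
  list(ped = ped, geno = geno, traits = sim$traits, state = sim$state)
}

test_that("backsolving reproduces GEBVs exactly in the unblended full-rank case", {
  set.seed(31)
  codes <- matrix(rbinom(4 * 6, 2, 0.5), 4, 6)
  geno <- as_geno(codes)
  # center at reference frequencies (not the sample's own, which would make
  # the all-ones vector a null vector of G and Gstar singular)
  f <- rep(0.5, 6)
  Zc <- center_genotypes(geno, freqs = f)
  D <- c(1, 2, 0.5, 1, 1, 1.5)
  G <- build_G(Zc, f, D)
  Gi <- blend_and_invert_G(G, NULL, tau = 1, omega = 0)
  u <- c(1.2, -0.4, 0.7, -1.5)

  a0 <- backsolve_snp_effects(rep(0, 4), Zc, D, Gi, f)
  expect_true(all(a0$effect == 0))                       # null GEBVs

  a <- backsolve_snp_effects(u, Zc, D, Gi, f)
  expect_equal(unname(drop(Zc %*% a$effect)), u, tolerance = 1e-8)  # projection identity

  # independent dense oracle: minimum-norm weighted solution of Z a = u
  a_or <- sqrt(D) * drop(MASS::ginv(sweep(Zc, 2, sqrt(D), `*`)) %*% u)
  expect_equal(a$effect, a_or, tolerance = 1e-8)

  expect_error(backsolve_snp_effects(u[1:3], Zc, D, Gi, f), "length")
})

test_that("nonlinearA weights follow the formula, the cap, and normalization", {
  # |a| = 2 sd(a) exactly: c(e, 0, 0, 0) has sd e/2, so the raw weight is 1.05^0 = 1
  w1 <- nonlinear_a_weights(data.frame(effect = c(3, 0, 0, 0)))
  raw1 <- c(1, rep(1.05^-2, 3))
  expect_equal(w1, raw1 * 4 / sum(raw1))

  # |a| = sd(a) exactly: c(e, -e, 0) has sd e, raw weight 1.05^-1 = 0.952381
  w2 <- nonlinear_a_weights(data.frame(effect = c(2, -2, 0)))
  raw2 <- c(1.05^-1, 1.05^-1, 1.05^-2)
  expect_equal(w2, raw2 * 3 / sum(raw2))
  expect_equal(1.05^-1, 0.95238, tolerance = 1e-5)

  # |a| = 60 sd(a): c(e, 0 x 3599) has sd e/60; the cap at 10 binds
  # (1.05^58 = 16.9 > 10); ratios to the zero-effect weight prove it
  eff <- data.frame(effect = c(5, rep(0, 3599)))
  w3 <- nonlinear_a_weights(eff)
  expect_equal(w3[1] / w3[2], 10 / 1.05^-2, tolerance = 1e-10)
  expect_equal(sum(w3), 3600)

  # random vectors: direct formula evaluation + exact sum preservation
  set.seed(32)
  for (r in 1:5) {
    a <- rnorm(50) * 10^runif(1, -2, 2)
    w <- nonlinear_a_weights(data.frame(effect = a))
    raw <- pmin(1.05^(abs(a) / sd(a) - 2), 10)
    expect_equal(w, raw * 50 / sum(raw), tolerance = 1e-12)
    expect_equal(sum(w), 50)
  }
  expect_warning(w0 <- nonlinear_a_weights(data.frame(effect = rep(0, 7))),
                 "zero")
  expect_equal(w0, rep(1, 7))
})

test_that("window variances match hand computation and are order-invariant", {
  # single-marker window: codes {0,1,2}, a=1, sigma_u2=10
  g <- as_geno(matrix(c(0, 1, 2), 3, 1))
  Zc <- center_genotypes(g)
  eff <- structure(data.frame(marker = "M001", effect = 1, weight = 1),
                   class = c("snp_effects", "data.frame"))
  wr <- window_variances(eff, Zc, g$map, sigma_u2 = 10)
  expect_equal(wr$pct_var, 100 * (2 / 3) / 10, tolerance = 1e-12)  # 6.67%

  # zero effects give zero percent
  eff0 <- eff; eff0$effect <- 0
  expect_equal(window_variances(eff0, Zc, g$map, 10)$pct_var, 0)

  # marker order within a window does not matter
  set.seed(33)
  codes <- matrix(sample(0:2, 30 * 8, TRUE), 30, 8)
  g8 <- as_geno(codes, bp = seq(1e5, 9e5, length.out = 8))  # one window
  Zc8 <- center_genotypes(g8)
  a8 <- rnorm(8)
  e8 <- data.frame(marker = g8$map$marker, effect = a8, weight = 1)
  w_a <- window_variances(e8, Zc8, g8$map, 5)
  perm <- sample(8)
  e8p <- data.frame(marker = g8$map$marker[perm], effect = a8[perm], weight = 1)
  w_b <- window_variances(e8p, Zc8[, perm], g8$map[perm, ], 5)
  expect_equal(w_a$pct_var, w_b$pct_var, tolerance = 1e-12)

  # planted-truth oracle: true effects put ~5% in the QTL window, 0 elsewhere
  fx <- scan_fixture(seed = 35, qtl_pct = 5)
  Zq <- center_genotypes(fx$geno)
  etrue <- data.frame(marker = fx$geno$map$marker, effect = 0, weight = 1)
  etrue$effect[etrue$marker == fx$state$qtl$marker[1]] <- fx$state$qtl$effect[1]
  wt <- window_variances(etrue, Zq, fx$geno$map, 1)
  qbp <- fx$geno$map$bp[fx$geno$map$marker == fx$state$qtl$marker[1]]
  inq <- wt$chrom == "2" & wt$start_bp <= qbp & wt$end_bp >= qbp
  expect_equal(wt$pct_var[inq], 5, tolerance = 0.2)
  expect_true(all(wt$pct_var[!inq] == 0))
})

test_that("one weighting round is plain ssGBLUP and the GEBV decomposition holds", {
  fx <- scan_fixture(seed = 36)
  dat <- prepare_ssgblup(fx$ped, fx$geno, fx$traits)
  vc <- list(sigma_u2 = 1, sigma_e2 = 1.5)
  fit1 <- run_wssgblup(dat, "T1", vc = vc, n_iterations = 1)
  fit3 <- run_wssgblup(dat, "T1", vc = vc, n_iterations = 3)
  expect_true(all(fit1$effects[[1]]$weight == 1))
  expect_equal(fit1$effects[[1]]$effect, fit3$effects[[1]]$effect)

  # sum over all genome windows of window genetic values = Zc a; and with an
  # unblended full-rank system that equals u_hat itself
  wins <- make_windows(dat$geno$map)
  e1 <- fit1$effects[[1]]
  wsum <- Reduce(`+`, lapply(wins$marker_idx, function(sel)
    if (length(sel)) drop(dat$Zc[, sel, drop = FALSE] %*% e1$effect[sel]) else 0))
  expect_equal(wsum, drop(dat$Zc %*% e1$effect), tolerance = 1e-10)

  # unblended projection identity: more markers than animals and
  # reference-frequency centering keep G full rank
  set.seed(37)
  gsm <- as_geno(matrix(rbinom(30 * 80, 2, 0.4), 30, 80))
  fref <- rep(0.4, 80)
  Zr <- center_genotypes(gsm, freqs = fref)
  u <- rnorm(30)
  Gi <- blend_and_invert_G(build_G(Zr, fref), NULL, tau = 1, omega = 0)
  af <- backsolve_snp_effects(u, Zr, rep(1, 80), Gi, fref)
  expect_equal(unname(drop(Zr %*% af$effect)), u, tolerance = 1e-7)

  # weight sums stay equal to the marker count after every iteration
  for (it in 2:3)
    expect_equal(sum(fit3$effects[[it]]$weight), ncol(dat$Zc), tolerance = 1e-9)
})

test_that("a planted QTL marker's effect rank holds or improves across iterations", {
  ok <- logical(20)
  for (r in 1:20) {
    fx <- scan_fixture(seed = 600 + 7 * r, n_founders = 80, n_markers = 200,
                       qtl_pct = 20)
    dat <- prepare_ssgblup(fx$ped, fx$geno, fx$traits)
    fit <- run_wssgblup(dat, "T1",
                        vc = list(sigma_u2 = 1, sigma_e2 = 1.5),
                        n_iterations = 3)
    jm <- match(fx$state$qtl$marker[1], dat$geno$map$marker)
    r1 <- rank(-abs(fit$effects[[1]]$effect))[jm]
    r3 <- rank(-abs(fit$effects[[3]]$effect))[jm]
    ok[r] <- r3 <= r1
  }
  expect_gte(mean(ok), 0.9)
})

test_that("conditioning on a mediating trait removes its borrowed signal", {
  # trait B = 0.6 * A + noise: B's QTL window signal is entirely mediated by A
  drops <- sapply(1:3, function(r) {
    fx <- scan_fixture(seed = 700 + r, n_founders = 80, n_markers = 200,
                       qtl_pct = 20)
    tr <- fx$traits
    set.seed(800 + r)
    tr$T2 <- 0.6 * tr$T1 + rnorm(nrow(tr), 0, 0.8)
    dat <- prepare_ssgblup(fx$ped, fx$geno, tr)
    vc <- list(sigma_u2 = 0.5, sigma_e2 = 1.2)
    qbp <- fx$geno$map$bp[fx$geno$map$marker == fx$state$qtl$marker[1]]
    pct_of <- function(conditional) {
      fit <- run_wssgblup(dat, "T2", vc = vc, n_iterations = 1,
                          conditional = conditional)
      w <- wssg_windows(fit, dat)
      w$pct_var[w$chrom == "2" & w$start_bp <= qbp & w$end_bp >= qbp]
    }
    c(uncond = pct_of(FALSE), cond = pct_of(TRUE))
  })
  # conditional share collapses relative to the unconditional one
  expect_lt(mean(drops["cond", ] / drops["uncond", ]), 0.5)
})

test_that("window schemes tile the map as documented", {
  map <- data.frame(marker = sprintf("M%02d", 1:6), chrom = c(rep("1", 4), "2", "2"),
                    bp = c(2e5, 9e5, 1.4e6, 2.6e6, 3e5, 1.9e6))
  grid <- make_windows(map, "grid")
  expect_true(all(grid$end_bp - grid$start_bp == 1e6 - 1))
  expect_equal(sum(grid$n_markers), 6)
  expect_equal(grid$start_bp[1], 1)

  adj <- make_windows(map, "adjacent")
  expect_equal(sum(adj$n_markers), 6)
  # first adjacent window on chrom 1 starts at the first marker and holds
  # both markers within 1 Mb of it
  expect_equal(adj$start_bp[1], 2e5)
  expect_equal(adj$n_markers[1], 2)
  expect_true(all(adj$end_bp - adj$start_bp < 1e6))
})
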