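make_traits <- function(ped, y, extra = NULL) {
  tr <- data.frame(animal = ped$animal, birth_year = ped$birth_year,
                   age = 500 + seq_len(nrow(ped)) %% 60, MARB = y)
  if (!is.null(extra)) tr <- cbind(tr, extra)
  tr
}

test_that("design construction applies the age rule, conditioning and complete cases", {
  set.seed(20)
  tr <- data.frame(animal = 1:10, birth_year = rep(c(2000, 2001), 5),
                   age = rnorm(10, 500, 30),
                   MARB = rnorm(10), TEND = rnorm(10), JUIC = rnorm(10),
                   FLAV = rnorm(10))
  tr$JUIC[c(2, 5, 9)] <- NA

  d_tend <- build_design(tr, "TEND")           # no age covariate for TEND
  expect_false("age" %in% colnames(d_tend$X))
  expect_equal(ncol(d_tend$X), 2)              # year classes only

  d_marb <- build_design(tr, "MARB", conditional = TRUE)
  expect_equal(d_marb$n, 7)                    # 3 records lose JUIC
  expect_setequal(d_marb$covariates, c("TEND", "JUIC", "FLAV"))
  # column-count oracle: year levels + age + 3 trait covariates
  expect_equal(ncol(d_marb$X), length(unique(tr$birth_year)) + 1 + 3)

  expect_error(build_design(tr, "nope"), "unknown trait")
  expect_error(build_design(tr[is.na(tr$JUIC), ], "JUIC"), "no usable records")
})

test_that("MME solutions equal a dense generalized-inverse oracle", {
  ped <- fullsib_ped()
  ped <- rbind(ped, data.frame(animal = 6:7, sire = 3L, dam = 4L,
                               birth_year = 2003L))
  set.seed(21)
  y <- rnorm(6)
  # animal 5 has no record; receives a breeding value through A
  tr <- make_traits(ped, c(y[1:4], NA, y[5:6]))
  Ainv <- build_Ainv(ped)
  vc <- list(sigma_u2 = 2, sigma_e2 = 3)
  des <- build_design(tr, "MARB", use_age = FALSE)
  fit <- solve_mme(des, vc, Ainv)

  # independent dense assembly with an explicit incidence matrix
  X <- des$X
  W <- matrix(0, des$n, 7)
  W[cbind(seq_len(des$n), match(des$animal, Ainv$labels))] <- 1
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + (3 / 2) * Ainv$values))
  rhs <- c(crossprod(X, des$y), crossprod(W, des$y))
  sol <- MASS::ginv(C) %*% rhs
  expect_equal(unname(fit$b), sol[seq_len(ncol(X))], tolerance = 1e-8)
  expect_equal(unname(fit$u), sol[ncol(X) + 1:7], tolerance = 1e-8)
  expect_lt(fit$sys_residual, 1e-6)
  expect_true(abs(fit$u["5"]) > 0)  # no record, yet connected through A

  # infinite-shrinkage limit: u -> 0, b -> GLS
  fit0 <- solve_mme(des, list(sigma_u2 = 1e-10, sigma_e2 = 3), Ainv)
  expect_lt(max(abs(fit0$u)), 1e-6)
  bls <- qr.coef(qr(X), des$y)
  expect_equal(unname(fit0$b), unname(bls), tolerance = 1e-5)
})

test_that("ssGBLUP collapses to pedigree BLUP when G equals A22", {
  ped <- random_ped(30, 6, seed = 22)
  ped$birth_year <- rep(c(2000, 2001, 2002), 10)
  set.seed(23)
  tr <- make_traits(ped, rnorm(30))
  A <- build_A(ped); Ainv <- build_Ainv(ped)
  A22i <- subset_relmat(A, 1:30, invert = TRUE)
  Hinv <- build_Hinv(Ainv, A22i, relmat(A22i$values, A22i$labels, "Ginv"), 1:30)
  des <- build_design(tr, "MARB", use_age = FALSE)
  vc <- list(sigma_u2 = 1.2, sigma_e2 = 2.5)
  expect_equal(solve_mme(des, vc, Hinv)$u, solve_mme(des, vc, Ainv)$u,
               tolerance = 1e-8)
})

test_that("AIREML equals closed-form ANOVA estimators on balanced half-sib data", {
  set.seed(7)
  s <- 60; n <- 10
  ped <- data.frame(animal = 1:(s + s * n),
                    sire = c(rep(0L, s), rep(1:s, each = n)), dam = 0L,
                    birth_year = 2000L)
  y <- 10 + rep(rnorm(s, 0, 1), each = n) + rnorm(s * n, 0, sqrt(10))
  tr <- data.frame(animal = s + 1:(s * n), birth_year = 2000L, MARB = y)
  vc <- aireml_single(build_design(tr, "MARB", use_age = FALSE),
                      build_A(ped), tol = 1e-10)
  # closed-form ANOVA estimators for the balanced one-way layout
  fam <- rep(1:s, each = n)
  ybar_i <- tapply(y, fam, mean)
  MSB <- n * sum((ybar_i - mean(y))^2) / (s - 1)
  MSW <- sum((y - ybar_i[fam])^2) / (s * (n - 1))
  ss2 <- (MSB - MSW) / n
  expect_equal(vc$sigma_u2, 4 * ss2, tolerance = 1e-6)
  expect_equal(vc$sigma_e2, MSW - 3 * ss2, tolerance = 1e-6)
  expect_true(vc$converged)
  expect_true(is.finite(vc$loglik) && vc$se["h2"] > 0)
})

test_that("AIREML lands on the boundary when data carry no genetic variance", {
  ped <- simulate_pedigree(250, 2, 2, seed = 24)
  sim <- simulate_traits(ped, matrix(0), matrix(5), seed = 25)
  vc <- suppressWarnings(
    aireml_single(build_design(sim$traits, "T1", use_age = FALSE), build_A(ped)))
  expect_lt(vc$h2, 0.1)
})

test_that("bivariate REML: duplicated trait, independent traits, path agreement", {
  ped <- simulate_pedigree(100, 3, 2, seed = 26)
  sim <- simulate_traits(ped, diag(c(2, 3)), diag(c(3, 2)), seed = 27)
  tr <- sim$traits
  A <- build_A(ped)

  # trait B an exact copy of trait A: genetic correlation pinned at 1
  tr$COPY <- tr$T1
  vc1 <- suppressWarnings(
    aireml_bivariate(build_design(tr, "T1", use_age = FALSE),
                     build_design(tr, "COPY", use_age = FALSE), A,
                     max_rounds = 60, tol = 1e-7))
  expect_gt(vc1$r_g, 0.95)

  # independently simulated traits: r_g near zero
  rgs <- sapply(1:3, function(s) {
    pp <- simulate_pedigree(100, 3, 2, seed = 30 + s)
    ss <- simulate_traits(pp, diag(c(2, 3)), diag(c(3, 2)), seed = 40 + s)
    vv <- aireml_bivariate(build_design(ss$traits, "T1", use_age = FALSE),
                           build_design(ss$traits, "T2", use_age = FALSE),
                           build_A(pp), tol = 1e-8)
    vv$r_g
  })
  expect_lt(abs(mean(rgs)), 0.25)

  # fast (eigen) path agrees with the dense general path on complete data
  d1 <- build_design(tr, "T1", use_age = FALSE)
  d2 <- build_design(tr, "T2", use_age = FALSE)
  vf <- aireml_bivariate(d1, d2, A, tol = 1e-9)
  vd <- pleioscan:::.aireml_bv_direct(d1, d2, A, NULL, 200, 1e-9)
  expect_equal(vf$T, vd$T, tolerance = 1e-6)
  expect_equal(vf$R, vd$R, tolerance = 1e-6)
  expect_equal(vf$loglik, vd$loglik, tolerance = 1e-8)

  # differing missingness: general path returns a valid estimate
  tr2 <- sim$traits
  tr2$T1[seq(1, 90, by = 3)] <- NA
  tr2$T2[seq(2, 120, by = 4)] <- NA
  vm <- suppressWarnings(
    aireml_bivariate(build_design(tr2, "T1", use_age = FALSE),
                     build_design(tr2, "T2", use_age = FALSE), A,
                     max_rounds = 80, tol = 1e-7))
  expect_true(all(diag(vm$T) >= 0) && all(diag(vm$R) >= 0))
  expect_lte(abs(vm$r_g), 1)
  expect_lte(abs(vm$r_p), 1)
})

test_that("heritability estimates are unbiased across desk-scale replicates", {
  # 20 replicates at reduced n; mean bias of h2 within 2 MC standard errors
  h2 <- sapply(1:20, function(s) {
    ped <- simulate_pedigree(120, 3, 2, seed = 400 + s)
    sim <- simulate_traits(ped, matrix(2), matrix(2), seed = 500 + s)
    aireml_single(build_design(sim$traits, "T1", use_age = FALSE),
                  build_A(ped), tol = 1e-8)$h2
  })
  se <- stats::sd(h2) / sqrt(20)
  expect_lt(abs(mean(h2) - 0.5), 2 * se + 0.01)
})
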