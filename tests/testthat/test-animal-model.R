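test_that("design bundle incidence matrices are well formed", {
  d <- data.frame(id = rep(c("a", "b", "c"), each = 2),
                  birth_year = rep(c(2001L, 2001L, 2002L), each = 2),
                  meas_year = rep(c(2003L, 2004L), 3),
                  age = rep(c(2L, 3L), 3),
                  trait = "length", value = rnorm(6))
  K <- diag(3); dimnames(K) <- list(c("a", "b", "c"), c("a", "b", "c"))
  grm <- structure(list(K = K, ids = c("a", "b", "c"), n_loci = 10L),
                   class = "grm")
  des <- build_design(d, grm, "length")
  expect_equal(dim(des$terms$pe$Z), c(6, 3))
  expect_equal(colSums(des$terms$pe$Z), c(a = 2, b = 2, c = 2))
  expect_equal(colSums(des$terms$ym$Z), c(`2003` = 3, `2004` = 3))
  expect_equal(colnames(des$X), c("(Intercept)", "age3"))

  # single age class: intercept only
  d2 <- d[d$age == 2, ]
  des2 <- build_design(d2, grm, "length")
  expect_equal(colnames(des2$X), "(Intercept)")

  d$id[1] <- "zz"
  expect_error(build_design(d, grm, "length"), "zz")
})

test_that("heritability is the additive share of phenotypic variance", {
  h <- heritability(c(va = 33, vpe = 35, vym = 2, vyb = 1, vr = 29))
  expect_equal(unname(h[["h2"]]), 0.33)
  expect_equal(unname(heritability(c(va = 0, vpe = 10, vym = 1, vyb = 1,
                                     vr = 8))[["h2"]]), 0)
  h10 <- heritability(10 * c(va = 33, vpe = 35, vym = 2, vyb = 1, vr = 29))
  expect_equal(h10[["h2"]], h[["h2"]])
  expect_error(heritability(c(vpe = 1, vr = 1)), "va")
})

test_that("restricted log-likelihood matches a dense-matrix evaluation", {
  fit <- small_fit()
  des <- fit$design
  ll_dense <- dense_reml_loglik(des$y, des$X, des$terms, fit$theta)
  expect_equal(fit$loglik, as.numeric(ll_dense), tolerance = 1e-6)
  # also at a non-optimal point, via the package evaluator
  theta2 <- fit$theta * c(1.5, 0.5, 1, 1, 1.2)
  blocks <- lapply(des$terms, hornherit:::term_factor)
  st <- hornherit:::reml_eval(des$y, des$X, blocks, theta2)
  expect_equal(st$loglik,
               as.numeric(dense_reml_loglik(des$y, des$X, des$terms, theta2)),
               tolerance = 1e-6)
})

test_that("REML improves the likelihood over nearby parameter values", {
  fit <- small_fit()
  des <- fit$design
  blocks <- lapply(des$terms, hornherit:::term_factor)
  set.seed(2)
  for (i in 1:8) {
    jitter <- exp(rnorm(5, 0, 0.25))
    theta2 <- pmax(fit$theta * jitter, 1e-8)
    st <- hornherit:::reml_eval(des$y, des$X, blocks, theta2)
    expect_lte(st$loglik, fit$loglik + 1e-6)
  }
})

test_that("constant phenotypes give a degenerate all-zero fit", {
  st <- small_study()
  phenos <- st$sim$phenotypes
  phenos$value <- 500
  fit <- animal_model(phenos, st$grm, trait = "length")
  expect_true(fit$degenerate)
  expect_equal(unname(fit$theta), rep(0, 5))
})

test_that("an identity GRM triggers the confounding warning", {
  st <- small_study()
  grm_id <- st$grm
  grm_id$K <- diag(nrow(grm_id$K))
  dimnames(grm_id$K) <- dimnames(st$grm$K)
  w <- capture_warnings(animal_model(st$sim$phenotypes, grm_id,
                                     trait = "length",
                                     control = reml_control(max_iter = 30)))
  expect_true(any(grepl("confounded", w)))
})

test_that("REML estimates are invariant to observation order and shift", {
  st <- small_study()
  fit <- small_fit()
  phenos <- st$sim$phenotypes
  set.seed(77)
  perm <- sample(nrow(phenos))
  fit_perm <- animal_model(phenos[perm, ], st$grm, trait = "length")
  expect_equal(fit_perm$theta, fit$theta, tolerance = 1e-4)
  expect_equal(fit_perm$loglik, fit$loglik, tolerance = 1e-6)

  shifted <- phenos
  shifted$value <- shifted$value + 250
  fit_shift <- animal_model(shifted, st$grm, trait = "length")
  expect_equal(fit_shift$theta, fit$theta, tolerance = 1e-4)
  expect_equal(unname(coef(fit_shift)[1] - coef(fit)[1]), 250,
               tolerance = 1e-6)
})

test_that("two-component reduction agrees with a profiled grid search", {
  # one record per individual, additive + residual only
  cfg <- sim_config(n_sires = 20, dams_per_sire = 2, offspring_per_dam = 2,
                    n_snps = 800, harvest_age_range = c(3L, 3L), seed = 55)
  sim <- simulate_horn_study(cfg, traits = "length")
  phen <- sim$phenotypes[sim$phenotypes$age == 2, ]
  qc <- qc_genotypes(sim$genotypes)
  grm <- stabilize_grm(compute_grm(qc$genotypes))
  fit <- animal_model(phen, grm, trait = "length", random = "additive")
  # grid search: V(h2) = vp * (h2 G + (1-h2) I), profile vp analytically
  des <- fit$design
  y <- des$y; X <- des$X
  G <- des$G[des$ids, des$ids]
  n <- length(y); p <- ncol(X)
  grid <- seq(0, 0.99, by = 0.01)
  prof <- sapply(grid, function(h2) {
    V0 <- h2 * G + (1 - h2) * diag(n)
    Vi <- solve(V0)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
    -0.5 * ((n - p) * log(s2) + determinant(V0)$modulus +
              determinant(XtViX)$modulus + (n - p))
  })
  h2_grid <- grid[which.max(prof)]
  expect_lt(abs(fit$h2 - h2_grid), 0.02)
})

test_that("true variance proportions are covered by the estimates", {
  # 95% intervals should contain the generating proportion in >= 15/20
  # replicates at the default study design
  cfg0 <- sim_config()
  target <- cfg0$variance_proportions$length
  hits <- matrix(FALSE, 20, 5,
                 dimnames = list(NULL, names(target)))
  for (r in 1:20) {
    cfg <- sim_config(seed = 300 + r)
    sim <- simulate_horn_study(cfg, traits = "length")
    qc <- qc_genotypes(sim$genotypes)
    grm <- stabilize_grm(compute_grm(qc$genotypes))
    fit <- animal_model(sim$phenotypes, grm, trait = "length")
    comp <- fit$components
    for (j in seq_len(5)) {
      k <- match(comp$component[j], names(target))
      lo <- comp$proportion[j] - 1.96 * comp$proportion_se[j]
      hi <- comp$proportion[j] + 1.96 * comp$proportion_se[j]
      hits[r, k] <- target[k] >= lo & target[k] <= hi
    }
  }
  expect_true(all(colSums(hits) >= 15),
              label = paste("coverage:", paste(colSums(hits), collapse = "/")))
})

test_that("model accessors are mutually consistent", {
  fit <- small_fit()
  expect_equal(sum(fit$components$proportion), 1, tolerance = 1e-9)
  expect_true(all(fit$components$variance >= 0))
  expect_gte(fit$h2, 0); expect_lte(fit$h2, 1)
  expect_equal(fit$vp, sum(fit$theta))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(length(coef(fit)), ncol(fit$design$X))
  expect_equal(dim(vcov(fit)), rep(ncol(fit$design$X), 2))
  expect_equal(fitted(fit) + residuals(fit), fit$design$y)
  re <- ranef(fit)
  expect_named(re, c("additive", "pe", "yb", "ym"))
  truth <- attr(small_study()$sim$phenotypes, "truth")$length
  expect_gt(cor(re$additive[truth$ids], truth$breeding_values), 0.3)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_obs, 3))
  expect_output(print(summary(fit)), "Fixed effects")
})
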