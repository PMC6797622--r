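# Repeated-measures animal model by average-information REML ------------
#
# Model: y = X beta + Z_a a + Z_pe pe + Z_yb b + Z_ym m + e with
#   a  ~ N(0, sigma2_a  G)      (G = genomic relationship matrix)
#   pe ~ N(0, sigma2_pe I)      (permanent environment, per individual)
#   b  ~ N(0, sigma2_yb I)      (birth-year cohort)
#   m  ~ N(0, sigma2_ym I)      (year of measurement)
#   e  ~ N(0, sigma2_r  I)
# All V-products go through a Woodbury factorization: with
# B_i = Z_i chol(A_i)' and W = [B_i sigma_i / sigma_r], V = sigma2_r
# (I + W W') so V^{-1} x and log|V| cost O(n q^2) instead of O(n^3).

#' REML fitting control
#'
#' @param max_iter iteration cap (default 200).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param n_em expectation-maximization warm-up iterations before
#'   switching to average-information updates (default 5; EM is slow but
#'   safe far from the optimum).
#' @param floor_frac variance components are projected to
#'   `floor_frac * Vp` at each step to keep the parameter space open
#'   (default 1e-10).
#' @param verbose print the likelihood trajectory.
#' @return List of class `reml_control`.
#' @export
reml_control <- function(max_iter = 200L, tol = 1e-6, n_em = 5L,
                         floor_frac = 1e-10, verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_em = as.integer(n_em), floor_frac = floor_frac,
                 verbose = isTRUE(verbose)), class = "reml_control")
}

#' Build the mixed-model design bundle
#'
#' Assembles the response, fixed-effect incidence (intercept plus
#' age-class dummies with the youngest age as reference, or a linear age
#' slope), and random-effect incidence matrices mapping observations to
#' individuals (shared by the additive and permanent-environment terms),
#' birth years, and measurement years.
#'
#' @param phenos long phenotype table (columns `id`, `birth_year`,
#'   `meas_year`, `age`, `trait`, `value`).
#' @param grm a `grm` from [compute_grm()]; every phenotyped individual
#'   must be present.
#' @param trait trait to extract.
#' @param age_effect `"factor"` (default; horn growth is strongly
#'   nonlinear in age) or `"linear"`.
#' @param random random-effect terms to include, a subset of
#'   `c("additive", "pe", "yb", "ym")`.
#' @return List of class `design_bundle` with `y`, `X`, `terms` (named
#'   list of incidence matrices and covariance factors), `ids`
#'   (individual per observation), `ind_levels`, and bookkeeping.
#' @export
build_design <- function(phenos, grm, trait = "length",
                         age_effect = c("factor", "linear"),
                         random = c("additive", "pe", "yb", "ym")) {
  age_effect <- match.arg(age_effect)
  random <- match.arg(random, several.ok = TRUE)
  d <- phenos[phenos$trait == trait, , drop = FALSE]
  stop_if(nrow(d) == 0, "no rows for trait '%s'", trait)
  miss <- setdiff(unique(d$id), grm$ids)
  stop_if(length(miss) > 0,
          "phenotyped individuals absent from GRM: %s%s",
          paste(utils::head(miss, 10), collapse = ", "),
          if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10) else "")
  n <- nrow(d)
  ind_levels <- grm$ids[grm$ids %in% unique(d$id)]
  ii <- match(d$id, ind_levels)
  # fixed effects
  ages <- sort(unique(d$age))
  if (age_effect == "factor" && length(ages) > 1) {
    X <- stats::model.matrix(~ factor(age, levels = ages), data = d)
    colnames(X) <- c("(Intercept)", paste0("age", ages[-1]))
  } else if (age_effect == "linear" && length(ages) > 1) {
    X <- cbind(`(Intercept)` = 1, age = d$age)
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  incidence <- function(fac) {
    lev <- sort(unique(fac))
    Z <- matrix(0, n, length(lev), dimnames = list(NULL, as.character(lev)))
    Z[cbind(seq_len(n), match(fac, lev))] <- 1
    Z
  }
  Zind <- matrix(0, n, length(ind_levels),
                 dimnames = list(NULL, ind_levels))
  Zind[cbind(seq_len(n), ii)] <- 1
  G <- grm$K[ind_levels, ind_levels, drop = FALSE]
  terms <- list()
  if ("additive" %in% random) {
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    stop_if(min(ev) < -1e-8,
            "GRM is not positive semi-definite; run stabilize_grm() first")
    if (min(ev) < 1e-8) {
      G <- G + diag(2 * (1e-8 - min(ev)), nrow(G))
    }
    terms$additive <- list(Z = Zind, L = chol(G), A = G, label = "va")
  }
  if ("pe" %in% random) terms$pe <- list(Z = Zind, L = NULL, label = "vpe")
  if ("yb" %in% random) {
    terms$yb <- list(Z = incidence(d$birth_year), L = NULL, label = "vyb")
  }
  if ("ym" %in% random) {
    terms$ym <- list(Z = incidence(d$meas_year), L = NULL, label = "vym")
  }
  structure(list(y = d$value, X = X, terms = terms, data = d,
                 ids = d$id, ind_levels = ind_levels, G = G,
                 trait = trait, age_effect = age_effect),
            class = "design_bundle")
}

# factor B_i = Z_i chol(A_i)' such that Z_i A_i Z_i' = B_i B_i'
term_factor <- function(term) {
  if (is.null(term$L)) term$Z else term$Z %*% t(term$L)
}

# Woodbury state for fixed theta; ops used by REML and the GWAS scan
vops_build <- function(blocks, theta, n) {
  k <- length(blocks)
  theta <- unname(theta)
  s2r <- theta[k + 1L]
  W <- do.call(cbind, lapply(seq_len(k), function(i)
    blocks[[i]] * sqrt(theta[i] / s2r)))
  M <- crossprod(W)
  diag(M) <- diag(M) + 1
  cM <- chol(M)
  list(W = W, cM = cM, s2r = s2r, n = n,
       logdetV = n * log(s2r) + 2 * sum(log(diag(cM))))
}

vops_solve <- function(vs, x) {
  wx <- crossprod(vs$W, x)
  (x - vs$W %*% backsolve(vs$cM, forwardsolve(t(vs$cM), wx))) / vs$s2r
}

# restricted log-likelihood pieces at fixed theta
reml_eval <- function(y, X, blocks, theta) {
  n <- length(y); p <- ncol(X)
  vs <- vops_build(blocks, theta, n)
  ViX <- vops_solve(vs, X)
  Viy <- vops_solve(vs, y)
  XtViX <- crossprod(X, ViX)
  cX <- chol(XtViX)
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(cX, forwardsolve(t(cX), XtViy))
  Py <- Viy - ViX %*% beta
  yPy <- sum(y * Py)
  ll <- -0.5 * ((n - p) * log(2 * pi) + vs$logdetV +
                  2 * sum(log(diag(cX))) + yPy)
  list(vs = vs, ViX = ViX, XtViX = XtViX, cX = cX, beta = drop(beta),
       Py = drop(Py), yPy = yPy, loglik = ll)
}

# apply the REML projection P to columns of x
apply_P <- function(st, x) {
  Vix <- vops_solve(st$vs, x)
  Vix - st$ViX %*% backsolve(st$cX, forwardsolve(t(st$cX),
                                                 crossprod(st$ViX, x)))
}

# trace(P V_i) for each random term plus the residual
reml_traces <- function(st, blocks, X) {
  n <- st$vs$n
  tr <- numeric(length(blocks) + 1L)
  for (i in seq_along(blocks)) {
    PB <- apply_P(st, blocks[[i]])
    tr[i] <- sum(blocks[[i]] * PB)
  }
  # residual: tr(P) = tr(V^-1) - tr((X'V^-1X)^-1 X'V^-2X)
  Wt <- t(st$vs$W)
  MiWt <- backsolve(st$vs$cM, forwardsolve(t(st$vs$cM), Wt))
  trVi <- (n - sum(Wt * MiWt)) / st$vs$s2r
  XtVi2X <- crossprod(st$ViX)
  tr[length(tr)] <- trVi - sum(chol2inv(st$cX) * XtVi2X)
  tr
}

#' Low-level AI-REML variance-component estimation
#'
#' Maximizes the restricted likelihood of a Gaussian mixed model with an
#' arbitrary list of random terms (each an incidence matrix with an
#' optional covariance factor) plus a residual. Five EM warm-up
#' iterations precede average-information (quasi-Newton) updates with
#' step halving; components are kept above `floor_frac * Vp`.
#' Convergence is declared when the restricted log-likelihood changes by
#' less than `tol`.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param terms named list; each element a list with incidence matrix
#'   `Z`, optional upper-triangular covariance factor `L` (so the term
#'   covariance is `t(L) %*% L`), and a `label`.
#' @param control a [reml_control()].
#' @return List with `theta` (component variances, residual last),
#'   `loglik`, `converged`, `iterations`, `vcov_theta`
#'   (inverse average-information matrix), `beta`, `beta_vcov`, `Py`,
#'   `trajectory`, and `degenerate`.
#' @export
reml_fit <- function(y, X, terms, control = reml_control()) {
  n <- length(y); p <- qr(X)$rank
  stop_if(p < ncol(X), "fixed-effect design is rank deficient")
  k <- length(terms)
  labels <- c(vapply(terms, `[[`, character(1), "label"), "vr")
  vp0 <- stats::var(stats::lm.fit(X, y)$residuals)
  if (!is.finite(vp0) || vp0 < .Machine$double.eps * max(1, mean(y)^2)) {
    theta <- stats::setNames(rep(0, k + 1L), labels)
    return(list(theta = theta, loglik = NA_real_, converged = TRUE,
                iterations = 0L, vcov_theta = matrix(NA, k + 1, k + 1),
                beta = rep(mean(y), ncol(X)) * c(1, rep(0, ncol(X) - 1)),
                beta_vcov = matrix(0, ncol(X), ncol(X)),
                trajectory = numeric(0), degenerate = TRUE))
  }
  blocks <- lapply(terms, term_factor)
  qi <- c(vapply(blocks, ncol, integer(1)), n)
  floor_v <- control$floor_frac * vp0
  theta <- rep(vp0 / (k + 1), k + 1L)
  st <- reml_eval(y, X, blocks, theta)
  traj <- st$loglik
  converged <- FALSE
  AI <- NULL
  for (iter in seq_len(control$max_iter)) {
    tr <- reml_traces(st, blocks, X)
    # quadratic forms y' P V_i P y via the factor form
    quad <- numeric(k + 1L)
    U <- matrix(0, n, k + 1L)
    for (i in seq_len(k)) {
      bty <- crossprod(blocks[[i]], st$Py)
      quad[i] <- sum(bty^2)
      U[, i] <- blocks[[i]] %*% bty
    }
    quad[k + 1L] <- sum(st$Py^2)
    U[, k + 1L] <- st$Py
    grad <- -0.5 * (tr - quad)
    PU <- apply_P(st, U)
    AI <- 0.5 * crossprod(U, PU)
    em_step <- theta^2 * (quad - tr) / qi
    # components pinned at the floor with downhill gradient are held
    # there and dropped from the AI system (keeps the update from
    # oscillating against the boundary)
    free <- !(theta <= floor_v * (1 + 1e-6) & grad < 0)
    if (iter <= control$n_em) {
      step <- em_step
    } else if (!any(free)) {
      converged <- TRUE
      break
    } else {
      step <- rep(0, k + 1L)
      step[free] <- tryCatch(
        drop(solve(AI[free, free, drop = FALSE], grad[free])),
        error = function(e) em_step[free])
    }
    ll_old <- st$loglik
    for (half in 0:10) {
      cand <- pmax(theta + step / 2^half, floor_v)
      st_new <- tryCatch(reml_eval(y, X, blocks, cand),
                         error = function(e) NULL)
      if (!is.null(st_new) && is.finite(st_new$loglik) &&
          (st_new$loglik >= ll_old - 1e-10 || half == 10)) break
    }
    if (is.null(st_new)) break
    theta <- cand
    st <- st_new
    traj <- c(traj, st$loglik)
    if (control$verbose) {
      message(sprintf("iter %3d logLik %.6f", iter, st$loglik))
    }
    if (abs(st$loglik - ll_old) < control$tol && iter > control$n_em) {
      converged <- TRUE
      break
    }
  }
  vcov_theta <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, k + 1, k + 1))
  names(theta) <- labels
  dimnames(vcov_theta) <- list(labels, labels)
  beta_vcov <- chol2inv(st$cX)
  dimnames(beta_vcov) <- list(colnames(X), colnames(X))
  list(theta = theta, loglik = st$loglik, converged = converged,
       iterations = length(traj) - 1L, vcov_theta = vcov_theta,
       beta = stats::setNames(st$beta, colnames(X)), beta_vcov = beta_vcov,
       Py = st$Py, trajectory = traj, degenerate = FALSE)
}

#' Fit the repeated-measures animal model
#'
#' Estimates the five-component variance decomposition of a horn-size
#' trait — additive genetic (`va`, covariance given by the genomic
#' relationship matrix), permanent environment (`vpe`), birth-year
#' cohort (`vyb`), year of measurement (`vym`) and residual (`vr`) —
#' with age fitted as a fixed categorical factor, by
#' average-information REML. Narrow-sense heritability is
#' `h2 = va / (va + vpe + vyb + vym + vr)`; standard errors of all
#' ratios are first-order delta-method.
#'
#' @inheritParams build_design
#' @param control a [reml_control()].
#' @return An object of class `animal_model` with components table,
#'   heritability, fixed-effect estimates and the design bundle.
#'   Supports `print()`, `summary()`, `coef()`, `vcov()`, `logLik()`,
#'   `fitted()`, `residuals()`, `ranef()`, `simulate()` and
#'   [heritability()].
#' @examples
#' cfg <- sim_config(n_sires = 8, dams_per_sire = 2, offspring_per_dam = 2,
#'                   n_snps = 400, seed = 42)
#' sim <- simulate_horn_study(cfg, traits = "length")
#' grm <- stabilize_grm(compute_grm(sim$genotypes))
#' fit <- animal_model(sim$phenotypes, grm, trait = "length")
#' heritability(fit)
#' @export
animal_model <- function(phenos, grm, trait = "length",
                         age_effect = c("factor", "linear"),
                         random = c("additive", "pe", "yb", "ym"),
                         control = reml_control()) {
  cl <- match.call()
  des <- build_design(phenos, grm, trait, age_effect, random)
  if ("additive" %in% names(des$terms)) {
    offd <- des$G[upper.tri(des$G)]
    if (length(unique(round(c(diag(des$G), offd), 10))) < 3 &&
        "pe" %in% names(des$terms)) {
      warning("GRM is (near) identity: additive and permanent-environment ",
              "variances are confounded")
    }
  }
  res <- reml_fit(des$y, des$X, des$terms, control)
  if (!res$converged && !res$degenerate) {
    warning(sprintf(
      "REML did not converge in %d iterations (last logLik change %.3g)",
      res$iterations,
      if (length(res$trajectory) > 1) diff(utils::tail(res$trajectory, 2)) else NA))
  }
  vp <- sum(res$theta)
  prop <- if (vp > 0) res$theta / vp else res$theta * NA
  prop_se <- rep(NA_real_, length(res$theta))
  if (vp > 0 && all(is.finite(res$vcov_theta))) {
    for (i in seq_along(res$theta)) {
      gvec <- -res$theta[i] / vp^2 + (seq_along(res$theta) == i) / vp
      prop_se[i] <- sqrt(max(0, drop(t(gvec) %*% res$vcov_theta %*% gvec)))
    }
  }
  comp <- data.frame(
    component = names(res$theta),
    variance = as.numeric(res$theta),
    se = sqrt(pmax(0, diag(res$vcov_theta))),
    proportion = as.numeric(prop),
    proportion_se = prop_se,
    stringsAsFactors = FALSE
  )
  vp_se <- if (all(is.finite(res$vcov_theta))) sqrt(max(0, sum(res$vcov_theta)))
           else NA_real_
  structure(list(
    components = comp, vp = vp, vp_se = vp_se,
    h2 = if ("va" %in% names(res$theta))
      unname(prop[["va"]]) else NA_real_,
    h2_se = if ("va" %in% names(res$theta))
      prop_se[match("va", names(res$theta))] else NA_real_,
    loglik = res$loglik, converged = res$converged,
    degenerate = res$degenerate, iterations = res$iterations,
    theta = res$theta, vcov_theta = res$vcov_theta,
    beta = res$beta, beta_vcov = res$beta_vcov,
    trajectory = res$trajectory, design = des, grm = grm,
    n_obs = length(des$y), n_ind = length(des$ind_levels),
    trait = trait, call = cl
  ), class = "animal_model")
}

#' Narrow-sense heritability
#'
#' `h2 = va / (va + vpe + vyb + vym + vr)`. For a fitted model the
#' standard error is first-order delta-method from the inverse
#' average-information matrix.
#'
#' @param object an `animal_model` fit or a named numeric vector of
#'   variance components including `va`.
#' @param ... unused.
#' @return Named numeric vector `c(h2, se)` (`se` is `NA` for plain
#'   component vectors).
#' @examples
#' heritability(c(va = 33, vpe = 35, vym = 2, vyb = 1, vr = 29))
#' @export
heritability <- function(object, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.animal_model <- function(object, ...) {
  c(h2 = object$h2, se = object$h2_se)
}

#' @rdname heritability
#' @export
heritability.numeric <- function(object, ...) {
  stop_if(!"va" %in% names(object), "components must include 'va'")
  stop_if(any(object < 0), "variance components must be >= 0")
  c(h2 = unname(object[["va"]] / sum(object)), se = NA_real_)
}

# S3 methods -------------------------------------------------------------

#' @export
print.animal_model <- function(x, digits = 4, ...) {
  cat(sprintf("Repeated-measures animal model (AI-REML), trait '%s'\n",
              x$trait))
  cat(sprintf("  %d observations on %d individuals; logLik %.3f (%s, %d iterations)\n",
              x$n_obs, x$n_ind, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (x$degenerate) cat("  degenerate fit: response has zero variance\n")
  cat(sprintf("  Vp = %s;  h2 = %.3f (SE %.3f)\n",
              format(x$vp, digits = digits), x$h2, x$h2_se))
  print(x$components, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  structure(list(fit = object), class = "summary.animal_model")
}

#' @export
print.summary.animal_model <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nFixed effects (age means relative to youngest class):\n")
  se <- sqrt(diag(x$fit$beta_vcov))
  tab <- data.frame(estimate = x$fit$beta, se = se,
                    z = x$fit$beta / se)
  print(tab, digits = digits)
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$beta

#' @export
vcov.animal_model <- function(object, ...) object$beta_vcov

#' @export
logLik.animal_model <- function(object, ...) {
  structure(object$loglik, df = length(object$theta) + length(object$beta),
            nobs = object$n_obs, class = "logLik")
}

#' Random-effect predictions (BLUPs)
#'
#' @param object an `animal_model`.
#' @param ... unused.
#' @return Named list of BLUP vectors, one per random term (estimated
#'   breeding values for `additive`).
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.animal_model <- function(object, ...) {
  res <- reml_eval(object$design$y, object$design$X,
                   lapply(object$design$terms, term_factor), object$theta)
  out <- list()
  for (nm in names(object$design$terms)) {
    trm <- object$design$terms[[nm]]
    s2 <- object$theta[[trm$label]]
    ZtPy <- crossprod(trm$Z, res$Py)
    u <- if (is.null(trm$L)) s2 * ZtPy else s2 * (trm$A %*% ZtPy)
    out[[nm]] <- stats::setNames(drop(u), colnames(trm$Z))
  }
  out
}

#' @export
fitted.animal_model <- function(object, ...) {
  des <- object$design
  mu <- unname(drop(des$X %*% object$beta))
  re <- ranef(object)
  for (nm in names(re)) {
    mu <- mu + drop(des$terms[[nm]]$Z %*% re[[nm]])
  }
  mu
}

#' @export
residuals.animal_model <- function(object, ...) {
  object$design$y - fitted(object)
}

#' @export
simulate.animal_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  n <- length(des$y)
  blocks <- lapply(des$terms, term_factor)
  labels <- vapply(des$terms, `[[`, character(1), "label")
  out <- matrix(0, n, nsim)
  for (s in seq_len(nsim)) {
    y <- drop(des$X %*% object$beta) + rnorm(n, 0, sqrt(object$theta[["vr"]]))
    for (i in seq_along(blocks)) {
      y <- y + drop(blocks[[i]] %*% rnorm(ncol(blocks[[i]]))) *
        sqrt(object$theta[[labels[i]]])
    }
    out[, s] <- y
  }
  as.data.frame(out)
}

#' @export
plot.animal_model <- function(x, ...) {
  graphics::plot(seq_along(x$trajectory) - 1L, x$trajectory, type = "b",
                 xlab = "iteration", ylab = "restricted log-likelihood",
                 main = sprintf("REML trajectory (%s)", x$trait), ...)
  invisible(x)
}

#' Write variance-component results as TSV
#'
#' One row per fitted trait with components, proportions, SEs,
#' heritability, log-likelihood and sample sizes.
#'
#' @param fits list of `animal_model` objects (or a single fit).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variance_components <- function(fits, path) {
  if (inherits(fits, "animal_model")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    comp <- f$components
    wide <- stats::setNames(as.list(c(comp$variance, comp$se,
                                      comp$proportion, comp$proportion_se)),
                            c(comp$component,
                              paste0(comp$component, "_se"),
                              paste0("prop_", comp$component),
                              paste0("prop_", comp$component, "_se")))
    cbind(data.frame(trait = f$trait, n_ind = f$n_ind, n_obs = f$n_obs,
                     vp = f$vp, vp_se = f$vp_se, h2 = f$h2, h2_se = f$h2_se,
                     loglik = f$loglik, converged = f$converged),
          as.data.frame(wide))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
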