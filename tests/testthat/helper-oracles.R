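# Independent brute-force oracles used to validate the fast
# implementations. All work with dense matrices and base linear algebra,
# deliberately avoiding the package's Woodbury code paths.

# Dense restricted log-likelihood of y ~ N(X beta, V) with
# V = sum_i theta_i Z_i A_i Z_i' + theta_r I.
dense_reml_loglik <- function(y, X, terms, theta) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(terms)) {
    Z <- terms[[i]]$Z
    A <- if (is.null(terms[[i]]$A)) diag(ncol(Z)) else terms[[i]]$A
    V <- V + theta[i] * (Z %*% A %*% t(Z))
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  -0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
            determinant(XtViX)$modulus + quad)
}

# Dense phenotypic covariance implied by a fitted animal model.
dense_V <- function(fit) {
  des <- fit$design
  n <- length(des$y)
  V <- diag(fit$theta[["vr"]], n)
  for (nm in names(des$terms)) {
    trm <- des$terms[[nm]]
    A <- if (is.null(trm$L)) diag(ncol(trm$Z)) else trm$A
    V <- V + fit$theta[[trm$label]] * (trm$Z %*% A %*% t(trm$Z))
  }
  V
}

# Dense GLS estimate and SE of the last column's coefficient.
dense_gls_last <- function(y, X, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  covb <- solve(XtViX)
  k <- ncol(X)
  c(beta = beta[k], se = sqrt(covb[k, k]))
}

# Exact Hardy-Weinberg p-value by full enumeration of the conditional
# heterozygote distribution using binomial coefficients directly.
hwe_enum_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * min(n_aa, n_bb) + n_ab     # minor allele count
  n2 <- 2 * n - n1
  hets <- seq(n1 %% 2, min(n1, n2), by = 2)
  probs <- sapply(hets, function(h) {
    choose(n, h) * choose(n - h, (n1 - h) / 2) * 2^h /
      choose(2 * n, n1)
  })
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= obs + 1e-12])
}

# Two-generation pedigree with a configurable number of full-sib pairs.
sib_pedigree <- function(n_pairs, sibs = 2L) {
  sires <- sprintf("S%02d", seq_len(n_pairs))
  dams <- sprintf("D%02d", seq_len(n_pairs))
  off <- sprintf("O%03d", seq_len(n_pairs * sibs))
  data.frame(
    id = c(sires, dams, off),
    sire = c(rep(NA, 2 * n_pairs), rep(sires, each = sibs)),
    dam = c(rep(NA, 2 * n_pairs), rep(dams, each = sibs)),
    birth_year = c(rep(2000L, 2 * n_pairs), rep(2004L, n_pairs * sibs)),
    phenotyped = c(rep(FALSE, 2 * n_pairs), rep(TRUE, n_pairs * sibs)),
    stringsAsFactors = FALSE
  )
}
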