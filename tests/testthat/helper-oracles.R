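# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles and share no code with R/.

# Hand-coded IRLS for the quasi-binomial GLM with logit link: returns
# slope, Pearson dispersion, and a two-sided p from a t reference.
oracle_irls_quasibinomial <- function(y, x, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, as.numeric(x))
  beta <- c(stats::qlogis(mean(y)), 0)
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    XtWX <- t(X) %*% (W * X)
    beta_new <- solve(XtWX, t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  n <- length(y)
  phi <- sum((y - mu)^2 / (mu * (1 - mu))) / (n - 2)
  XtWX <- t(X) %*% ((mu * (1 - mu)) * X)
  se <- sqrt(diag(solve(XtWX)) * phi)
  tval <- beta[2] / se[2]
  list(slope = unname(beta[2]), dispersion = phi,
       p = 2 * stats::pt(-abs(tval), n - 2))
}

# Exhaustive two-sided rank-sum p-value by enumerating every assignment of
# the pooled observations to the two groups (no ties assumed).
oracle_ranksum_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Tie-corrected Kruskal-Wallis H from the rank-sum definition.
oracle_kw <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Benjamini-Hochberg by direct definition (step-up).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# small synthetic meth_matrix used across tests
make_toy_matrix <- function(n = 6, J = 4, seed = 1, chrom = NULL) {
  set.seed(seed)
  beta <- matrix(runif(n * J, 0.1, 0.9), n, J,
                 dimnames = list(paste0("s", seq_len(n)),
                                 paste0("L", seq_len(J))))
  detp <- matrix(0, n, J, dimnames = dimnames(beta))
  if (is.null(chrom)) chrom <- rep("1", J)
  ann <- data.frame(locus = colnames(beta),
                    gene = paste0("G", seq_len(J)),
                    chromosome = chrom, stringsAsFactors = FALSE)
  meth_matrix(beta, detp, ann)
}
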