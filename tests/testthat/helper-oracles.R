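# Independent oracles, deliberately written along different routes than the
# package implementations.

# Cohen's kappa by explicit double loop over categories
brute_force_kappa <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  k <- nrow(tab)
  po <- 0; pe <- 0
  for (i in seq_len(k)) {
    po <- po + tab[i, i] / n
    ri <- 0; ci <- 0
    for (j in seq_len(k)) { ri <- ri + tab[i, j]; ci <- ci + tab[j, i] }
    pe <- pe + (ri / n) * (ci / n)
  }
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

# ICC(1,1) through stats::aov on the long layout
aov_icc <- function(m) {
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(nrow(m)), ncol(m))))
  ms <- summary(stats::aov(y ~ subj, data = long))[[1]]$"Mean Sq"
  msb <- ms[1]; msw <- ms[2]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

# delta-method variance of kappa via numeric gradient and the multinomial
# covariance of the cell proportions
numeric_kappa_var <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  p <- as.vector(tab) / n
  kap_of <- function(pv) {
    m <- matrix(pv, nrow(tab))
    po <- sum(diag(m)); pe <- sum(rowSums(m) * colSums(m))
    (po - pe) / (1 - pe)
  }
  eps <- 1e-6
  g <- vapply(seq_along(p), function(i) {
    up <- p; up[i] <- up[i] + eps
    dn <- p; dn[i] <- dn[i] - eps
    (kap_of(up) - kap_of(dn)) / (2 * eps)
  }, numeric(1))
  Sigma <- (diag(p) - tcrossprod(p)) / n
  drop(t(g) %*% Sigma %*% g)
}

# random k x k count table with all-positive marginals
random_table <- function(k, n = 200) {
  repeat {
    tab <- matrix(stats::rpois(k * k, lambda = stats::runif(k * k, 0.5, 8)),
                  k, k)
    if (sum(tab) >= k && all(rowSums(tab) + colSums(tab) > 0)) return(tab)
  }
}

# minimal hand-built rating table: every PEDro item present, chosen CROB
# columns; other CROB columns default to not_assessed
make_records <- function(trial_id, review_id, crob = list(), pedro = list()) {
  n <- length(trial_id)
  df <- data.frame(trial_id = trial_id, review_id = review_id,
                   stringsAsFactors = FALSE)
  for (nm in names(crob)) df[[nm]] <- crob[[nm]]
  defaults <- stats::setNames(rep(list(rep(1L, n))), NULL)
  for (it in pedro_items()$item)
    df[[it]] <- if (it %in% names(pedro)) as.integer(pedro[[it]]) else rep(1L, n)
  as_trial_ratings(df)
}
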