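# Independent oracles, kept deliberately naive.

# Classical sums-of-squares decomposition of a balanced three-way factorial,
# computed directly from cell/marginal means (no model fitting).
anova_ss_oracle <- function(tab, factors = c("side", "parcel", "diagnosis")) {
  y <- tab$value
  f <- lapply(tab[factors], factor)
  names(f) <- factors
  grand <- mean(y)
  mean_by <- function(which) {
    m <- tapply(y, f[which], mean)
    m[do.call(cbind, lapply(f[which], as.integer))]
  }
  ma <- lapply(factors, function(a) mean_by(a))
  names(ma) <- factors
  pairs <- utils::combn(factors, 2L, simplify = FALSE)
  mab <- lapply(pairs, function(p) mean_by(p))
  names(mab) <- vapply(pairs, paste, "", collapse = ":")
  mabc <- mean_by(factors)
  ss <- c()
  for (a in factors) ss[a] <- sum((ma[[a]] - grand)^2)
  for (p in pairs) {
    nm <- paste(p, collapse = ":")
    ss[nm] <- sum((mab[[nm]] - ma[[p[1]]] - ma[[p[2]]] + grand)^2)
  }
  nm3 <- paste(factors, collapse = ":")
  ss[nm3] <- sum((mabc - mab[[paste(factors[c(1, 2)], collapse = ":")]] -
                    mab[[paste(factors[c(1, 3)], collapse = ":")]] -
                    mab[[paste(factors[c(2, 3)], collapse = ":")]] +
                    ma[[factors[1]]] + ma[[factors[2]]] + ma[[factors[3]]] -
                    grand)^2)
  ss_err <- sum((y - mabc)^2)
  df1 <- c()
  nl <- vapply(f, nlevels, integer(1))
  for (a in factors) df1[a] <- nl[a] - 1L
  for (p in pairs) df1[paste(p, collapse = ":")] <- prod(nl[p] - 1L)
  df1[nm3] <- prod(nl - 1L)
  df_err <- length(y) - prod(nl)
  Fv <- (ss / df1) / (ss_err / df_err)
  list(ss = ss, df1 = df1, ss_err = ss_err, df_err = df_err, F = Fv,
       p = stats::pf(Fv, df1, df_err, lower.tail = FALSE))
}

# exhaustive per-voxel argmax with the fixed tie rule (loop, no vectorization)
classify_oracle <- function(value_matrix) {
  n <- nrow(value_matrix)
  out <- integer(n)
  for (i in seq_len(n)) {
    v <- value_matrix[i, ]
    if (all(v <= 0)) { out[i] <- 0L; next }
    best <- 1L
    for (k in seq_along(v)) if (v[k] > v[best]) best <- k
    out[i] <- best
  }
  out
}
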