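# Group-level inference: full-factorial three-way ANOVA
# (side x parcel x diagnosis) per measure with Type III sums of squares and
# partial eta-squared, plus Bonferroni-adjusted pairwise post-hoc contrasts
# on estimated marginal means.

check_design <- function(tab, factors) {
  for (f in factors) {
    if (!f %in% names(tab)) stop("missing factor column: ", f)
    if (length(unique(tab[[f]])) < 2L)
      stop("factor '", f, "' has fewer than 2 levels")
  }
  cells <- table(lapply(tab[factors], factor))
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    nm <- mapply(function(d, i) dimnames(cells)[[d]][i], seq_along(idx), idx)
    stop("empty design cell: ", paste(factors, nm, sep = "=", collapse = ", "))
  }
  invisible(tab)
}

fit_cell_model <- function(tab, measure, factors) {
  tab <- as.data.frame(tab)
  tab <- tab[tab$measure == measure, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for measure '", measure, "'")
  for (f in factors) tab[[f]] <- factor(tab[[f]])
  check_design(tab, factors)
  fml <- stats::as.formula(paste("value ~", paste(factors, collapse = " * ")))
  ctr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  mod <- stats::lm(fml, data = tab, contrasts = ctr)
  list(model = mod, data = tab)
}

#' Full-factorial fixed-effects ANOVA with Type III sums of squares
#'
#' Fits `value ~ f1 * f2 * f3` on the long-format records for one measure
#' (sum-to-zero contrasts, Type III sums of squares, appropriate for the
#' unbalanced two-diagnosis design) and reports per term the F statistic,
#' degrees of freedom, p-value and partial eta-squared
#' (SS_effect / (SS_effect + SS_error)). A saturated fit with zero residual
#' sum of squares reports F = Inf (p = 0) for terms with positive SS.
#'
#' @param tab long-format data.frame with columns `measure`, `value` and the
#'   factor columns; every design cell must be populated.
#' @param measure which measure to analyse (rows with `measure == measure`).
#' @param factors character vector of factor column names.
#' @param ss_type "III" (default) or "I" (sequential; classical balanced
#'   decomposition).
#' @return an `anova_result` data.frame: term, df1, df2, ss, F, p,
#'   partial_eta2, plus attributes `residual_ss` and `residual_df`.
#' @export
fit_anova <- function(tab, measure, factors = c("side", "parcel", "diagnosis"),
                      ss_type = c("III", "I")) {
  ss_type <- match.arg(ss_type)
  fit <- fit_cell_model(tab, measure, factors)
  rss <- sum(stats::residuals(fit$model)^2)
  saturated <- rss <= .Machine$double.eps^0.5 *
    max(sum(fit$data$value^2), 1)
  if (ss_type == "III" && !saturated) {
    a <- car::Anova(fit$model, type = 3, singular.ok = TRUE)
    a <- a[!rownames(a) %in% c("(Intercept)"), , drop = FALSE]
  } else {
    # sequential SS; with zero residual variance (or on balanced designs)
    # it coincides with the Type III decomposition
    a <- suppressWarnings(stats::anova(fit$model))
  }
  res_row <- rownames(a) == "Residuals"
  ss_err <- a[res_row, "Sum Sq"]
  df_err <- a[res_row, "Df"]
  terms <- rownames(a)[!res_row]
  ss <- a[!res_row, "Sum Sq"]
  df1 <- a[!res_row, "Df"]
  if (df_err > 0 && !saturated) {
    mse <- ss_err / df_err
    Fv <- (ss / df1) / mse
    p <- stats::pf(Fv, df1, df_err, lower.tail = FALSE)
  } else {
    # saturated fit: terms whose SS is numerical dust are null effects
    ss[ss <= max(sum(ss), 1) * 1e-12] <- 0
    Fv <- ifelse(ss > 0, Inf, 0)
    p <- ifelse(ss > 0, 0, 1)
    ss_err <- 0
  }
  eta <- ifelse(ss + ss_err > 0, ss / (ss + ss_err), 0)
  out <- data.frame(term = terms, df1 = df1, df2 = df_err, ss = ss,
                    F = Fv, p = p, partial_eta2 = eta,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "residual_ss") <- ss_err
  attr(out, "residual_df") <- df_err
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Bonferroni-adjusted pairwise post-hoc comparisons on marginal means
#'
#' Estimated marginal means per level of `factor` are unweighted averages
#' of the full-factorial cell means (the convention of common commercial
#' ANOVA software); pairwise differences are tested with the pooled
#' residual MSE of the full model and Bonferroni-adjusted over the
#' `choose(k, 2)` pairs.
#'
#' @inheritParams fit_anova
#' @param factor which factor's levels to compare.
#' @param alpha significance level for the `significant` flag.
#' @return a `posthoc_result` data.frame: level1, level2, diff
#'   (level1 - level2), se, t, df, p, p_bonferroni, significant.
#' @export
posthoc_bonferroni <- function(tab, factor, measure,
                               factors = c("side", "parcel", "diagnosis"),
                               alpha = 0.05) {
  stopifnot(factor %in% factors)
  fit <- fit_cell_model(tab, measure, factors)
  d <- fit$data
  mod <- fit$model
  df_err <- stats::df.residual(mod)
  mse <- sum(stats::residuals(mod)^2) / df_err
  others <- setdiff(factors, factor)
  cell <- interaction(d[c(factor, others)], drop = FALSE)
  cm <- tapply(d$value, d[c(factor, others)], mean)        # cell means
  cn <- tapply(d$value, d[c(factor, others)], length)      # cell sizes
  lev <- levels(d[[factor]])
  k <- length(lev)
  ncells_per_level <- prod(dim(cm)[-1])
  emm <- apply(cm, 1L, mean)                               # unweighted EMMs
  var_emm <- apply(1 / cn, 1L, sum) * mse / ncells_per_level^2
  pairs <- utils::combn(k, 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    diff <- emm[i1] - emm[i2]
    se <- sqrt(var_emm[i1] + var_emm[i2])
    tv <- if (se > 0) diff / se else ifelse(diff == 0, 0, Inf * sign(diff))
    p <- 2 * stats::pt(-abs(tv), df_err)
    data.frame(level1 = lev[i1], level2 = lev[i2], diff = diff, se = se,
               t = tv, df = df_err, p = p,
               p_bonferroni = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Simulate a long-format quantitative table with injected effects
#'
#' Generates subject x side x parcel records with per-parcel population
#' means plus optional diagnosis and side shifts and i.i.d. Gaussian noise;
#' used for power and calibration studies of the inference layer. The
#' default means and SD mirror the observed midbrain parcel-density pattern
#' (sensorimotor much denser than the nearly-equal limbic and prefrontal
#' territories, between-subject SD at the upper end of the observed range).
#'
#' @param parcel_means named numeric vector (names = parcel labels).
#' @param sd residual SD of the measure.
#' @param n_hc,n_sz group sizes.
#' @param diagnosis_effect additive shift for the SZ group.
#' @param side_effect additive shift for the right side.
#' @param sides side labels to generate; use a single side for
#'   subject-level (side-free) records.
#' @param measure measure name stamped into the records.
#' @param rng_seed integer seed.
#' @return long data.frame: subject, diagnosis, side, parcel, measure, value.
#' @export
simulate_quant_table <- function(parcel_means = c(limbic = 25, prefrontal = 27,
                                                  sensorimotor = 41.5),
                                 sd = 12, n_hc = 24L, n_sz = 30L,
                                 diagnosis_effect = 0, side_effect = 0,
                                 sides = c("L", "R"),
                                 measure = "sdi", rng_seed = 1L) {
  set.seed(rng_seed)
  n <- n_hc + n_sz
  g <- expand.grid(parcel = names(parcel_means), side = sides,
                   subject = sprintf("sub-%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  g$diagnosis <- ifelse(match(g$subject, sprintf("sub-%03d", seq_len(n))) <= n_hc,
                        "HC", "SZ")
  g$measure <- measure
  g$value <- parcel_means[g$parcel] +
    ifelse(g$diagnosis == "SZ", diagnosis_effect, 0) +
    ifelse(g$side == "R", side_effect, 0) +
    stats::rnorm(nrow(g), 0, sd)
  rownames(g) <- NULL
  g[c("subject", "diagnosis", "side", "parcel", "measure", "value")]
}

#' Group-level analysis report over the cohort metrics table
#'
#' For each measure present, fits the three-way ANOVA and the post-hoc
#' contrasts for every factor, and tabulates mean and SD per
#' diagnosis x side x parcel cell (12 rows per measure in the standard
#' 2 x 2 x 3 design).
#'
#' @param tab long-format metrics table (subject, diagnosis, side, parcel,
#'   measure, value).
#' @param factors factor columns of the design.
#' @param alpha significance level.
#' @return a `group_report`: per-measure list(anova, posthoc, cells).
#' @export
run_group_analysis <- function(tab, factors = c("side", "parcel", "diagnosis"),
                               alpha = 0.05) {
  measures <- unique(tab$measure)
  out <- list()
  for (m in measures) {
    sub <- tab[tab$measure == m, , drop = FALSE]
    cells <- stats::aggregate(value ~ parcel + diagnosis + side, data = sub,
                              FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                                  n = length(v)))
    cells <- do.call(data.frame, cells)
    names(cells) <- c("parcel", "diagnosis", "side", "mean", "sd", "n")
    ph <- lapply(stats::setNames(factors, factors), function(f)
      posthoc_bonferroni(tab, f, m, factors = factors, alpha = alpha))
    out[[m]] <- list(anova = fit_anova(tab, m, factors = factors),
                     posthoc = ph, cells = cells)
  }
  structure(out, class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  for (m in names(x)) {
    cat("== measure:", m, "==\n")
    a <- x[[m]]$anova
    for (i in seq_len(nrow(a))) {
      cat(sprintf("  %-24s F(%d,%d) = %8.3f  p = %.4g  eta2p = %.3f\n",
                  a$term[i], a$df1[i], a$df2[i], a$F[i], a$p[i],
                  a$partial_eta2[i]))
    }
  }
  invisible(x)
}
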