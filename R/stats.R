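#' Kolmogorov-Smirnov normality screen
#'
#' Tests a sample against a normal distribution with the sample's own mean
#' and SD (the Lilliefors caveat — estimated parameters make the nominal KS
#' p value conservative — is accepted and documented). Samples smaller than
#' 8, or degenerate constant samples, are routed non-normal with a warning
#' rather than tested.
#'
#' @param x numeric sample.
#' @param alpha decision level (default .05); `normal` iff p >= alpha.
#' @return list with `p_value` and `normal` (logical).
#' @export
normality_screen <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 8) {
    warning("sample size < 8: routed non-normal without testing")
    return(list(p_value = NA_real_, normal = FALSE))
  }
  if (sd(x) == 0) return(list(p_value = 0, normal = FALSE))
  p <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  list(p_value = p, normal = p >= alpha)
}

#' Common language effect size
#'
#' The probability that a value sampled at random from `a` exceeds a value
#' sampled at random from `b`, computed by full pairwise enumeration with
#' ties counted half: `(#(a > b) + 0.5 * #(a == b)) / (n_a * n_b)`.
#'
#' @param a,b numeric samples (non-empty).
#' @return probability in `[0, 1]`; `cles(a, b) + cles(b, a) == 1` always.
#' @export
cles <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  mean(cmp)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' usual (n-1)-weighted pooled SD.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return effect size; `NA` (with a warning) when the pooled SD is zero.
#' @export
cohen_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    warning("zero pooled SD: Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Mann-Whitney U test (mid-ranks; exact by enumeration for small samples)
#'
#' Computes the U statistic from mid-ranks of the combined sample. For
#' `n_a + n_b <= exact_max` the two-sided p value is exact: the null
#' distribution of U is enumerated over all group assignments of the
#' observed combined values (valid with ties). Larger samples use the
#' normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max combined-size threshold for exact enumeration.
#' @return list with `U` (for sample `a`), `p_value` (two-sided), `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 20) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= exact_max) {
    # exact null: U over all choose(na+nb, na) assignments of the pooled values
    idx <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= U + eps), mean(u_all >= U - eps))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(c(a, b))
    n <- na + nb
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = U, p_value = min(p, 1), method = method)
}

#' Route and run a two-group comparison
#'
#' The comparison protocol applied to every kinetic feature: both groups are
#' screened for normality (KS against a fitted normal); if both pass, an F
#' test for homoscedasticity chooses between a pooled-variance and a Welch
#' two-sided t test, and Cohen's d is reported; otherwise a two-sided
#' Mann-Whitney test with the common language effect size. Significance is
#' declared at two-sided alpha = .05 on the raw p value (no multiplicity
#' correction, by design — effect sizes accompany every p value).
#'
#' @param a,b numeric samples (group A conventionally typical development,
#'   group B developmental disability).
#' @param feature label carried into the result.
#' @param alpha significance level.
#' @return list of class `comparison_result`: `feature`, `n_a`, `n_b`,
#'   `routed_test`, `normality_p_a`, `normality_p_b`, `variance_test_p`,
#'   `p_value`, `effect_size_kind`, `effect_size_value`, `significant`.
#' @export
route_and_test <- function(a, b, feature = "feature", alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  small <- length(a) < 8 || length(b) < 8
  if (small) {
    norm_a <- list(p_value = NA_real_, normal = FALSE)
    norm_b <- list(p_value = NA_real_, normal = FALSE)
  } else {
    norm_a <- normality_screen(a, alpha)
    norm_b <- normality_screen(b, alpha)
  }
  var_p <- NA_real_
  if (norm_a$normal && norm_b$normal) {
    var_p <- stats::var.test(a, b)$p.value
    tt <- stats::t.test(a, b, var.equal = var_p >= alpha)
    p <- tt$p.value
    es <- cohen_d(a, b)
    kind <- "cohen_d"
    routed <- "t_test"
  } else {
    mw <- mann_whitney(a, b)
    p <- mw$p_value
    es <- cles(a, b)
    kind <- "cles"
    routed <- "mann_whitney"
  }
  structure(list(feature = feature, n_a = length(a), n_b = length(b),
                 routed_test = routed,
                 normality_p_a = norm_a$p_value, normality_p_b = norm_b$p_value,
                 variance_test_p = var_p, p_value = p,
                 effect_size_kind = kind, effect_size_value = es,
                 significant = is.finite(p) && p < alpha),
            class = "comparison_result")
}

#' Chi-square test with an eta-squared-style effect size
#'
#' Pearson chi-square (no continuity correction, so the statistic matches
#' the textbook closed form) on a contingency table, reporting
#' `eta^2 = chi^2 / N` as the effect size for categorical contrasts.
#'
#' @param tab matrix of non-negative counts (typically 2x2).
#' @return list with `chi_square`, `p_value`, `eta_squared`, `degenerate`
#'   (`TRUE`, with `NA` p, when a margin is zero).
#' @export
chi_square_with_eta <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0))
  n <- sum(tab)
  if (n == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi_square = NA_real_, p_value = NA_real_,
                eta_squared = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi_square = unname(ct$statistic), p_value = ct$p.value,
       eta_squared = unname(ct$statistic) / n, degenerate = FALSE)
}

#' Compare every kinetic feature between two cohorts
#'
#' Runs [route_and_test()] per feature column and emits a report shaped
#' like the published movement-feature comparison tables: group medians and
#' IQRs, the routed test, the two-sided p value, and the effect size.
#'
#' @param features_a,features_b data.frames with aligned numeric feature
#'   columns (e.g. two label subsets of [features_table()] output).
#' @param features which columns to compare; defaults to the kinetic
#'   feature battery present in both inputs.
#' @param alpha significance level.
#' @return data.frame of class `comparison_table`, one row per feature, with
#'   columns `feature`, `median_a`, `iqr_a`, `median_b`, `iqr_b`,
#'   `routed_test`, `p_value`, `effect_size_kind`, `effect_size`,
#'   `significant`. All-missing features are skipped with a message.
#' @export
compare_all_features <- function(features_a, features_b,
                                 features = NULL, alpha = 0.05) {
  if (is.null(features)) {
    features <- intersect(feature_names(),
                          intersect(names(features_a), names(features_b)))
  }
  rows <- list()
  for (f in features) {
    a <- features_a[[f]]; b <- features_b[[f]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0 || length(b) == 0) {
      message("feature '", f, "' all-missing in one group: skipped")
      next
    }
    cr <- route_and_test(a, b, feature = f, alpha = alpha)
    rows[[length(rows) + 1]] <- data.frame(
      feature = f,
      median_a = median(a), iqr_a = unname(diff(quantile(a, c(.25, .75)))),
      median_b = median(b), iqr_b = unname(diff(quantile(b, c(.25, .75)))),
      routed_test = cr$routed_test, p_value = cr$p_value,
      effect_size_kind = cr$effect_size_kind,
      effect_size = cr$effect_size_value,
      significant = cr$significant,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), median_a = numeric(0),
               iqr_a = numeric(0), median_b = numeric(0), iqr_b = numeric(0),
               routed_test = character(0), p_value = numeric(0),
               effect_size_kind = character(0), effect_size = numeric(0),
               significant = logical(0))
  class(out) <- c("comparison_table", class(out))
  out
}
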