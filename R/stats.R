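#' @importFrom stats pchisq wilcox.test cor cor.test median setNames
NULL

#' D'Agostino-Pearson omnibus normality test
#'
#' K-squared statistic combining the z-transformed sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe-Glynn 1983), referred to a
#' chi-square distribution with 2 degrees of freedom.
#'
#' @param x Numeric sample, n >= 8 (small-sample validity floor of the
#'   z-approximations).
#' @return List with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m) ^ 2)
  if (m2 < 1e-20) stop("degenerate (constant) sample")
  g1 <- mean((x - m) ^ 3) / m2 ^ 1.5
  b2 <- mean((x - m) ^ 4) / m2 ^ 2

  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n ^ 2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha) ^ 2 + 1))

  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1) ^ 2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n ^ 2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1 ^ 2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4)))) ^ (1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1 ^ 2 + z2 ^ 2
  list(statistic = k2, p.value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Paired Wilcoxon test over channels
#'
#' Nonparametric before/after comparison of the 16 per-channel AUC values.
#' The paired design mandates the signed-rank form (the default); zero
#' differences are dropped, and for small samples without ties the exact
#' signed-rank distribution is used. The two-sample rank-sum form is
#' available for literal replication.
#'
#' @param auc_s0,auc_sf Equal-length numeric vectors paired by channel.
#' @param method `"signed_rank"` (paired) or `"rank_sum"`.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return p-value.
#' @export
wilcoxon_paired <- function(auc_s0, auc_sf,
                            method = c("signed_rank", "rank_sum"),
                            alternative = "two.sided") {
  method <- match.arg(method)
  stopifnot(length(auc_s0) == length(auc_sf))
  if (method == "signed_rank") {
    d <- auc_sf - auc_s0
    d <- d[d != 0]
    if (length(d) == 0) {
      warning("all paired differences are zero")
      return(1)
    }
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    suppressWarnings(
      wilcox.test(d, alternative = alternative, exact = exact)$p.value)
  } else {
    suppressWarnings(
      wilcox.test(auc_sf, auc_s0, alternative = alternative)$p.value)
  }
}

#' Evaluate a therapy group: normality then nonparametric comparison
#'
#' Runs the D'Agostino-Pearson normality test on the AUC inputs (pooled
#' over both sessions by default), then the paired Wilcoxon comparison of
#' the 16 per-channel AUCs between the initial (S0) and final (Sf)
#' sessions. The null of no therapy effect (S0 = Sf) is rejected when
#' p < `alpha`.
#'
#' @param auc_s0,auc_sf Per-channel AUC vectors for each session.
#' @param group Group label.
#' @param alpha Significance level.
#' @param normality `"pooled"` (one test on the 2 x 16 values) or
#'   `"per_session"`.
#' @param method Comparison form, see [wilcoxon_paired()].
#' @return A `therapy_test_result`: `group`, `normality_p`, `p`, `decision`
#'   (`"difference"` / `"no difference"`), `alpha`, `method`.
#' @export
evaluate_therapy <- function(auc_s0, auc_sf, group = NULL, alpha = 0.05,
                             normality = c("pooled", "per_session"),
                             method = "signed_rank") {
  normality <- match.arg(normality)
  if (is.null(auc_s0) || is.null(auc_sf)) stop("both sessions are required")
  norm_p <- if (normality == "pooled") {
    dagostino_pearson(c(auc_s0, auc_sf))$p.value
  } else {
    c(S0 = dagostino_pearson(auc_s0)$p.value,
      Sf = dagostino_pearson(auc_sf)$p.value)
  }
  p <- wilcoxon_paired(auc_s0, auc_sf, method = method)
  structure(list(group = group, normality_p = norm_p, p = p,
                 decision = if (p < alpha) "difference" else "no difference",
                 alpha = alpha, method = method),
            class = "therapy_test_result")
}

#' Pairwise correlation screen
#'
#' Spearman rank correlations (Pearson behind a flag) between every pair of
#' columns, with per-pair p-values and significance flags at `alpha`.
#' Factors and character columns are integer-coded; constant columns yield
#' `NA` coefficients and are flagged.
#'
#' @param table Data frame, participants x variables.
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha Significance level.
#' @return A `correlation_screen`: `rho` and `p` matrices (symmetric,
#'   unit diagonal), `significant` data frame of flagged pairs,
#'   `constant` names of degenerate columns.
#' @export
correlation_screen <- function(table, method = c("spearman", "pearson"),
                               alpha = 0.05) {
  method <- match.arg(method)
  num <- as.data.frame(lapply(table, function(col) {
    if (is.numeric(col)) col else as.integer(factor(col))
  }))
  vars <- names(num)
  k <- length(vars)
  complete_pair <- function(i, j) {
    ok <- stats::complete.cases(num[[i]], num[[j]])
    list(x = num[[i]][ok], y = num[[j]][ok])
  }
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  constant <- vars[vapply(num, function(v) length(unique(v[!is.na(v)])) <= 1,
                          logical(1))]
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (vars[i] %in% constant || vars[j] %in% constant) next
    pr <- complete_pair(i, j)
    if (length(pr$x) < 3) next
    ct <- suppressWarnings(cor.test(pr$x, pr$y, method = method, exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  sig <- which(upper.tri(p) & p < alpha, arr.ind = TRUE)
  significant <- data.frame(var1 = vars[sig[, 1]], var2 = vars[sig[, 2]],
                            rho = rho[sig], p = p[sig],
                            stringsAsFactors = FALSE)
  structure(list(rho = rho, p = p, significant = significant,
                 constant = constant, method = method, alpha = alpha),
            class = "correlation_screen")
}

#' Per-group questionnaire effect summary
#'
#' For every group and instrument (THI, HADS-A, HADS-S), categorizes the S0
#' and Sf scores, labels each participant's change as positive / none /
#' negative, and reports integer-rounded percentages of the group size.
#'
#' @param cohort A `cohort` (see [simulate_cohort()]).
#' @return Data frame with columns `group`, `instrument`, `n`, `positive`,
#'   `none`, `negative` (percent).
#' @export
effect_summary <- function(cohort) {
  tab <- cohort_table(cohort)
  instruments <- list(
    THI = list(s0 = "thi_s0", sf = "thi_sf", cat = categorize_thi),
    `HADS-A` = list(s0 = "hads_a_s0", sf = "hads_a_sf", cat = categorize_hads),
    `HADS-S` = list(s0 = "hads_s_s0", sf = "hads_s_sf", cat = categorize_hads)
  )
  rows <- list()
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    if (nrow(sub) == 0) { warning("empty group ", g, " excluded"); next }
    for (ins in names(instruments)) {
      spec <- instruments[[ins]]
      labels <- mapply(function(s0, sf)
        categorize_effect(spec$cat(s0), spec$cat(sf)),
        sub[[spec$s0]], sub[[spec$sf]])
      counts <- table(factor(labels, levels = c("positive", "none", "negative")))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, instrument = ins, n = nrow(sub),
        positive = round(100 * counts[["positive"]] / nrow(sub)),
        none = round(100 * counts[["none"]] / nrow(sub)),
        negative = round(100 * counts[["negative"]] / nrow(sub)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
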