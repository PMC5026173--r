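#' Bland-Altman method agreement
#'
#' Agreement between two measurement techniques (e.g. non-slice-selective
#' versus slice-selective global signal intensity) via the mean bias of
#' paired differences and the 95% limits of agreement
#' `bias +/- 1.96 * sd(differences)` (sample SD; conventional 1.96
#' multiplier).
#'
#' @param a,b paired measurements (equal length, >= 2 pairs).
#' @param scale `"raw"` differences `a - b`, or `"percent_of_mean"`:
#'   `100 * (a - b) / ((a + b) / 2)`.
#' @return An object of class `bland_altman` with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_pairs`, `differences`, `means`, `scale`.
#' @export
bland_altman <- function(a, b, scale = c("raw", "percent_of_mean")) {
  scale <- match.arg(scale)
  .assert(length(a) == length(b), "a and b must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  .assert(length(a) >= 2L, "at least 2 complete pairs are required")
  d <- if (scale == "raw") a - b else 100 * (a - b) / ((a + b) / 2)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 n_pairs = length(d), differences = d,
                 means = (a + b) / 2, scale = scale),
            class = "bland_altman")
}

#' Two-sample t test
#'
#' Student's (pooled-variance) flavor by default, Welch available. The
#' degenerate case of zero variance in both groups is resolved by
#' convention: equal means give `t = 0, p = 1`; unequal means give an
#' infinite statistic and `p = 0`.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param flavor `"student"` or `"welch"`.
#' @return A list with `t`, `df`, `p_value` and `flavor`.
#' @export
two_sample_t <- function(a, b, flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  .assert(length(a) >= 2L && length(b) >= 2L, "each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                  flavor = flavor))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p_value = 0, flavor = flavor))
  }
  fit <- stats::t.test(a, b, var.equal = (flavor == "student"))
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, flavor = flavor)
}

#' Compare dose-response curves between groups
#'
#' Two-way analysis of variance of normalized global signal intensity with
#' factors group and cumulative dose (plus their interaction), followed by
#' per-dose group contrasts (Student's t) with Bonferroni correction (raw p
#' multiplied by the number of dose levels, capped at 1). Balanced designs
#' use the sequential (type I) decomposition, whose sums of squares
#' partition the total exactly; unbalanced designs fall back to type II
#' sums of squares.
#'
#' @param data data frame with columns `subject`, `group`, `dose`, `gs`
#'   (one row per subject x dose).
#' @param alpha significance threshold for the adjusted contrasts.
#' @return An object of class `dose_response_comparison` with fields
#'   `anova` (term table), `contrasts` (per-dose t, raw and adjusted p),
#'   `group_summary` (per group x dose mean and SD), `balanced`, `alpha`.
#' @export
compare_dose_response <- function(data, alpha = 0.05) {
  .assert(is.data.frame(data) &&
            all(c("subject", "group", "dose", "gs") %in% names(data)),
          "data must have columns subject, group, dose, gs")
  data <- data[!is.na(data$gs), , drop = FALSE]
  data$group <- factor(data$group)
  data$dose_f <- factor(data$dose)
  .assert(nlevels(data$group) >= 2L, "at least 2 groups are required")
  counts <- table(data$group, data$dose_f)
  .assert(all(counts > 0), "mismatched dose grids: every group needs every dose")
  .assert(any(counts >= 2), "at least one group needs >= 2 subjects per dose")
  balanced <- length(unique(as.vector(counts))) == 1L

  fit <- stats::lm(gs ~ group * dose_f, data = data)
  tab <- if (balanced) stats::anova(fit) else car::Anova(fit, type = 2)
  anova_df <- data.frame(term = trimws(rownames(tab)),
                         df = tab[["Df"]],
                         sum_sq = tab[["Sum Sq"]],
                         F = tab[["F value"]],
                         p = tab[["Pr(>F)"]],
                         stringsAsFactors = FALSE)

  doses <- sort(unique(data$dose))
  contrasts <- NULL
  if (nlevels(data$group) == 2L) {
    g <- levels(data$group)
    rows <- lapply(doses, function(d) {
      a <- data$gs[data$group == g[1] & data$dose == d]
      b <- data$gs[data$group == g[2] & data$dose == d]
      if (length(a) >= 2L && length(b) >= 2L) {
        tt <- two_sample_t(a, b, flavor = "student")
        data.frame(dose = d, t = tt$t, p_raw = tt$p_value)
      } else {
        data.frame(dose = d, t = NA_real_, p_raw = NA_real_)
      }
    })
    contrasts <- do.call(rbind, rows)
    contrasts$p_adj <- pmin(1, contrasts$p_raw * length(doses))
    contrasts$significant <- !is.na(contrasts$p_adj) & contrasts$p_adj < alpha
  }

  group_summary <- do.call(rbind, lapply(split(data, list(data$group, data$dose_f)),
    function(d) data.frame(group = d$group[1], dose = d$dose[1],
                           n = nrow(d), mean_gs = mean(d$gs),
                           sd_gs = stats::sd(d$gs))))
  rownames(group_summary) <- NULL

  structure(list(anova = anova_df, contrasts = contrasts,
                 group_summary = group_summary, balanced = balanced,
                 alpha = alpha),
            class = "dose_response_comparison")
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$scale == "percent_of_mean") "%" else ""
  cat(sprintf("<bland_altman> n = %d: bias %.3g%s, limits of agreement [%.3g, %.3g]%s\n",
              x$n_pairs, x$bias, unit, x$loa_low, x$loa_high, unit))
  invisible(x)
}

#' @export
print.dose_response_comparison <- function(x, ...) {
  cat("<dose_response_comparison>\n")
  print(x$anova, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat(sprintf("Per-dose contrasts (Bonferroni-adjusted, alpha = %g):\n", x$alpha))
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}
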