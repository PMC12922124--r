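#' Biomarker panel constructor
#'
#' A panel holds replicate measurements of one antioxidant endpoint
#' (e.g. total phenolic content, DPPH or hydroxyl-radical scavenging,
#' or CAT/GST/GPx/SOD activity) across exposure treatments. When a
#' `tech_replicate` column is present, technical replicates are averaged
#' into their biological replicate first, so downstream tests see one
#' value per biological replicate and are not pseudo-replicated.
#'
#' @param data Data frame with columns `treatment`, `value`, and
#'   optionally `bio_replicate` and `tech_replicate`.
#' @param endpoint Endpoint label.
#' @param unit Measurement unit label (free text).
#' @return Object of class `biomarker_panel` (a data frame with
#'   attributes `endpoint` and `unit`).
#' @export
biomarker_panel <- function(data, endpoint = "endpoint", unit = "") {
  stopifnot(is.data.frame(data), all(c("treatment", "value") %in% names(data)))
  if (!is.numeric(data$value)) stop("value must be numeric", call. = FALSE)
  if ("tech_replicate" %in% names(data) && "bio_replicate" %in% names(data)) {
    agg <- stats::aggregate(value ~ treatment + bio_replicate, data = data,
                            FUN = mean)
    data <- agg[order(agg$treatment, agg$bio_replicate), ]
  }
  if (length(unique(data$treatment)) < 2L)
    stop("panel needs >= 2 treatments", call. = FALSE)
  structure(data, endpoint = endpoint, unit = unit,
            class = c("biomarker_panel", "data.frame"))
}

#' Normality and variance-homogeneity checks for a panel
#'
#' Per-treatment Shapiro-Wilk tests plus Levene's test (via
#' `car::leveneTest`, centred on the median) across treatments, the
#' standard assumption screen before a parametric ANOVA. Groups with
#' fewer than 3 values or zero within-group variance are degenerate for
#' normality testing and are reported with `NA` p-values and a flag
#' rather than an error.
#'
#' @param panel A [biomarker_panel()].
#' @param alpha Flagging level (default 0.05).
#' @return List of class `assumption_report`: `shapiro` (data frame:
#'   treatment, statistic, p_value, degenerate), `levene` (statistic,
#'   df, p_value), `violations` (character vector of flags).
#' @export
assumption_checks <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "biomarker_panel"))
  groups <- split(panel$value, panel$treatment)
  shapiro <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (length(v) < 3L || stats::sd(v) == 0)
      return(data.frame(treatment = g, statistic = NA_real_,
                        p_value = NA_real_, degenerate = TRUE))
    sw <- stats::shapiro.test(v)
    data.frame(treatment = g, statistic = unname(sw$statistic),
               p_value = sw$p.value, degenerate = FALSE)
  }))
  lev <- car::leveneTest(panel$value, factor(panel$treatment))
  levene <- list(statistic = lev[1, "F value"],
                 df = c(lev[1, "Df"], lev[2, "Df"]),
                 p_value = lev[1, "Pr(>F)"])
  violations <- character(0)
  if (any(shapiro$degenerate))
    violations <- c(violations, "degenerate for normality testing")
  if (any(!is.na(shapiro$p_value) & shapiro$p_value < alpha))
    violations <- c(violations, "non-normal group(s)")
  if (!is.na(levene$p_value) && levene$p_value < alpha)
    violations <- c(violations, "heterogeneous variances")
  structure(list(shapiro = shapiro, levene = levene,
                 violations = violations, alpha = alpha),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Shapiro-Wilk per treatment:\n")
  print(x$shapiro, row.names = FALSE)
  cat(sprintf("Levene: F = %.4g (df %d, %d), p = %.3g\n",
              x$levene$statistic, x$levene$df[1], x$levene$df[2],
              x$levene$p_value))
  if (length(x$violations))
    cat("flags:", paste(x$violations, collapse = "; "), "\n")
  invisible(x)
}

#' One-way ANOVA with Bonferroni post hoc tests
#'
#' Fits the one-way ANOVA across treatments and, when the omnibus test
#' is significant at `alpha`, runs all pairwise two-sided t-tests
#' (unpooled) with Bonferroni correction: raw p multiplied by the number
#' of comparisons and capped at 1.
#'
#' @param panel A [biomarker_panel()].
#' @param alpha Significance level gating the post hoc step.
#' @return List of class `anova_report`: `f`, `df` (between, within),
#'   `p_value`, `pairwise` (data frame: group1, group2, p_raw, p_adj;
#'   `NULL` when the omnibus test is not significant).
#' @export
anova_bonferroni <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "biomarker_panel"))
  groups <- split(panel$value, panel$treatment)
  if (length(groups) < 2L) stop("nothing to compare", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("each treatment needs >= 2 replicates", call. = FALSE)
  fit <- stats::aov(value ~ factor(treatment), data = panel)
  tab <- summary(fit)[[1]]
  f <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
  df <- c(between = tab[1, "Df"], within = tab[2, "Df"])
  if (is.na(f)) { f <- 0; p <- 1 }  # zero within AND between variance
  pairwise <- NULL
  if (p < alpha) {
    nms <- names(groups)
    prs <- utils::combn(nms, 2)
    m <- ncol(prs)
    pairwise <- do.call(rbind, lapply(seq_len(m), function(i) {
      g1 <- groups[[prs[1, i]]]; g2 <- groups[[prs[2, i]]]
      praw <- if (stats::sd(g1) == 0 && stats::sd(g2) == 0)
        as.numeric(mean(g1) == mean(g2))  # identical constants vs distinct
      else stats::t.test(g1, g2)$p.value
      data.frame(group1 = prs[1, i], group2 = prs[2, i], p_raw = praw)
    }))
    pairwise$p_adj <- pmin(1, pairwise$p_raw * m)
  }
  structure(list(f = f, df = df, p_value = p, pairwise = pairwise,
                 alpha = alpha),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$f, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Bonferroni pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  } else cat("omnibus not significant; no post hoc tests\n")
  invisible(x)
}

#' Pearson correlation matrix across endpoints
#'
#' Correlates endpoints over their treatment-level means: each panel is
#' collapsed to one mean per treatment, panels are aligned on shared
#' treatments, and pairwise Pearson R is computed. A zero-variance
#' endpoint yields `NA` against everything (its correlation is
#' undefined); the diagonal is always 1.
#'
#' @param panels Named list of [biomarker_panel()] objects measured over
#'   a common set of treatments.
#' @return Symmetric numeric matrix of Pearson R with unit diagonal,
#'   dimnames from the panel names.
#' @export
correlation_matrix <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 2L,
            !is.null(names(panels)), all(nzchar(names(panels))))
  means <- lapply(panels, function(p) {
    stopifnot(inherits(p, "biomarker_panel"))
    agg <- stats::aggregate(value ~ treatment, data = p, FUN = mean)
    stats::setNames(agg$value, agg$treatment)
  })
  common <- Reduce(intersect, lapply(means, names))
  if (length(common) < 3L)
    stop("need >= 3 shared treatments across panels", call. = FALSE)
  mat <- sapply(means, function(m) m[common])
  r <- suppressWarnings(stats::cor(mat, method = "pearson"))
  diag(r) <- 1
  r
}
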