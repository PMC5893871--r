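#' One-way ANOVA p-value per texture feature
#'
#' Fixed-effects one-way F test of each feature column against the tissue
#' class labels. Groups with zero within-group variance but distinct means
#' yield p = 0 (an infinite F) rather than an error, so degenerate synthetic
#' edge cases do not abort a report.
#'
#' @param table a \code{feature_table} (raw or z-scored; the F statistic is
#'   invariant to per-column affine maps, so normalization order does not
#'   matter).
#' @param grouping factor of class labels; defaults to \code{table$label}.
#' @param statistic return F statistics instead of p-values.
#' @return named numeric vector of raw p-values (or F statistics), one per
#'   feature column.
#' @export
anova_per_feature <- function(table, grouping = table$label,
                              statistic = FALSE) {
  g <- factor(grouping)
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  cols <- setdiff(names(table), c("sample_id", "label"))
  n <- length(g); k <- nlevels(g)
  st <- vapply(cols, function(cn) {
    y <- table[[cn]]
    gm <- tapply(y, g, mean)
    ssb <- sum(sizes * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    if (ssw == 0) {
      if (ssb == 0) return(c(F = 0, p = 1))   # all values identical
      return(c(F = Inf, p = 0))               # distinct means, no within var
    }
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    c(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
  }, c(F = 0, p = 0))
  if (statistic) st["F", ] else st["p", ]
}

#' Holm-Bonferroni step-down adjustment
#'
#' Thin validated wrapper over \code{stats::p.adjust(method = "holm")}: the
#' i-th smallest p-value is multiplied by (m - i + 1), the running maximum is
#' enforced and values are capped at 1.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Univariate significance report over the 24 texture features
#'
#' Runs the per-feature one-way ANOVA across tissue classes, applies the
#' Holm-Bonferroni correction over the full feature family (m = number of
#' features, 24 for the standard quantifier x octant grid) and flags features
#' with adjusted p below \code{alpha}.
#'
#' @inheritParams anova_per_feature
#' @param alpha familywise significance level (default 0.01).
#' @return object of class \code{stats_report}: data.frame with columns
#'   \code{feature}, \code{F}, \code{p_raw}, \code{p_adjusted},
#'   \code{neg_log10_adjusted}, \code{significant}; the group sizes, degrees
#'   of freedom and \code{alpha} are attached as attributes.
#' @export
significance_report <- function(table, grouping = table$label, alpha = 0.01) {
  p_raw <- anova_per_feature(table, grouping)
  f_stat <- anova_per_feature(table, grouping, statistic = TRUE)
  p_adj <- holm_bonferroni(p_raw)
  rep <- data.frame(feature = names(p_raw),
                    F = as.numeric(f_stat),
                    p_raw = as.numeric(p_raw),
                    p_adjusted = as.numeric(p_adj),
                    neg_log10_adjusted = -log10(pmax(p_adj, .Machine$double.xmin)),
                    significant = as.numeric(p_adj) < alpha,
                    row.names = NULL)
  g <- factor(grouping)
  structure(rep, class = c("stats_report", "data.frame"),
            alpha = alpha, m = length(p_raw),
            group_sizes = as.integer(table(g)),
            df = c(between = nlevels(g) - 1L,
                   within = length(g) - nlevels(g)))
}

#' @export
print.stats_report <- function(x, ...) {
  m <- attr(x, "m"); alpha <- attr(x, "alpha")
  cat(sprintf("Univariate ANOVA report: %d features, Holm-Bonferroni (m = %d), alpha = %g\n",
              nrow(x), m, alpha))
  cat(sprintf("  significant features: %d\n", sum(x$significant)))
  if (any(x$significant))
    cat("   ", paste(x$feature[x$significant], collapse = ", "), "\n")
  invisible(x)
}

#' Heatmap-style matrix of -log10 adjusted p-values
#'
#' Arranges the report's adjusted p-values as a quantifier x octant matrix for
#' plotting.
#'
#' @param report a \code{stats_report} over the 24-feature grid.
#' @return 3 x 8 numeric matrix (rows variance/entropy/energy, columns octant
#'   sub-bands).
#' @export
significance_matrix <- function(report) {
  q <- c("variance", "entropy", "energy")
  oct <- octant_keys()
  m <- matrix(NA_real_, 3, 8, dimnames = list(q, oct))
  for (i in q) for (j in oct) {
    row <- report$feature == paste(i, j, sep = "_")
    if (any(row)) m[i, j] <- report$neg_log10_adjusted[row]
  }
  m
}

#' @export
plot.stats_report <- function(x, ...) {
  m <- significance_matrix(x)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "octant sub-band",
                  ylab = "quantifier",
                  main = expression(-log[10] ~ "adjusted p"))
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, seq_len(nrow(m)), rownames(m))
  invisible(x)
}
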