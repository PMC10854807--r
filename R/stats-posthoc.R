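#' Fisher LSD post hoc comparisons for a within-subject factor
#'
#' Pairwise least-significant-difference t tests on the factor's marginal
#' means (averaged over the other factors), using the mean square and
#' degrees of freedom of the factor's own repeated-measures error term
#' (subject x factor interaction):
#' `t = (m_i - m_j) / sqrt(2 * MSE / n)`. No multiplicity adjustment is
#' applied — that is the definition of LSD.
#'
#' @param table a band-power table.
#' @param factor factor to compare (`"hemisphere"`, `"state"`, `"band"`).
#' @param slice optional named list restricting the table to one level of
#'   other factor(s) before collapsing (simple-simple comparisons).
#' @return data.frame with one row per unordered level pair: `level_1`,
#'   `level_2`, `mean_diff`, `t`, `df`, `p`.
#' @export
lsd_posthoc <- function(table, factor, slice = NULL) {
  Y <- collapse_table(table, factor, slice = slice)
  n <- nrow(Y); k <- ncol(Y)
  fit <- rm_anova1(Y)
  mse <- fit$MSE; df <- fit$df_error
  m <- colMeans(Y)
  pairs <- utils::combn(k, 2)
  se <- sqrt(2 * mse / n)
  out <- data.frame(
    level_1 = colnames(Y)[pairs[1, ]],
    level_2 = colnames(Y)[pairs[2, ]],
    mean_diff = m[pairs[1, ]] - m[pairs[2, ]],
    stringsAsFactors = FALSE)
  out$t <- if (se > 0) out$mean_diff / se else
    ifelse(out$mean_diff == 0, 0, NaN)
  out$df <- df
  out$p <- ifelse(out$t == 0, 1,
                  2 * stats::pt(-abs(out$t), df))
  rownames(out) <- NULL
  out
}

#' Assumption checks for the band-power ANOVA
#'
#' Shapiro-Wilk normality per design cell (across subjects) and Levene's
#' test of variance homogeneity across the cell groups.
#'
#' @param table a band-power table.
#' @return list: `shapiro` (data.frame per cell: `hemisphere`, `state`,
#'   `band`, `W`, `p`), `levene` (list `F`, `df1`, `df2`, `p`).
#' @export
check_assumptions <- function(table) {
  df <- as.data.frame(table)
  if (anyNA(df$log_power)) stop("missing cells in band power table")
  cells <- unique(df[, c("hemisphere", "state", "band")])
  sw <- lapply(seq_len(nrow(cells)), function(i) {
    v <- df$log_power[df$hemisphere == cells$hemisphere[i] &
                        df$state == cells$state[i] &
                        df$band == cells$band[i]]
    res <- tryCatch(shapiro_wilk(v),
                    error = function(e) list(W = NA_real_, p = NA_real_))
    cbind(cells[i, ], W = res$W, p = res$p)
  })
  sw <- do.call(rbind, sw)
  rownames(sw) <- NULL
  groups <- interaction(df$hemisphere, df$state, df$band)
  list(shapiro = sw, levene = levene_test(df$log_power, groups))
}
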