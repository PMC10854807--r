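# Repeated-measures ANOVA with all factors within subject, implemented
# directly from the balanced sum-of-squares decomposition. Each effect is
# tested against its own subject-by-effect interaction; sphericity is
# assessed per effect (Mauchly) with Greenhouse-Geisser correction of the
# degrees of freedom.

# inclusion-exclusion sum of squares for the term spanned by `dims`
# (subject = dim 1); `y` is the full n x a x b x c array
ss_term <- function(y, dims) {
  res <- array(0, dim = dim(y))
  for (b in 0:(2^length(dims) - 1)) {   # all subsets of `dims`
    U <- dims[bitwAnd(b, 2^(seq_along(dims) - 1)) > 0]
    sgn <- (-1)^(length(dims) - length(U))
    res <- res + sgn * mean_broadcast(y, U)
  }
  sum(res^2)
}

mean_broadcast <- function(y, keep) {
  nd <- length(dim(y))
  if (length(keep) == 0) return(array(mean(y), dim = dim(y)))
  keep <- sort(keep)
  m <- apply(y, keep, mean)
  others <- setdiff(seq_len(nd), keep)
  src <- array(m, dim = c(dim(y)[keep], dim(y)[others]))
  aperm(src, match(seq_len(nd), c(keep, others)))
}

# table -> complete n x levels array; errors name the missing cells
bp_array <- function(table) {
  req <- c("subject", "hemisphere", "state", "band", "log_power")
  if (!all(req %in% names(table)))
    stop("band power table must have columns: ", paste(req, collapse = ", "))
  subs <- unique(table$subject)
  hemi <- c("L", "R"); states <- EVENT_STATES; bands <- BAND_NAMES
  y <- array(NA_real_,
             dim = c(length(subs), length(hemi), length(states),
                     length(bands)),
             dimnames = list(subject = as.character(subs),
                             hemisphere = hemi, state = states,
                             band = bands))
  idx <- cbind(match(table$subject, subs), match(table$hemisphere, hemi),
               match(table$state, states), match(table$band, bands))
  if (any(is.na(idx))) stop("unknown factor level in band power table")
  y[idx] <- table$log_power
  if (anyNA(y)) {
    miss <- which(is.na(y), arr.ind = TRUE)
    lab <- apply(miss, 1, function(r)
      paste(subs[r[1]], hemi[r[2]], states[r[3]], bands[r[4]], sep = "/"))
    stop("incomplete design; missing cells: ",
         paste(utils::head(lab, 10), collapse = ", "),
         if (nrow(miss) > 10) " ..." else "")
  }
  y
}

# subject scores on the orthonormal contrast basis of an effect,
# averaging over the within factors not in the effect
effect_scores <- function(y, dims) {
  nd <- length(dim(y))
  n <- dim(y)[1]
  others <- setdiff(2:nd, dims)
  m <- y
  for (d in sort(others, decreasing = TRUE))
    m <- array_mean_over(m, d)
  Y <- matrix(m, nrow = n)                 # n x prod(levels in dims)
  Cs <- lapply(dims, function(d) orthonormal_contrasts(dim(y)[d]))
  C <- Reduce(kronecker, rev(Cs))          # column-major: last dim fastest?
  Y %*% C
}

# mean over dimension d, keeping the others in order
array_mean_over <- function(a, d) {
  nd <- length(dim(a))
  keep <- setdiff(seq_len(nd), d)
  m <- apply(a, keep, mean)
  array(m, dim = dim(a)[keep])
}

#' Three-way repeated-measures ANOVA of the band-power table
#'
#' Factors: `hemisphere` (brain area, 2 levels), `state` (stimulus, 5
#' levels) and `band` (5 levels), all within subject, one observation per
#' subject x cell. Each effect is tested against its subject-by-effect
#' interaction (df = effect df x (n - 1)); per-effect Mauchly tests and
#' Greenhouse-Geisser epsilons are computed from the subject contrast
#' scores, and the corrected p-value replaces the uncorrected one when
#' Mauchly rejects at `sphericity_alpha` (or always, with
#' `always_gg = TRUE`). Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table a [build_band_power_table()] result (complete design).
#' @param always_gg apply the Greenhouse-Geisser correction
#'   unconditionally.
#' @param sphericity_alpha alpha for the Mauchly gate.
#' @return object of class `rm_anova`: data.frame with one row per
#'   effect (`SS_effect`, `SS_error`, `df_num`, `df_den`, `F`, `epsilon`,
#'   `mauchly_W`, `mauchly_p`, `p_uncorrected`, `p_GG`, `gg_applied`,
#'   `p`, `partial_eta_sq`), with attributes `n_subjects` and
#'   `zero_variance`.
#' @export
rm_anova3 <- function(table, always_gg = FALSE, sphericity_alpha = 0.05) {
  y <- bp_array(table)
  n <- dim(y)[1]
  if (n < 2) stop("repeated-measures ANOVA needs at least 2 subjects")
  factor_names <- c("subject", "hemisphere", "state", "band")
  effects <- list(hemisphere = 2, state = 3, band = 4,
                  `hemisphere:state` = c(2, 3),
                  `hemisphere:band` = c(2, 4),
                  `state:band` = c(3, 4),
                  `hemisphere:state:band` = c(2, 3, 4))
  rows <- lapply(names(effects), function(nm) {
    dims <- effects[[nm]]
    ss_eff <- ss_term(y, dims)
    ss_err <- ss_term(y, c(1, dims))
    df_num <- prod(dim(y)[dims] - 1)
    df_den <- df_num * (n - 1)
    scores <- effect_scores(y, dims)
    eps <- gg_epsilon_scores(scores)
    mt <- mauchly_from_M(stats::cov(scores), n)
    zero <- ss_err <= 0
    Fv <- if (zero) NaN else (ss_eff / df_num) / (ss_err / df_den)
    p_unc <- if (zero) NA_real_ else
      stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
    p_gg <- if (zero) NA_real_ else
      stats::pf(Fv, df_num * eps, df_den * eps, lower.tail = FALSE)
    applied <- !zero && df_num > 1 &&
      (always_gg || (is.finite(mt$p) && mt$p < sphericity_alpha))
    data.frame(effect = nm, SS_effect = ss_eff, SS_error = ss_err,
               df_num = df_num, df_den = df_den, F = Fv, epsilon = eps,
               mauchly_W = mt$W, mauchly_p = mt$p,
               p_uncorrected = p_unc, p_GG = p_gg, gg_applied = applied,
               p = if (isTRUE(applied)) p_gg else p_unc,
               partial_eta_sq = if (ss_eff + ss_err > 0)
                 ss_eff / (ss_eff + ss_err) else NaN,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_subjects") <- n
  attr(out, "zero_variance") <- any(!is.finite(out$F))
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat("Repeated-measures ANOVA (n =", attr(x, "n_subjects"), "subjects)\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, digits); df$epsilon <- signif(df$epsilon, 3)
  df$p <- signif(df$p, 3); df$partial_eta_sq <- signif(df$partial_eta_sq, 3)
  print(df[, c("effect", "df_num", "df_den", "F", "epsilon", "p",
               "gg_applied", "partial_eta_sq")], row.names = FALSE)
  invisible(x)
}

#' One-way repeated-measures ANOVA on a subject x level matrix
#'
#' @param Y numeric matrix, rows = subjects, columns = factor levels.
#' @param always_gg,sphericity_alpha as in [rm_anova3()].
#' @return one-row `rm_anova` data.frame (plus `MSE` and `df_error`
#'   columns used by the LSD post hocs).
#' @export
rm_anova1 <- function(Y, always_gg = FALSE, sphericity_alpha = 0.05) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 levels")
  g <- mean(Y)
  m_s <- rowMeans(Y); m_a <- colMeans(Y)
  ss_eff <- n * sum((m_a - g)^2)
  ss_err <- sum((Y - outer(m_s, rep(1, k)) -
                   outer(rep(1, n), m_a) + g)^2)
  df_num <- k - 1; df_den <- (k - 1) * (n - 1)
  scores <- Y %*% orthonormal_contrasts(k)
  eps <- gg_epsilon_scores(scores)
  mt <- mauchly_from_M(stats::cov(scores), n)
  zero <- ss_err <= 0
  Fv <- if (zero) NaN else (ss_eff / df_num) / (ss_err / df_den)
  p_unc <- if (zero) NA_real_ else
    stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
  p_gg <- if (zero) NA_real_ else
    stats::pf(Fv, df_num * eps, df_den * eps, lower.tail = FALSE)
  applied <- !zero && df_num > 1 &&
    (always_gg || (is.finite(mt$p) && mt$p < sphericity_alpha))
  out <- data.frame(effect = "level", SS_effect = ss_eff,
                    SS_error = ss_err, df_num = df_num, df_den = df_den,
                    F = Fv, epsilon = eps, mauchly_W = mt$W,
                    mauchly_p = mt$p, p_uncorrected = p_unc, p_GG = p_gg,
                    gg_applied = applied,
                    p = if (isTRUE(applied)) p_gg else p_unc,
                    partial_eta_sq = if (ss_eff + ss_err > 0)
                      ss_eff / (ss_eff + ss_err) else NaN,
                    MSE = ss_err / df_den, df_error = df_den,
                    stringsAsFactors = FALSE)
  attr(out, "n_subjects") <- n
  class(out) <- c("rm_anova", "data.frame")
  out
}

# subject x level matrix of cell means for `factor`, averaging over the
# other factors, optionally within a slice (named list level constraints)
collapse_table <- function(table, factor, slice = NULL, levels = NULL) {
  df <- as.data.frame(table)
  if (!is.null(slice))
    for (nm in names(slice)) df <- df[df[[nm]] == slice[[nm]], ]
  if (!nrow(df)) stop("empty slice: ",
                      paste(names(slice), unlist(slice), collapse = "="))
  if (anyNA(df$log_power)) stop("missing cells in slice")
  ag <- stats::aggregate(log_power ~ subject + df[[factor]], data = df,
                         FUN = mean)
  names(ag)[2] <- "level"
  lev <- if (is.null(levels)) sort(unique(as.character(ag$level))) else
    levels
  subs <- unique(ag$subject)
  Y <- matrix(NA_real_, length(subs), length(lev),
              dimnames = list(as.character(subs), lev))
  Y[cbind(match(ag$subject, subs), match(as.character(ag$level), lev))] <-
    ag$log_power
  if (anyNA(Y)) stop("incomplete level(s) for factor ", factor)
  Y
}

#' Simple-effects analysis after a significant interaction
#'
#' Runs a one-way repeated-measures ANOVA of `factor` within each level
#' of `within` (e.g. the band effect separately at each stimulus level),
#' averaging over the remaining factor. Each slice uses its own error
#' term and Greenhouse-Geisser epsilon.
#'
#' @param table a band-power table.
#' @param factor factor analysed within each slice
#'   (`"hemisphere"`, `"state"` or `"band"`).
#' @param within slicing factor.
#' @param ... passed to [rm_anova1()].
#' @return data.frame with one row per `within` level (columns of
#'   [rm_anova1()] plus `within` and `level`).
#' @export
simple_effects <- function(table, factor = "band", within = "state", ...) {
  stopifnot(factor != within)
  df_all <- as.data.frame(table)
  levs <- sort(unique(df_all[[within]]))
  factor_levels <- sort(unique(df_all[[factor]]))
  rows <- lapply(levs, function(lv) {
    Y <- collapse_table(table, factor,
                        slice = stats::setNames(list(lv), within),
                        levels = factor_levels)
    r <- rm_anova1(Y, ...)
    cbind(within = within, level = lv, r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
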