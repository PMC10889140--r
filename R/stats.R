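# Mixed-design (split-plot) repeated-measures ANOVA for conditioning data:
# stimulus group (CS+/CS-) as the between-unit factor and trial as the
# within-unit factor, plus simple effects and Benjamini-Hochberg control
# over the per-trial family.
#
# Unit convention: each subject contributes one CS+ and one CS- trial
# series, and the two series are treated as separate units. With n
# subjects this gives N = 2n units, hence a group-effect error df of
# 2n - 2 (e.g. 24 subjects -> df (1, 46)). This treats non-independent
# series as independent units and is stated prominently because the
# field's published df arithmetic follows it.

#' Build the unit x trial response matrix from score records
#'
#' Rows are units (subject x condition series), columns are
#' within-condition trial ordinals, values are the chosen per-trial scalar
#' (AUC-per-time by default).
#'
#' @param records A `per_scores` data frame.
#' @param value Column to analyse (default `"auc_per_time"`).
#' @param drop_incomplete Drop units with any missing/excluded cell
#'   (default `TRUE`, with a message); the ANOVA requires complete rows.
#' @return A `response_matrix`: numeric matrix with attributes `group`
#'   (factor per row) and `subject` (subject id per row).
#' @export
response_matrix <- function(records, value = "auc_per_time",
                            drop_incomplete = TRUE) {
  stopifnot(value %in% names(records))
  key <- interaction(records$subject_id, records$condition, drop = TRUE)
  ords <- sort(unique(records$cs_ordinal))
  mat <- matrix(NA_real_, nlevels(key), length(ords),
                dimnames = list(levels(key), paste0("t", ords)))
  mat[cbind(as.integer(key), match(records$cs_ordinal, ords))] <-
    records[[value]]
  group <- factor(vapply(strsplit(levels(key), ".", fixed = TRUE),
                         function(z) z[2], ""))
  subject <- vapply(strsplit(levels(key), ".", fixed = TRUE),
                    function(z) z[1], "")
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)
    if (!drop_incomplete)
      stop("completeness error: missing cells in rows ",
           paste(rownames(mat)[bad], collapse = ", "), call. = FALSE)
    message(sprintf("dropping %d incomplete unit(s) of %d", length(bad),
                    nrow(mat)))
    mat <- mat[-bad, , drop = FALSE]
    group <- droplevels(group[-bad])
    subject <- subject[-bad]
  }
  structure(mat, group = group, subject = subject, class = c("response_matrix",
                                                             "matrix"))
}

mat_group <- function(matrix, group) {
  g <- group %||% attr(matrix, "group")
  if (is.null(g)) stop("`group` must be supplied (one level per row)",
                       call. = FALSE)
  factor(g)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the trial columns.
gg_epsilon <- function(mat, group) {
  T <- ncol(mat)
  S <- matrix(0, T, T)
  for (lev in levels(group)) {
    sub <- mat[group == lev, , drop = FALSE]
    S <- S + stats::cov(sub) * (nrow(sub) - 1)
  }
  S <- S / (nrow(mat) - nlevels(group))
  C <- diag(T) - 1 / T
  M <- C %*% S %*% C
  sum(diag(M))^2 / ((T - 1) * sum(M * M))
}

#' Two-way mixed-design repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for a complete design with one
#' between-unit factor (group) and one within-unit factor (trial): main
#' group effect (tested against between-unit error), trial effect and
#' group x trial interaction (tested against the within-unit error).
#'
#' @param matrix Complete numeric unit x trial matrix (no missing cells),
#'   e.g. from [response_matrix()].
#' @param group Factor of group labels, one per row; defaults to the
#'   matrix's `group` attribute.
#' @param sphericity `"none"` (default; no correction) or `"GG"` for
#'   Greenhouse-Geisser adjusted within-unit df.
#' @return A `per_anova` data frame: `effect`, `F`, `df_num`, `df_den`,
#'   `p` for `main_group`, `trial`, `interaction`.
#' @examples
#' m <- matrix(rnorm(20), 4)
#' rm_anova(m, group = factor(c("a", "a", "b", "b")))
#' @export
rm_anova <- function(matrix, group = NULL, sphericity = c("none", "GG")) {
  sphericity <- match.arg(sphericity)
  mat <- unclass(matrix)
  g <- mat_group(matrix, group)
  if (anyNA(mat)) stop("completeness error: matrix contains missing cells",
                       call. = FALSE)
  N <- nrow(mat); T <- ncol(mat); G <- nlevels(g)
  if (T < 2) stop("need >= 2 trials", call. = FALSE)
  if (any(table(g) < 2))
    stop("df error: need >= 2 units per group", call. = FALSE)
  gm <- mean(mat)
  mu_unit <- rowMeans(mat)
  mu_trial <- colMeans(mat)
  mu_group <- tapply(mu_unit, g, mean)
  n_g <- as.numeric(table(g))
  cell <- rowsum(mat, g) / n_g                     # G x T cell means

  ss_between_units <- T * sum((mu_unit - gm)^2)
  ss_group <- T * sum(n_g * (mu_group - gm)^2)
  ss_unit_err <- ss_between_units - ss_group
  ss_trial <- N * sum((mu_trial - gm)^2)
  ss_int <- sum(n_g * (cell - outer(as.numeric(mu_group), rep(1, T)) -
                         outer(rep(1, G), mu_trial) + gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_within_err <- ss_tot - ss_between_units - ss_trial - ss_int

  df <- list(group = c(G - 1, N - G),
             trial = c(T - 1, (N - G) * (T - 1)),
             interaction = c((G - 1) * (T - 1), (N - G) * (T - 1)))
  eps <- if (sphericity == "GG") gg_epsilon(mat, g) else 1
  ms_unit_err <- ss_unit_err / df$group[2]
  ms_within_err <- ss_within_err / df$trial[2]
  safe_f <- function(ss, d, ms_err) if (ms_err <= 0) 0 else (ss / d) / ms_err
  F_group <- safe_f(ss_group, df$group[1], ms_unit_err)
  F_trial <- safe_f(ss_trial, df$trial[1], ms_within_err)
  F_int <- safe_f(ss_int, df$interaction[1], ms_within_err)
  p_of <- function(F, d, correct = FALSE) {
    e <- if (correct) eps else 1
    stats::pf(F, d[1] * e, d[2] * e, lower.tail = FALSE)
  }
  out <- data.frame(
    effect = c("main_group", "trial", "interaction"),
    F = c(F_group, F_trial, F_int),
    df_num = c(df$group[1], df$trial[1] * eps, df$interaction[1] * eps),
    df_den = c(df$group[2], df$trial[2] * eps, df$interaction[2] * eps),
    p = c(p_of(F_group, df$group),
          p_of(F_trial, df$trial, TRUE),
          p_of(F_int, df$interaction, TRUE)),
    stringsAsFactors = FALSE)
  attr(out, "ss") <- c(group = ss_group, unit_error = ss_unit_err,
                       trial = ss_trial, interaction = ss_int,
                       within_error = ss_within_err, total = ss_tot)
  attr(out, "epsilon") <- eps
  class(out) <- c("per_anova", "data.frame")
  out
}

#' Simple within-unit (trial) effect per group
#'
#' One-way repeated-measures ANOVA over trials, computed separately within
#' each group: the learning- and experience-induced change inside one
#' stimulus condition. df = (T-1, (n-1)(T-1)).
#'
#' @inheritParams rm_anova
#' @param groups Which group levels to analyse (default: all).
#' @return A `per_anova` data frame with one `within_group(<level>)` row
#'   per group.
#' @export
simple_within_effects <- function(matrix, group = NULL, groups = NULL) {
  mat <- unclass(matrix)
  g <- mat_group(matrix, group)
  groups <- groups %||% levels(g)
  rows <- lapply(groups, function(lev) {
    sub <- mat[g == lev, , drop = FALSE]
    n <- nrow(sub); T <- ncol(sub)
    if (n < 2) stop("df error: need >= 2 units in group ", lev, call. = FALSE)
    gm <- mean(sub)
    ss_subj <- T * sum((rowMeans(sub) - gm)^2)
    ss_trial <- n * sum((colMeans(sub) - gm)^2)
    ss_err <- sum((sub - gm)^2) - ss_subj - ss_trial
    d <- c(T - 1, (n - 1) * (T - 1))
    F <- if (ss_err <= 0) 0 else (ss_trial / d[1]) / (ss_err / d[2])
    data.frame(effect = sprintf("within_group(%s)", lev), F = F,
               df_num = d[1], df_den = d[2],
               p = stats::pf(F, d[1], d[2], lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("per_anova", "data.frame")
  out
}

#' Simple between-group effect per trial, with FDR control
#'
#' For every trial, a between-group one-way ANOVA on that trial's values
#' (default `mode = "per_trial"`: denominator df N-2), or a pooled-error
#' variant that tests each trial's group contrast against the cell-level
#' error pooled across all trials (df T(N-2)). Raw p-values are adjusted
#' across the trial family by the Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams rm_anova
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param mode `"per_trial"` or `"pooled"`.
#' @return A `per_anova` data frame with one `simple_between(trial t)` row
#'   per trial: `F`, `df_num`, `df_den`, `p`, `p_adjusted`, `significant`.
#' @export
simple_between_effects <- function(matrix, group = NULL, alpha = 0.05,
                                   mode = c("per_trial", "pooled")) {
  mode <- match.arg(mode)
  mat <- unclass(matrix)
  g <- mat_group(matrix, group)
  N <- nrow(mat); T <- ncol(mat); G <- nlevels(g)
  if (any(table(g) < 1)) stop("both groups must be present", call. = FALSE)
  n_g <- as.numeric(table(g))
  ss_b <- numeric(T); ss_w <- numeric(T)
  for (t in seq_len(T)) {
    x <- mat[, t]
    m_g <- tapply(x, g, mean)
    ss_b[t] <- sum(n_g * (m_g - mean(x))^2)
    ss_w[t] <- sum((x - m_g[as.integer(g)])^2)
  }
  if (mode == "per_trial") {
    df_den <- rep(N - G, T)
    ms_err <- ss_w / df_den
  } else {
    df_den <- rep(T * (N - G), T)
    ms_err <- rep(sum(ss_w) / (T * (N - G)), T)
  }
  F <- ifelse(ms_err > 0, (ss_b / (G - 1)) / ms_err, ifelse(ss_b > 0, Inf, 0))
  p <- stats::pf(F, G - 1, df_den, lower.tail = FALSE)
  degenerate <- ms_err <= 0 & ss_b <= 1e-300
  if (any(degenerate)) {
    p[degenerate] <- 1  # zero variance in both groups with equal means
    message(sprintf("%d degenerate trial(s): p set to 1", sum(degenerate)))
  }
  out <- data.frame(
    effect = sprintf("simple_between(trial %d)", seq_len(T)),
    trial = seq_len(T), F = F, df_num = G - 1, df_den = df_den, p = p,
    p_adjusted = bh_adjust(p), stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted <= alpha
  class(out) <- c("per_anova", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values are `q_(i) = min_(j>=i) p_(j) * m / j` on the ascending
#' ordering, capped at 1 and returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Full statistical analysis of an experiment's score table
#'
#' Convenience wrapper running [rm_anova()], [simple_within_effects()] and
#' [simple_between_effects()] on the AUC-per-time response matrix.
#'
#' @param records A `per_scores` data frame.
#' @param value Score column to analyse.
#' @param alpha Significance level.
#' @param sphericity Passed to [rm_anova()].
#' @param mode Passed to [simple_between_effects()].
#' @return A list `omnibus`, `within`, `between` of `per_anova` tables,
#'   plus the `matrix` analysed.
#' @export
analyze_experiment <- function(records, value = "auc_per_time", alpha = 0.05,
                               sphericity = "none", mode = "per_trial") {
  m <- response_matrix(records, value = value)
  list(omnibus = rm_anova(m, sphericity = sphericity),
       within = simple_within_effects(m),
       between = simple_between_effects(m, alpha = alpha, mode = mode),
       matrix = m)
}

#' @export
print.per_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$F <- signif(df$F, 4)
  df$p <- signif(df$p, 3)
  if ("p_adjusted" %in% names(df)) df$p_adjusted <- signif(df$p_adjusted, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
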