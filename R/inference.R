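#' One-way analysis of variance
#'
#' Classic fixed-effects decomposition:
#' `SS_between = sum n_i (mean_i - grand)^2`,
#' `SS_within = sum sum (y - mean_i)^2`, `F = MS_between / MS_within` on
#' (k - 1, N - k) degrees of freedom. When every group is constant the
#' within-group mean square is zero and F is reported as undefined (`NA`
#' with `f_defined = FALSE`) rather than silently infinite.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @return An `anova_oneway` list: `table` (rows Between/Within/Total with
#'   df, SS, MSS), `F`, `p_value`, `f_defined`, `group_means`, `group_n`.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  labels <- unique(groups)
  k <- length(labels)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n_i <- vapply(labels, function(g) sum(groups == g), numeric(1))
  if (any(n_i < 2)) stop("each group needs at least two observations", call. = FALSE)
  m_i <- vapply(labels, function(g) mean(values[groups == g]), numeric(1))
  grand <- mean(values)
  ss_b <- sum(n_i * (m_i - grand)^2)
  ss_w <- sum((values - m_i[match(groups, labels)])^2)
  df_b <- k - 1
  df_w <- length(values) - k
  out <- anova_table_from_ss(ss_b, df_b, ss_w, df_w)
  out$group_means <- stats::setNames(m_i, labels)
  out$group_n <- stats::setNames(n_i, labels)
  class(out) <- c("anova_oneway", class(out))
  out
}

#' ANOVA table from sums of squares
#'
#' Completes a one-way table from its between/within sums of squares and
#' degrees of freedom: mean squares `SS/df`, `F = MS_b/MS_w` and the upper
#' F-tail p-value. Useful for auditing published ANOVA tables from their
#' printed decompositions.
#'
#' @param ss_between,df_between between-group sum of squares and df.
#' @param ss_within,df_within within-group (residual) sum of squares and df.
#' @return An `anova_from_ss` list with `table`, `F`, `p_value`,
#'   `f_defined`.
#' @export
#' @examples
#' anova_table_from_ss(6.594, 2, 0.513, 6)$F  # about 38.6
anova_table_from_ss <- function(ss_between, df_between, ss_within, df_within) {
  if (ss_between < 0 || ss_within < 0) stop("sums of squares must be >= 0", call. = FALSE)
  if (df_between < 1 || df_within < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  f_defined <- ms_w > 0
  f <- if (f_defined) ms_b / ms_w else NA_real_
  p <- if (f_defined) stats::pf(f, df_between, df_within, lower.tail = FALSE) else NA_real_
  tab <- data.frame(
    source = c("Between groups", "Within groups", "Total"),
    df = c(df_between, df_within, df_between + df_within),
    SS = c(ss_between, ss_within, ss_between + ss_within),
    MSS = c(ms_b, ms_w, NA),
    F = c(f, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, F = f, p_value = p, f_defined = f_defined),
            class = "anova_from_ss")
}

#' @export
print.anova_from_ss <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!x$f_defined) cat("F undefined: zero within-group mean square\n")
  invisible(x)
}

#' Upper-tail probability of the studentized range distribution
#'
#' `P(Q_{k,df} > q)` for the range of k independent standard normals divided
#' by an independent chi-based scale estimate on `df` degrees of freedom —
#' the reference distribution of Tukey's HSD. Evaluated by nested numerical
#' quadrature: the normal-range probability
#' `P(R <= r) = k * integral phi(z) [Phi(z) - Phi(z - r)]^(k-1) dz` is
#' integrated against the density of the scale estimate. Accurate to at
#' least four decimals over the usual (q, k, df) grid.
#'
#' @param q non-negative quantile.
#' @param k number of groups (>= 2).
#' @param df residual degrees of freedom (>= 1).
#' @return The upper-tail probability.
#' @export
#' @examples
#' studentized_range_sf(4.34, 3, 6)  # about 0.05
studentized_range_sf <- function(q, k, df) {
  if (!all(is.finite(c(q, k, df)))) stop("inputs must be finite", call. = FALSE)
  if (k < 2 || df < 1) stop("need k >= 2 and df >= 1", call. = FALSE)
  if (length(q) > 1) return(vapply(q, studentized_range_sf, numeric(1), k = k, df = df))
  if (q <= 0) return(1)

  prange <- function(r) {
    # P(range of k std normals <= r), vectorized over r
    vapply(r, function(ri) {
      if (ri <= 0) return(0)
      f <- function(z) k * stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - ri))^(k - 1)
      stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  # density of S = chi_df / sqrt(df)
  log_c <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  dscale <- function(s) exp(log_c + (df - 1) * log(s) - df * s^2 / 2)
  cdf <- stats::integrate(function(s) dscale(s) * prange(q * s),
                          0, Inf, rel.tol = 1e-9)$value
  max(0, min(1, 1 - cdf))
}

#' Tukey HSD multiple comparisons
#'
#' All pairwise group comparisons after a one-way ANOVA. For each pair,
#' `q = |mean_i - mean_j| / sqrt(MS_w/2 * (1/n_i + 1/n_j))` (the
#' Tukey-Kramer form, reducing to the classic HSD for equal group sizes);
#' the adjusted p-value is the studentized-range upper tail at (k, df_w).
#' Groups are labelled with a compact letter display: two groups share a
#' letter iff they are not significantly different at `alpha`.
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @param alpha family-wise significance level (default 0.05).
#' @return A `tukey_hsd` list: `comparisons` (pair, diff, se, q, p_adj,
#'   significant), `letters`, `alpha`, and the underlying `anova`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  an <- anova_oneway(values, groups)
  if (!an$f_defined) stop("Tukey HSD undefined: zero within-group variance", call. = FALSE)
  labels <- names(an$group_means)
  k <- length(labels)
  df_w <- an$table$df[2]
  ms_w <- an$table$MSS[2]
  pairs <- utils::combn(labels, 2)
  comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pc) {
    i <- pairs[1, pc]; j <- pairs[2, pc]
    diff <- an$group_means[j] - an$group_means[i]
    se <- sqrt(ms_w / 2 * (1 / an$group_n[i] + 1 / an$group_n[j]))
    q <- abs(diff) / se
    p <- studentized_range_sf(q, k, df_w)
    data.frame(group_1 = i, group_2 = j, diff = unname(diff), se = unname(se),
               q = unname(q), p_adj = p, significant = p <= alpha,
               stringsAsFactors = FALSE)
  }))
  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (r in seq_len(nrow(comp))) {
    sig[comp$group_1[r], comp$group_2[r]] <- comp$significant[r]
    sig[comp$group_2[r], comp$group_1[r]] <- comp$significant[r]
  }
  structure(list(comparisons = comp, letters = compact_letters(sig),
                 alpha = alpha, anova = an), class = "tukey_hsd")
}

#' Percent change of a treatment mean versus control
#'
#' `(treatment - control) / control x 100`, signed: increases are positive,
#' reductions negative. [percent_change_label()] renders the conventional
#' wording ("80% reduction", "135% increase").
#'
#' @param treatment treatment group mean.
#' @param control control group mean; must be positive.
#' @return Signed percent change.
#' @export
percent_change <- function(treatment, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop("control mean must be positive", call. = FALSE)
  }
  (treatment - control) / control * 100
}

#' @rdname percent_change
#' @param pct signed percent change.
#' @export
percent_change_label <- function(pct) {
  ifelse(pct < 0, sprintf("%.4g%% reduction", -pct),
         sprintf("%.4g%% increase", pct))
}

#' Compact letter display from pairwise significance flags
#'
#' Insert-and-absorb assignment: starting from a single letter covering all
#' groups, each significant pair splits every letter containing both, and
#' redundant (absorbed) letters are dropped. Two groups share a letter iff
#' they are not significantly different.
#'
#' @param sig square logical matrix, `TRUE` where the row/column pair
#'   differs significantly; must be symmetric with a `FALSE` diagonal.
#'   Dimnames give the group labels.
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' m["a", "c"] <- m["c", "a"] <- TRUE
#' compact_letters(m)  # a, ab, b
compact_letters <- function(sig) {
  if (!is.matrix(sig) || nrow(sig) != ncol(sig) || !all(sig == t(sig))) {
    stop("sig must be a symmetric square logical matrix", call. = FALSE)
  }
  k <- nrow(sig)
  labels <- rownames(sig)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  # columns of membership matrix = letters; start with one letter for all
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb: drop columns whose membership is a subset of another's
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] && all(cols[[a]] <= cols[[b]]) &&
          !identical(cols[[a]], cols[[b]])) {
        keep[a] <- FALSE
      }
    }
    # drop exact duplicates too
    sig_cols <- vapply(cols, function(c) paste(as.integer(c), collapse = ""), character(1))
    keep <- keep & !duplicated(sig_cols)
    cols <- cols[keep]
  }
  # letter order follows the first group each letter covers
  cols <- cols[order(vapply(cols, function(c) min(which(c)), numeric(1)))]
  member <- do.call(cbind, cols)
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(member[g, ])], collapse = "")
  }, character(1))
  stats::setNames(out, labels)
}

#' ANOVA + Tukey over every analyte of a long-format table
#'
#' Runs [anova_oneway()], [tukey_hsd()] and [percent_change()] (against the
#' stated control group) separately for each analyte of a long table, and
#' stacks results in the layout of a published ANOVA table (Parameter,
#' Source of variation, df, SS, MSS, F, p).
#'
#' @param data long data frame with columns `group`, `analyte`, `value`.
#' @param control_group label of the control group (default `"0"`).
#' @param alpha significance level for Tukey flags.
#' @return List with `anova` (stacked tables), `tukey` (stacked pairwise
#'   comparisons with letters), `effects` (group means, SE and percent
#'   change vs control per analyte).
#' @export
analyte_tests <- function(data, control_group = "0", alpha = 0.05) {
  stopifnot(all(c("group", "analyte", "value") %in% names(data)))
  analytes <- unique(data$analyte)
  anova_rows <- list(); tukey_rows <- list(); effect_rows <- list()
  for (a in analytes) {
    sub <- data[data$analyte == a, ]
    an <- anova_oneway(sub$value, sub$group)
    tk <- tukey_hsd(sub$value, sub$group, alpha = alpha)
    anova_rows[[a]] <- cbind(parameter = a, an$table)
    tukey_rows[[a]] <- cbind(parameter = a, tk$comparisons,
                             letters_1 = tk$letters[tk$comparisons$group_1],
                             letters_2 = tk$letters[tk$comparisons$group_2])
    ms <- group_mean_se(sub$value, sub$group)
    ms$percent_change <- percent_change(ms$mean_value,
                                        ms$mean_value[ms$group == control_group])
    ms$letters <- tk$letters[ms$group]
    effect_rows[[a]] <- cbind(parameter = a, ms)
  }
  list(anova = do.call(rbind, anova_rows),
       tukey = do.call(rbind, tukey_rows),
       effects = do.call(rbind, effect_rows))
}
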