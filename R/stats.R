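#' Split-resampling sampling-sufficiency test
#'
#' Checks whether a set of per-ROI (or per-cell) values is sampled deeply
#' enough that random halves agree: each repetition randomly permutes the
#' values, splits them into two halves (the first half receives the extra
#' element when n is odd), and compares the halves by a two-tailed Welch
#' t-test. The mean p-value over repetitions is reported; sampling is
#' deemed sufficient when it is at least `threshold` (default 0.1).
#' Degenerate repetitions where both halves have zero variance score p = 1
#' when the means agree and p = 0 otherwise.
#'
#' @param values numeric vector (>= 4 values).
#' @param n_repetitions number of random splits (default 15).
#' @param seed integer seed for the permutation stream.
#' @param threshold sufficiency threshold on the mean p-value.
#' @return object of class `split_test`: list with `p_split`, `p_values`,
#'   `n_repetitions`, `sufficient`.
#' @export
split_sufficiency_test <- function(values, n_repetitions = 15, seed = NULL,
                                   threshold = 0.1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("need at least 4 values for the split test")
  check_scalar(n_repetitions, "n_repetitions", 1)
  p <- with_seed(seed, vapply(seq_len(n_repetitions), function(i) {
    perm <- sample.int(n)
    k <- ceiling(n / 2)
    a <- values[perm[seq_len(k)]]
    b <- values[perm[(k + 1):n]]
    if (sd(a) == 0 && sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1)))
  p_split <- mean(p, na.rm = TRUE)
  structure(list(p_split = p_split, p_values = p,
                 n_repetitions = as.integer(n_repetitions),
                 sufficient = p_split >= threshold),
            class = "split_test")
}

#' Group comparisons used for reporting
#'
#' Thin wrappers around the standard routines: two-tailed Welch t-test
#' (`welch_t`), Mann-Whitney / Wilcoxon rank-sum (`mann_whitney`; exact in
#' small tie-free samples), and one-way ANOVA with Tukey HSD post hoc
#' (`anova_tukey`, for two or more groups).
#'
#' @param x numeric vector (first group) or a named list of groups.
#' @param y second group (ignored when `x` is a list).
#' @param method one of `"welch_t"`, `"mann_whitney"`, `"anova_tukey"`.
#' @return list with `method`, `p_value` (overall, or the ANOVA F-test p),
#'   `pairwise` (data.frame of Tukey-adjusted pairwise p-values, ANOVA
#'   only) and `summary` (per-group n, mean, median, sem).
#' @export
compare_groups <- function(x, y = NULL,
                           method = c("welch_t", "mann_whitney",
                                      "anova_tukey")) {
  method <- match.arg(method)
  groups <- if (is.list(x)) x else list(a = x, b = y)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values")
  summ <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 1L),
    mean = vapply(groups, mean, 1),
    median = vapply(groups, median, 1),
    sem = vapply(groups, function(v) sd(v) / sqrt(length(v)), 1),
    row.names = NULL
  )
  out <- list(method = method, summary = summ, pairwise = NULL)
  if (method == "anova_tukey") {
    df <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), vapply(groups, length, 1L)))
    )
    fit <- aov(value ~ group, data = df)
    out$p_value <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$group
    out$pairwise <- data.frame(pair = rownames(tk),
                               p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    if (length(groups) != 2)
      stop(method, " compares exactly two groups")
    a <- groups[[1]]; b <- groups[[2]]
    out$p_value <- if (method == "welch_t")
      t.test(a, b, var.equal = FALSE)$p.value
    else
      suppressWarnings(wilcox.test(a, b)$p.value)
  }
  out
}
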