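#' Two-tailed Mann-Whitney U test
#'
#' Wilcoxon rank-sum comparison of two independent samples.  The p
#' value is exact (enumeration over rank assignments) when the combined
#' sample size is at most 20 and there are no ties, and otherwise uses
#' the normal approximation with tie and continuity corrections -- the
#' behaviour of the classical tables and of GraphPad-style software.
#'
#' @param a,b numeric samples (each of size >= 3).
#' @return list: `U` (the Mann-Whitney U of sample `a`), `p`
#'   (two-sided), `method` (`"exact"` or `"normal_approx"`), `n` =
#'   `c(n_a, n_b)`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each sample needs at least 3 finite values", call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 20L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       n = c(length(a), length(b)))
}

# Dunn's z for groups i, j on pooled ranks with tie correction
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- levels(groups)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    unname((mean_rank[pr[1]] - mean_rank[pr[2]]) / se)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p value, followed
#' by Dunn's pairwise z tests on the pooled ranks.  Pairwise p values
#' are adjusted over all pairs by Bonferroni (default; the behaviour of
#' GraphPad Prism's "Dunn's multiple comparison test") or Sidak.  A
#' compact letter display summarises which groups differ at `alpha`:
#' groups sharing a letter are not significantly different.
#'
#' @param values numeric response.
#' @param groups group labels (>= 3 groups, >= 3 values each).
#' @param p_adjust `"bonferroni"` (default) or `"sidak"`.
#' @param alpha significance level for the letter display (default
#'   0.05).
#' @return list: `H`, `df`, `p` (omnibus), `pairwise` (data frame
#'   `group1, group2, z, p, p_adj`), `letters` (named character vector,
#'   one entry per group).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = c("bonferroni", "sidak"),
                         alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 3L)
    stop("need at least 3 groups (use mann_whitney for 2)", call. = FALSE)
  if (any(table(groups) < 3L))
    stop("every group needs at least 3 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  pw <- dunn_pairwise(values, groups)
  m <- nrow(pw)
  pw$p_adj <- if (p_adjust == "bonferroni") pmin(1, pw$p * m) else
    1 - (1 - pw$p)^m
  letters <- cld_letters(levels(groups), pw, values, groups, alpha)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw, letters = letters)
}

# insert-and-absorb compact letter display; groups ordered by decreasing
# mean rank so "a" marks the highest group, deterministically
cld_letters <- function(lev, pairwise, values, groups, alpha = 0.05) {
  mean_rank <- tapply(rank(values), groups, mean)
  ord <- lev[order(-mean_rank, lev)]
  sets <- list(ord)   # start: everyone shares one letter
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  if (nrow(sig)) for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[i]; g2 <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (ii in seq_along(new_sets)) for (jj in seq_along(new_sets)) {
      if (ii != jj && keep[ii] && keep[jj] &&
          all(new_sets[[ii]] %in% new_sets[[jj]]) &&
          (length(new_sets[[ii]]) < length(new_sets[[jj]]) || ii > jj))
        keep[ii] <- FALSE
    }
    sets <- new_sets[keep]
  }
  # order sets by the best-ranked group they contain, then letter them
  first_pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (k in seq_along(sets))
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  out[order(names(out))]
}

#' Group comparison on a tidy value table
#'
#' Dispatches to [mann_whitney()] for two groups and [kruskal_dunn()]
#' for three or more, returning one tidy results table.
#'
#' @param table data frame with columns `group` and `value` (an
#'   optional `metric` column splits the analysis per metric).
#' @param alpha significance level for letter displays.
#' @return data frame with columns `metric`, `test`, `groups`,
#'   `statistic`, `p`, `p_adj`, `letters`.
#' @export
compare_groups <- function(table, alpha = 0.05) {
  stopifnot(all(c("group", "value") %in% names(table)))
  if (!"metric" %in% names(table)) table$metric <- "value"
  out <- list()
  for (met in unique(table$metric)) {
    tb <- table[table$metric == met, , drop = FALSE]
    gl <- unique(as.character(tb$group))
    if (length(gl) < 2L) next
    if (length(gl) == 2L) {
      mw <- mann_whitney(tb$value[tb$group == gl[1]],
                         tb$value[tb$group == gl[2]])
      out[[length(out) + 1L]] <- data.frame(
        metric = met, test = "mann_whitney",
        groups = paste(gl, collapse = " vs "),
        statistic = mw$U, p = mw$p, p_adj = mw$p, letters = "")
    } else {
      kd <- kruskal_dunn(tb$value, tb$group, alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        metric = met, test = "kruskal_wallis",
        groups = paste(gl, collapse = ", "),
        statistic = kd$H, p = kd$p, p_adj = NA_real_,
        letters = paste(names(kd$letters), kd$letters, sep = "=",
                        collapse = ";"))
      out[[length(out) + 1L]] <- data.frame(
        metric = met, test = "dunn",
        groups = paste(kd$pairwise$group1, kd$pairwise$group2,
                       sep = " vs "),
        statistic = kd$pairwise$z, p = kd$pairwise$p,
        p_adj = kd$pairwise$p_adj, letters = "")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
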