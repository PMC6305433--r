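#' Holm-Sidak step-down adjustment
#'
#' Sorts the raw p-values increasingly and sets
#' `adj_(i) = max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, capped at 1;
#' adjusted values are returned in the input order. Adjusted p-values are
#' monotone in raw-p order and never smaller than the raw p.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out
}

.pair_labels <- function(groups) {
  idx <- utils::combn(seq_along(groups), 2)
  apply(idx, 2, function(k) paste(groups[k[1]], groups[k[2]], sep = " vs "))
}

#' Friedman test with Holm-Sidak post hoc comparisons
#'
#' Friedman chi-square on within-block ranks (mid-ranks for ties) for a
#' related-samples design, followed by pairwise z comparisons on the mean
#' ranks, `z = (Rbar_i - Rbar_j) / sqrt(k (k + 1) / (6 n))`, with two-sided
#' raw p-values adjusted by the Holm-Sidak step-down procedure.
#'
#' @param data numeric matrix with one row per block and one column per
#'   group (column names used as group labels), or a data.frame coercible
#'   to such a matrix.
#' @return list of class `test_result`: `test, statistic, df, p, pairwise`
#'   (data.frame with pair, z, p_raw, p_adj, sided), `adjustment`, `n`.
#' @export
friedman_holm <- function(data) {
  y <- as.matrix(data)
  if (anyNA(y)) {
    y <- y[stats::complete.cases(y), , drop = FALSE]
  }
  n <- nrow(y); k <- ncol(y)
  if (k < 2L || n < 2L)
    stop("design error: need >= 2 groups and >= 2 complete blocks",
         call. = FALSE)
  groups <- colnames(y)
  if (is.null(groups)) groups <- paste0("g", seq_len(k))
  ft <- stats::friedman.test(y)
  stat <- unname(ft$statistic); pval <- ft$p.value
  if (is.nan(stat) && all(apply(y, 1, function(r) length(unique(r)) == 1))) {
    # every block fully tied: no evidence of any ordering
    stat <- 0; pval <- 1
  }
  ranks <- t(apply(y, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  idx <- utils::combn(seq_len(k), 2)
  z <- (rbar[idx[1, ]] - rbar[idx[2, ]]) / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  structure(list(test = "Friedman ANOVA on ranks",
                 statistic = stat,
                 df = unname(ft$parameter), p = pval,
                 pairwise = data.frame(pair = .pair_labels(groups),
                                       z = unname(z), p_raw = unname(p_raw),
                                       p_adj = holm_sidak(unname(p_raw)),
                                       sided = "two_sided"),
                 adjustment = "holm-sidak", n = n),
            class = "test_result")
}

#' Kruskal-Wallis test with one-sided Dunn post hoc comparisons
#'
#' Kruskal-Wallis H with tie correction on independent groups, followed by
#' Dunn z statistics on pooled mean ranks with tie-corrected variance. The
#' one-sided alternative is a *reduction* relative to the earlier-listed
#' group (the reference, e.g. sham, should come first): for pair (i, j)
#' with i before j, `p = P(Z >= z)` where
#' `z = (Rbar_i - Rbar_j) / SE`.
#'
#' @param groups named list of numeric vectors, reference group first.
#' @param adjustment `"holm-sidak"` or `"none"` for the pairwise p-values.
#' @param sided `"one_sided"` (default, direction test < reference) or
#'   `"two_sided"`.
#' @return list of class `test_result` (see [friedman_holm()]); carries
#'   `degenerate = TRUE` with `p = NA` when all values are identical.
#' @export
kruskal_dunn <- function(groups, adjustment = c("holm-sidak", "none"),
                         sided = c("one_sided", "two_sided")) {
  adjustment <- match.arg(adjustment)
  sided <- match.arg(sided)
  if (length(groups) < 2L)
    stop("design error: need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  if (N < 3L) stop("design error: total n >= 3 required", call. = FALSE)
  if (length(unique(x)) == 1L) {
    return(structure(list(test = "Kruskal-Wallis", statistic = NA_real_,
                          df = length(groups) - 1L, p = NA_real_,
                          pairwise = NULL, adjustment = adjustment,
                          n = lengths(groups), degenerate = TRUE),
                     class = "test_result"))
  }
  kt <- stats::kruskal.test(x, g)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  idx <- utils::combn(seq_along(groups), 2)
  ni <- lengths(groups)
  se <- sqrt(v * (1 / ni[idx[1, ]] + 1 / ni[idx[2, ]]))
  z <- (rbar[idx[1, ]] - rbar[idx[2, ]]) / se
  p_raw <- if (sided == "one_sided") stats::pnorm(z, lower.tail = FALSE)
           else 2 * stats::pnorm(-abs(z))
  p_adj <- if (adjustment == "holm-sidak") holm_sidak(unname(p_raw))
           else unname(p_raw)
  structure(list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value,
                 pairwise = data.frame(pair = .pair_labels(names(groups)),
                                       z = unname(z), p_raw = unname(p_raw),
                                       p_adj = p_adj, sided = sided),
                 adjustment = adjustment, n = ni, degenerate = FALSE),
            class = "test_result")
}

#' Blinded-rater questionnaire analysis
#'
#' Each reviewer is analyzed independently: for every (reviewer, category)
#' cell a Friedman test across the groups is run with samples as blocks,
#' followed by Holm-Sidak-adjusted pairwise comparisons. Blocks with a
#' missing score are dropped for that category; cells with fewer than 2
#' complete blocks are flagged as having insufficient data.
#'
#' @param table data.frame `reviewer, sample_id, group, category, score`
#'   (scores 1-4 or `NA`); sample ids must align across groups by their
#'   numeric suffix (block index).
#' @return data.frame with one row per (reviewer, category):
#'   `reviewer, category, n_blocks, statistic, p, insufficient`, plus a
#'   `tests` attribute holding the full [friedman_holm()] results keyed by
#'   `"reviewer.category"`.
#' @export
rater_analysis <- function(table) {
  stopifnot(all(c("reviewer", "sample_id", "group", "category", "score")
                %in% names(table)))
  block <- sub("^.*_", "", table$sample_id)
  rows <- list(); tests <- list()
  for (rev in unique(table$reviewer)) {
    for (cat in unique(table$category)) {
      sub <- table[table$reviewer == rev & table$category == cat, ]
      y <- tapply(sub$score, list(block[table$reviewer == rev &
                                          table$category == cat],
                                  sub$group), function(v) v[1])
      complete <- stats::complete.cases(y)
      n_blocks <- sum(complete)
      if (n_blocks < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          reviewer = rev, category = cat, n_blocks = n_blocks,
          statistic = NA_real_, p = NA_real_, insufficient = TRUE)
        next
      }
      res <- friedman_holm(y[complete, , drop = FALSE])
      tests[[paste(rev, cat, sep = ".")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        reviewer = rev, category = cat, n_blocks = n_blocks,
        statistic = res$statistic, p = res$p, insufficient = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  out
}
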