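#' Relative expression change by the delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale per (animal, gene).
#' In the default reference-normalized mode, each animal's delta-Ct is
#' `Ct(gene) - Ct(reference)`; the group contrast is
#' `ddCt = mean dCt(CCI) - mean dCt(sham)` and the fold change is
#' `2^-ddCt`, with percent change `100 * (1 - fold_change)`. The
#' `"raw_dct"` mode differences unnormalized group Ct means instead,
#' matching the formula `2^-(Ct(CCI) - Ct(sham))` taken literally.
#'
#' @param table Ct table as produced by [generate_ct_table()] (columns
#'   `animal_id, group, gene, replicate, ct`).
#' @param gene target gene name.
#' @param reference_gene reference gene (default from the table attribute,
#'   falling back to `"GAPDH"`).
#' @param mode `"ddct"` (reference-normalized, default) or `"raw_dct"`.
#' @return list of class `expression_result`: `gene, fold_change,
#'   percent_change, ddct, n_per_group`.
#' @export
delta_ct_expression <- function(table, gene, reference_gene = NULL,
                                mode = c("ddct", "raw_dct")) {
  mode <- match.arg(mode)
  if (is.null(reference_gene))
    reference_gene <- attr(table, "reference_gene")
  if (is.null(reference_gene)) reference_gene <- "GAPDH"
  need <- c("animal_id", "group", "gene", "ct")
  if (!all(need %in% names(table)))
    stop("data error: Ct table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (g in c("sham", "cci")) {
    if (!any(table$group == g & table$gene == gene))
      stop("data error: gene '", gene, "' missing for group '", g, "'",
           call. = FALSE)
    if (mode == "ddct" &&
        !any(table$group == g & table$gene == reference_gene))
      stop("data error: reference gene '", reference_gene,
           "' missing for group '", g, "'", call. = FALSE)
  }
  per_animal <- stats::aggregate(ct ~ animal_id + group + gene, table, mean)
  tgt <- per_animal[per_animal$gene == gene, ]
  if (mode == "ddct") {
    ref <- per_animal[per_animal$gene == reference_gene, ]
    merged <- merge(tgt, ref, by = c("animal_id", "group"),
                    suffixes = c("_t", "_r"))
    merged$dct <- merged$ct_t - merged$ct_r
  } else {
    merged <- tgt
    merged$dct <- merged$ct
  }
  mu <- tapply(merged$dct, merged$group, mean)
  ddct <- unname(mu["cci"] - mu["sham"])
  fold <- 2^(-ddct)
  structure(list(gene = gene, fold_change = fold,
                 percent_change = 100 * (1 - fold), ddct = ddct,
                 n_per_group = table(merged$group)),
            class = "expression_result")
}

#' Paired t-test
#'
#' Classical paired t on index-aligned pairs. When all pairwise differences
#' are identical the statistic is degenerate (zero variance); the result is
#' flagged rather than returning a spurious p-value.
#'
#' @param x,y equal-length numeric vectors, paired by index.
#' @return list `(t, df, p, degenerate)`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("pairing error: x and y must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("pairing error: need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1L, p = NA_real_, degenerate = TRUE))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
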