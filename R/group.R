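#' Scaled Wilcoxon rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum test of samples `a` (reference group,
#' conventionally WT) and `b` (comparison group, conventionally HET),
#' with the W statistic rescaled to `[-1, 1]`:
#' `scaled_w = 2 U / (n_a n_b) - 1`, where `U` counts pairs with
#' `b > a` (half-credit for ties; the rank-biserial form).  So `+1`
#' means every `b` value exceeds every `a` value, `-1` the reverse, and
#' the sign convention is negative when the comparison group tends
#' lower.  P-values use exact enumeration for small tie-free samples
#' (both sizes at most 8) and the normal approximation with continuity
#' and tie correction otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @return A list: `u` (pair count for `b > a`), `w_stat` (rank sum of
#'   `b`), `scaled_w`, `p_value`, `n_a`, `n_b`.
#' @export
ranksum_scaled <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("samples must be finite")
  cmp <- outer(b, a, function(x, y) (x > y) + 0.5 * (x == y))
  u <- sum(cmp)
  n_a <- length(a); n_b <- length(b)
  ties <- any(duplicated(c(a, b)))
  exact <- (n_a <= 8 && n_b <= 8 && !ties)
  p <- suppressWarnings(
    wilcox.test(b, a, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
  list(u = u, w_stat = sum(rank(c(a, b))[(n_a + 1):(n_a + n_b)]),
       scaled_w = 2 * u / (n_a * n_b) - 1, p_value = p,
       n_a = n_a, n_b = n_b)
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up control (default) over a family of
#' p-values, or the Benjamini-Yekutieli variant for robustness under
#' arbitrary dependence.
#'
#' @param pvals p-values in (0, 1].
#' @param alpha FDR level.
#' @param method `"BH"` or `"BY"`.
#' @return A list: `adjusted` p-values, logical `significant` flags, and
#'   the family size `m`.
#' @export
fdr_adjust <- function(pvals, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  adj <- p.adjust(pvals, method = method)
  list(adjusted = adj, significant = adj <= alpha, m = length(pvals))
}

#' Compare genotype networks edge-by-edge
#'
#' Wilcoxon rank-sum comparison of band-limited GC between genotypes,
#' with the scaled-W effect direction and FDR control.
#' `mode = "per_band"` tests every (edge, band) cell, each animal
#' contributing one value.  `mode = "broadband"` pools the per-band
#' values of each animal as separate samples (animals x bands per edge
#' -- e.g. 84 and 66 at 14 vs 11 animals and six bands) and tests each
#' directed edge once.  FDR is applied within the family of all tests
#' performed in the chosen mode; the family size is reported in the
#' output.
#'
#' @param bandgc tidy band-GC table (see [band_gc()] / [gc_cohort()])
#'   with columns `animal`, `genotype`, `source_region`,
#'   `target_region`, `band`, `gc_value`.
#' @param mode `"broadband"` or `"per_band"`.
#' @param alpha FDR level.
#' @param fdr_method `"BH"` or `"BY"`.
#' @param groups character vector of length 2: reference and comparison
#'   genotype (negative scaled W means the comparison group is lower).
#' @param pool `"band_samples"` (each band value is a sample, the
#'   printed-n convention) or `"animal_mean"` (one broadband mean per
#'   animal); broadband mode only.
#' @return A list of class `network_comparison`: `table` (one row per
#'   test with `u`, `w_stat`, `scaled_w`, `p_value`, `p_adjusted`,
#'   `significant`, group sizes), `family_size`, `mode`, `skipped`
#'   (edges missing a genotype, if any).
#' @export
compare_network <- function(bandgc, mode = c("broadband", "per_band"),
                            alpha = 0.05, fdr_method = c("BH", "BY"),
                            groups = c("WT", "HET"),
                            pool = c("band_samples", "animal_mean")) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  fdr_method <- match.arg(fdr_method)
  need <- c("animal", "genotype", "source_region", "target_region",
            "band", "gc_value")
  if (!all(need %in% names(bandgc)))
    stop("bandgc missing columns: ",
         paste(setdiff(need, names(bandgc)), collapse = ", "))
  if (!all(groups %in% bandgc$genotype))
    stop("both groups must be represented in bandgc")
  edge_key <- paste(bandgc$source_region, bandgc$target_region, sep = "->")
  strata <- if (mode == "per_band")
    split(bandgc, list(edge_key, bandgc$band), drop = TRUE, sep = "|")
  else
    split(bandgc, edge_key)
  rows <- list(); skipped <- character()
  for (nm in names(strata)) {
    d <- strata[[nm]]
    if (mode == "broadband" && pool == "animal_mean")
      d <- stats::aggregate(gc_value ~ animal + genotype + source_region +
                              target_region, data = d, FUN = mean)
    va <- d$gc_value[d$genotype == groups[1]]
    vb <- d$gc_value[d$genotype == groups[2]]
    if (!length(va) || !length(vb)) {
      skipped <- c(skipped, nm)
      next
    }
    rs <- ranksum_scaled(va, vb)
    rows[[length(rows) + 1L]] <- data.frame(
      source_region = d$source_region[1], target_region = d$target_region[1],
      stratum = if (mode == "per_band") d$band[1] else "broadband",
      u = rs$u, w_stat = rs$w_stat, scaled_w = rs$scaled_w,
      p_value = rs$p_value, n_a = rs$n_a, n_b = rs$n_b,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("skipped strata with a missing genotype: ",
            paste(skipped, collapse = ", "))
  tab <- do.call(rbind, rows)
  fdr <- fdr_adjust(tab$p_value, alpha = alpha, method = fdr_method)
  tab$p_adjusted <- fdr$adjusted
  tab$significant <- fdr$significant
  structure(list(table = tab, family_size = fdr$m, mode = mode,
                 alpha = alpha, fdr_method = fdr_method, groups = groups,
                 skipped = skipped),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> mode %s: %d tests (%s FDR at %.2f), %d significant\n",
              x$mode, x$family_size, x$fdr_method, x$alpha,
              sum(x$table$significant)))
  invisible(x)
}

#' Group network summary
#'
#' Per genotype and directed edge, the median GC over the pooled
#' animal x band samples -- the edge weights of the group connectivity
#' graphs -- plus the list of FDR-significant edges if a comparison is
#' supplied.
#'
#' @param bandgc tidy band-GC table.
#' @param comparison optional [compare_network()] result.
#' @return A list of class `network_summary`: `medians` (genotype,
#'   source, target, median_gc) and `significant_edges`.
#' @export
network_summary <- function(bandgc, comparison = NULL) {
  med <- stats::aggregate(gc_value ~ genotype + source_region + target_region,
                          data = bandgc, FUN = median)
  names(med)[names(med) == "gc_value"] <- "median_gc"
  sig <- NULL
  if (!is.null(comparison)) {
    st <- comparison$table
    sig <- st[st$significant,
              c("source_region", "target_region", "stratum", "scaled_w",
                "p_adjusted")]
    rownames(sig) <- NULL
  }
  structure(list(medians = med, significant_edges = sig),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d genotype x edge medians",
              nrow(x$medians)))
  if (!is.null(x$significant_edges))
    cat(sprintf(", %d significant edges", nrow(x$significant_edges)))
  cat("\n")
  invisible(x)
}
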