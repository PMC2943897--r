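# Stage 1: per dataset and per sample group (normal, tumor), Pearson-test
# every probe-level L/R pair, Bonferroni-correct within the dataset, and
# promote gene-level pairs that pass in at least one group of one dataset.

#' Correlation screen configuration
#'
#' @param alpha_screen significance level applied to the Bonferroni-adjusted
#'   p-value (default 0.05).
#' @param min_group_size smallest sample group that is tested (default 3;
#'   Pearson correlation needs at least 3 points).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(alpha_screen = 0.05, min_group_size = 3) {
  if (!(alpha_screen > 0 && alpha_screen < 1))
    stop("'alpha_screen' must lie in (0, 1)", call. = FALSE)
  if (min_group_size < 3) stop("'min_group_size' must be >= 3", call. = FALSE)
  structure(list(alpha_screen = alpha_screen, min_group_size = min_group_size),
            class = "screen_config")
}

# Vectorized row-wise Pearson r and two-sided p between two aligned
# probe x sample log2 matrices. Rows with a constant vector get NA.
.rowwise_pearson <- function(xl, xr) {
  n <- ncol(xl)
  cl <- xl - rowMeans(xl)
  cr <- xr - rowMeans(xr)
  ssl <- rowSums(cl^2)
  ssr <- rowSums(cr^2)
  r <- rowSums(cl * cr) / sqrt(ssl * ssr)
  r[ssl == 0 | ssr == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  df <- n - 2
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df))
  list(r = r, p = p, n = n)
}

#' Screen one dataset for correlated ligand/receptor probe pairs
#'
#' For every probe pair and every sample group (normal, tumor) with at least
#' `min_group_size` samples, the Pearson correlation of the two probes' log2
#' values across the group's samples is tested. The Bonferroni family is the
#' set of tests actually performed within this dataset (both groups pooled);
#' probe pairs with a constant probe in a group are undefined there, excluded
#' from the family size, and reported via `message()`.
#'
#' @param dataset an [lr_dataset].
#' @param probe_pairs data frame from [expand_to_probe_pairs()] for this
#'   dataset's platform.
#' @param config a [screen_config()].
#' @return Data frame with one row per performed test: `dataset`, `group`,
#'   `ligand`, `receptor`, `ligand_probe`, `receptor_probe`, `n`, `r`, `p`,
#'   `p_bonferroni`, `passed`.
#' @export
screen_dataset <- function(dataset, probe_pairs, config = screen_config()) {
  stopifnot(inherits(dataset, "lr_dataset"), inherits(config, "screen_config"))
  if (nrow(probe_pairs) == 0)
    stop(sprintf("no testable probe pairs on dataset %s", dataset$name), call. = FALSE)
  E <- .log2_exprs(dataset)
  ann <- dataset$annotations
  out <- list()
  n_undefined <- 0
  for (group in c("normal", "tumor")) {
    ids <- ann$sample_id[ann$tissue == group]
    if (length(ids) < config$min_group_size) next
    xl <- E[probe_pairs$ligand_probe, ids, drop = FALSE]
    xr <- E[probe_pairs$receptor_probe, ids, drop = FALSE]
    res <- .rowwise_pearson(xl, xr)
    keep <- !is.na(res$r)
    n_undefined <- n_undefined + sum(!keep)
    if (!any(keep)) next
    out[[group]] <- data.frame(
      dataset = dataset$name, group = group,
      probe_pairs[keep, c("ligand", "receptor", "ligand_probe", "receptor_probe")],
      n = res$n, r = res$r[keep], p = res$p[keep],
      stringsAsFactors = FALSE
    )
  }
  if (n_undefined > 0)
    message(sprintf("screen_dataset [%s]: excluded %d undefined test(s) (constant probe)",
                    dataset$name, n_undefined))
  if (length(out) == 0)
    stop(sprintf("no testable pairs in dataset %s", dataset$name), call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  m <- nrow(res)  # family = tests performed in this dataset, both groups
  res$p_bonferroni <- bonferroni(res$p, m)
  res$passed <- res$p_bonferroni < config$alpha_screen
  res
}

#' Gene-level pairs passing the screen in at least one dataset
#'
#' A gene-level ligand/receptor pair is promoted if any of its probe pairs
#' passed the Bonferroni-corrected screen in any group (normal or tumor) of
#' any dataset — the most permissive aggregation over probes.
#'
#' @param results one or more [screen_dataset()] result frames (a single data
#'   frame or a list of them).
#' @return Data frame with columns `ligand`, `receptor`, unique, in first-pass
#'   order.
#' @export
pairs_passing_any <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (length(results) == 0) stop("no screen results supplied", call. = FALSE)
  all_res <- do.call(rbind, results)
  hit <- all_res[all_res$passed, c("ligand", "receptor")]
  hit <- hit[!duplicated(paste(hit$ligand, hit$receptor, sep = "\r")), ]
  rownames(hit) <- NULL
  hit
}

#' Per-group correlation of one gene-level pair (scatter-style query)
#'
#' Returns the unadjusted Pearson correlation of every probe combination of a
#' ligand/receptor pair within one sample group, suitable for scatter
#' reporting of individual pairs.
#'
#' @param dataset an [lr_dataset].
#' @param ligand,receptor gene symbols.
#' @param group `"normal"` or `"tumor"`.
#' @return Data frame with columns `ligand_probe`, `receptor_probe`, `n`, `r`,
#'   `p` (unadjusted).
#' @export
correlate_pair_in_group <- function(dataset, ligand, receptor,
                                    group = c("normal", "tumor")) {
  stopifnot(inherits(dataset, "lr_dataset"))
  group <- match.arg(group)
  pm <- dataset$probe_map
  lp <- pm$probe_id[pm$gene == ligand]
  rp <- pm$probe_id[pm$gene == receptor]
  if (length(lp) == 0 || length(rp) == 0)
    stop(sprintf("pair %s/%s is not measurable on dataset %s",
                 ligand, receptor, dataset$name), call. = FALSE)
  ids <- dataset$annotations$sample_id[dataset$annotations$tissue == group]
  if (length(ids) < 3)
    stop(sprintf("group '%s' of dataset %s has fewer than 3 samples",
                 group, dataset$name), call. = FALSE)
  grid <- expand.grid(receptor_probe = rp, ligand_probe = lp,
                      stringsAsFactors = FALSE)[, c("ligand_probe", "receptor_probe")]
  E <- .log2_exprs(dataset)
  res <- .rowwise_pearson(E[grid$ligand_probe, ids, drop = FALSE],
                          E[grid$receptor_probe, ids, drop = FALSE])
  data.frame(grid, n = res$n, r = res$r, p = res$p, stringsAsFactors = FALSE)
}
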