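# Stage 2: per-probe paired differential expression within one dataset —
# tumor/normal ratio (geometric mean over patient pairs), paired-t p-value,
# Benjamini-Hochberg q over the dataset's probe family, and the per-dataset
# significance call (P < 0.01 and/or FDR < 0.25 by default).

#' Differential-call configuration
#'
#' Defaults encode the selection rule "P<0.01 (paired t-test) and/or
#' FDR <0.25": a probe is significant in a dataset when either threshold is
#' met.
#'
#' @param p_threshold paired-t p-value threshold (default 0.01).
#' @param fdr_threshold q-value threshold (default 0.25).
#' @return A list of class `differential_config`.
#' @export
differential_config <- function(p_threshold = 0.01, fdr_threshold = 0.25) {
  if (!(p_threshold > 0 && p_threshold < 1) || !(fdr_threshold > 0 && fdr_threshold < 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(p_threshold = p_threshold, fdr_threshold = fdr_threshold),
            class = "differential_config")
}

#' Tumor/normal expression ratio of one probe
#'
#' The "mean ratio of paired tumor/normal expression" is computed as the
#' geometric mean of the per-patient ratios, i.e.
#' \eqn{2^{\mathrm{mean}(\log_2 T_i - \log_2 N_i)}}. The geometric mean is
#' symmetric under tissue swap (swap gives the reciprocal) and is the summary
#' consistent with t-testing log2 differences. `method = "arithmetic"` gives
#' the arithmetic mean of per-patient ratios for sensitivity analysis.
#'
#' @param dataset an [lr_dataset].
#' @param probe_id probe to summarize.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return A positive scalar; > 1 means higher in tumors.
#' @export
tn_ratio <- function(dataset, probe_id, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  v <- get_values(dataset, probe_id, "paired")
  if (method == "geometric") {
    2^mean(v$tumor - v$normal)
  } else {
    mean(2^(v$tumor - v$normal))
  }
}

#' Per-dataset differential calls for a set of probes
#'
#' Runs [paired_t()] on the log2 values of each probe over the dataset's
#' patient pairs, adjusts p-values by [bh_fdr()] over the family of all probes
#' tested here (the ligand/receptor-catalog probes of this dataset, not
#' genome-wide), and flags significance by the "p OR q" rule. Probes with
#' degenerate differences (zero variance) get `direction = "flat"` when the
#' ratio is exactly 1, are never significant, and are reported via
#' `message()`; they are excluded from the q-value family.
#'
#' @param dataset an [lr_dataset].
#' @param probes character vector of probe ids to test; default all probes in
#'   the matrix.
#' @param config a [differential_config()].
#' @return Data frame with one row per probe: `probe_id`, `gene`, `dataset`,
#'   `tn_ratio`, `p`, `q`, `direction` (`"up"`, `"down"`, `"flat"`),
#'   `significant`.
#' @export
test_dataset <- function(dataset, probes = NULL, config = differential_config()) {
  stopifnot(inherits(dataset, "lr_dataset"), inherits(config, "differential_config"))
  if (is.null(probes)) probes <- rownames(dataset$exprs)
  probes <- as.character(probes)
  missing_probes <- setdiff(probes, rownames(dataset$exprs))
  if (length(missing_probes))
    stop(sprintf("probe(s) absent from dataset %s: %s", dataset$name,
                 paste(utils::head(missing_probes, 5), collapse = ", ")), call. = FALSE)
  E <- .log2_exprs(dataset)
  tum <- E[probes, dataset$pairs$tumor_sample, drop = FALSE]
  nor <- E[probes, dataset$pairs$normal_sample, drop = FALSE]
  d <- tum - nor
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- if (n >= 2) sqrt(rowSums((d - md)^2) / (n - 1)) else rep(NA_real_, length(md))
  ratio <- 2^md
  p <- rep(NA_real_, length(probes))
  ok <- !is.na(sdd) & sdd > 0
  if (n >= 2 && any(ok)) {
    tstat <- md[ok] / (sdd[ok] / sqrt(n))
    p[ok] <- 2 * stats::pt(-abs(tstat), n - 1)
  }
  degenerate <- n >= 2 & !ok & md != 0  # constant non-zero difference: certain change
  p[degenerate] <- 0
  if (any(!ok & md == 0))
    message(sprintf("test_dataset [%s]: %d degenerate probe(s) (zero-variance, zero-mean differences) called flat",
                    dataset$name, sum(!ok & md == 0)))
  q <- rep(NA_real_, length(probes))
  defined <- !is.na(p)
  q[defined] <- bh_fdr(p[defined])
  direction <- ifelse(ratio > 1, "up", ifelse(ratio < 1, "down", "flat"))
  significant <- defined & direction != "flat" &
    (p < config$p_threshold | q < config$fdr_threshold)
  significant[is.na(significant)] <- FALSE
  data.frame(
    probe_id = probes,
    gene = dataset$probe_map$gene[match(probes, dataset$probe_map$probe_id)],
    dataset = dataset$name,
    tn_ratio = unname(ratio), p = unname(p), q = unname(q),
    direction = unname(direction), significant = unname(significant),
    stringsAsFactors = FALSE
  )
}

#' Apply the per-dataset significance rule to a table of printed statistics
#'
#' Annotates a calls table that already carries `tn_ratio`, `p` and `q`
#' columns (e.g. a transcription of a published per-gene/per-dataset table)
#' with `direction` and `significant` under the same rule used by
#' [test_dataset()]: significant iff `p < p_threshold` OR `q < fdr_threshold`,
#' direction from the ratio.
#'
#' @param calls data frame with columns `probe_id`, `gene`, `dataset`,
#'   `tn_ratio`, `p`, `q`.
#' @param config a [differential_config()].
#' @return The input with `direction` and `significant` columns added.
#' @export
apply_significance <- function(calls, config = differential_config()) {
  stopifnot(inherits(config, "differential_config"))
  need <- c("probe_id", "gene", "dataset", "tn_ratio", "p", "q")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols))
    stop(sprintf("calls table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  calls$direction <- ifelse(calls$tn_ratio > 1, "up",
                            ifelse(calls$tn_ratio < 1, "down", "flat"))
  calls$significant <- !is.na(calls$p) & calls$direction != "flat" &
    (calls$p < config$p_threshold | calls$q < config$fdr_threshold)
  calls
}

#' Unpaired group comparison (unequal-variance t)
#'
#' Thin wrapper over [welch_t()] for unpaired designs such as tumors versus
#' independent normal tissues.
#'
#' @param group_a,group_b numeric vectors (log2 values).
#' @return An [lr_test].
#' @export
welch_compare <- function(group_a, group_b) {
  welch_t(group_a, group_b)
}
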