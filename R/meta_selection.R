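# Stage 3: cross-dataset concordance voting on probes, anchor-based
# enumeration of reported L/R pairs with direction, and co-significance
# counting — the construction behind a published per-pair/per-dataset
# modulation table.

#' Meta-selection configuration
#'
#' @param min_datasets a probe qualifies as concordantly modulated when it is
#'   significant, in one shared direction, in at least this many datasets
#'   (absolute count, default 3 — not a fraction of the datasets on which the
#'   probe is measurable).
#' @param conflict how to direct a pair whose ligand and receptor both qualify
#'   but in opposite directions: `"receptor"` (default; the receptor's
#'   direction wins) or `"both"` (report the pair once per direction).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(min_datasets = 3, conflict = c("receptor", "both")) {
  if (min_datasets < 1) stop("'min_datasets' must be >= 1", call. = FALSE)
  conflict <- match.arg(conflict)
  structure(list(min_datasets = min_datasets, conflict = conflict),
            class = "selection_config")
}

#' Vote probes as concordantly modulated across datasets
#'
#' For each probe, collects the datasets in which it is significant; the probe
#' qualifies when that count reaches `min_datasets` and all significant calls
#' share one direction.
#'
#' @param calls differential calls pooled across datasets ([test_dataset()]
#'   rows or [apply_significance()] output, row-bound).
#' @param config a [selection_config()].
#' @return Data frame with one row per probe: `probe_id`, `gene`,
#'   `direction` (shared direction of the significant calls, `NA` when none or
#'   discordant), `n_qualifying`, `qualifying_datasets` (comma-separated),
#'   `qualified`.
#' @export
vote_genes <- function(calls, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  need <- c("probe_id", "gene", "dataset", "direction", "significant")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols))
    stop(sprintf("calls table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  split_idx <- split(seq_len(nrow(calls)), calls$probe_id)
  rows <- lapply(split_idx, function(idx) {
    sig <- idx[calls$significant[idx]]
    dirs <- unique(calls$direction[sig])
    dirs <- setdiff(dirs, "flat")  # flat probes never count toward votes
    concordant <- length(dirs) == 1
    data.frame(
      probe_id = calls$probe_id[idx[1]],
      gene = calls$gene[idx[1]],
      direction = if (concordant) dirs else NA_character_,
      n_qualifying = length(sig),
      qualifying_datasets = paste(sort(calls$dataset[sig]), collapse = ","),
      qualified = concordant && length(sig) >= config$min_datasets,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$probe_id), , drop = FALSE]
}

#' Enumerate reported L/R pairs from probe votes
#'
#' A probe pair is reported when its ligand probe or its receptor probe (or
#' both) is a qualified vote — "all the possible pairings" of a qualified
#' anchor are reported. The pair's assigned direction is the shared direction
#' when both members qualify concordantly; the single qualified member's
#' direction otherwise; and on a qualified-but-opposite conflict, the
#' receptor's direction (or both directions, per `config$conflict`).
#'
#' @param votes output of [vote_genes()].
#' @param pair_universe probe-level pair universe: data frame with columns
#'   `ligand`, `receptor`, `ligand_probe`, `receptor_probe` and optionally
#'   `category` (from [expand_to_probe_pairs()] restricted to screen-passing
#'   pairs, or supplied directly for fixture runs).
#' @param calls optional pooled differential calls; when given, each reported
#'   pair is annotated with its co-significance count
#'   ([count_cosignificance()]).
#' @param config a [selection_config()].
#' @return Data frame with one row per reported pair: `category`, `ligand`,
#'   `receptor`, `ligand_probe`, `receptor_probe`, `direction`, `anchor`
#'   (`"ligand"`, `"receptor"` or `"both"`), `cosignificant_count` (`NA`
#'   without `calls`).
#' @export
enumerate_pairs <- function(votes, pair_universe, calls = NULL,
                            config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  need <- c("ligand", "receptor", "ligand_probe", "receptor_probe")
  missing_cols <- setdiff(need, names(pair_universe))
  if (length(missing_cols))
    stop(sprintf("pair universe lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  if (nrow(votes) == 0 || !any(votes$qualified)) {
    return(data.frame(category = character(0), ligand = character(0),
                      receptor = character(0), ligand_probe = character(0),
                      receptor_probe = character(0), direction = character(0),
                      anchor = character(0), cosignificant_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (!"category" %in% names(pair_universe))
    pair_universe$category <- NA_character_
  li <- match(pair_universe$ligand_probe, votes$probe_id)
  ri <- match(pair_universe$receptor_probe, votes$probe_id)
  l_q <- !is.na(li) & votes$qualified[li]
  r_q <- !is.na(ri) & votes$qualified[ri]
  keep <- l_q | r_q
  pu <- pair_universe[keep, , drop = FALSE]
  l_q <- l_q[keep]; r_q <- r_q[keep]
  l_dir <- votes$direction[li[keep]]
  r_dir <- votes$direction[ri[keep]]
  anchor <- ifelse(l_q & r_q, "both", ifelse(l_q, "ligand", "receptor"))
  direction <- ifelse(l_q & r_q,
                      ifelse(l_dir == r_dir, l_dir, NA_character_),
                      ifelse(l_q, l_dir, r_dir))
  conflict <- l_q & r_q & (l_dir != r_dir)
  out <- data.frame(
    category = pu$category, ligand = pu$ligand, receptor = pu$receptor,
    ligand_probe = pu$ligand_probe, receptor_probe = pu$receptor_probe,
    direction = direction, anchor = anchor, stringsAsFactors = FALSE
  )
  if (any(conflict)) {
    if (config$conflict == "receptor") {
      out$direction[conflict] <- r_dir[conflict]
    } else {
      extra <- out[conflict, , drop = FALSE]
      out$direction[conflict] <- r_dir[conflict]
      extra$direction <- l_dir[conflict]
      out <- rbind(out, extra)
    }
  }
  out$cosignificant_count <- NA_integer_
  if (!is.null(calls)) {
    out$cosignificant_count <- mapply(
      count_cosignificance, ligand_probe = out$ligand_probe,
      receptor_probe = out$receptor_probe, MoreArgs = list(calls = calls),
      USE.NAMES = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Count datasets where both members of a pair are significant
#'
#' @param calls pooled differential calls with `probe_id`, `dataset`,
#'   `significant` columns.
#' @param ligand_probe,receptor_probe the pair's probe ids.
#' @return Integer: the number of datasets in which both probes are flagged
#'   significant.
#' @export
count_cosignificance <- function(calls, ligand_probe, receptor_probe) {
  ds_l <- calls$dataset[calls$probe_id == ligand_probe & calls$significant]
  ds_r <- calls$dataset[calls$probe_id == receptor_probe & calls$significant]
  length(intersect(ds_l, ds_r))
}

#' Write the long-format pair report
#'
#' One row per reported pair per dataset with both members' statistics — the
#' layout of a per-pair/per-dataset modulation table. Deterministic: two runs
#' on identical input produce byte-identical files.
#'
#' @param reports output of [enumerate_pairs()].
#' @param calls pooled differential calls used to fill the per-dataset cells.
#' @param path output TSV path; `NULL` returns the table without writing.
#' @return The report data frame, invisibly when `path` is given.
#' @export
emit_report <- function(reports, calls, path = NULL) {
  cols <- c("block", "category", "ligand", "receptor", "ligand_probe",
            "receptor_probe", "direction", "dataset", "tn_ratio_L", "p_L",
            "q_L", "sig_L", "tn_ratio_R", "p_R", "q_R", "sig_R",
            "cosignificant_count")
  if (nrow(reports) == 0) {
    out <- as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                                   simplify = FALSE), cols),
                         stringsAsFactors = FALSE)
  } else {
    datasets <- sort(unique(calls$dataset))
    key <- function(probe, ds) paste(probe, ds, sep = "\r")
    call_key <- key(calls$probe_id, calls$dataset)
    cell <- function(probe, ds, col) {
      v <- calls[[col]][match(key(probe, ds), call_key)]
      v
    }
    rows <- list()
    for (i in seq_len(nrow(reports))) {
      r <- reports[i, ]
      for (ds in datasets) {
        lr_present <- any(call_key %in% key(c(r$ligand_probe, r$receptor_probe), ds))
        if (!lr_present) next
        rows[[length(rows) + 1]] <- data.frame(
          block = r$direction, category = r$category, ligand = r$ligand,
          receptor = r$receptor, ligand_probe = r$ligand_probe,
          receptor_probe = r$receptor_probe, direction = r$direction,
          dataset = ds,
          tn_ratio_L = cell(r$ligand_probe, ds, "tn_ratio"),
          p_L = cell(r$ligand_probe, ds, "p"),
          q_L = cell(r$ligand_probe, ds, "q"),
          sig_L = cell(r$ligand_probe, ds, "significant"),
          tn_ratio_R = cell(r$receptor_probe, ds, "tn_ratio"),
          p_R = cell(r$receptor_probe, ds, "p"),
          q_R = cell(r$receptor_probe, ds, "q"),
          sig_R = cell(r$receptor_probe, ds, "significant"),
          cosignificant_count = r$cosignificant_count,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
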