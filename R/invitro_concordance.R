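# Stage 4: compare the tumor-derived direction of each L/R pair member with a
# two-condition in vitro fold-change table (e.g. oncogene-transduced vs normal
# thyrocytes) and classify pairs concordant / discordant / undetermined.
# The comparison is direction-only: no magnitude threshold is applied.

#' Read a two-condition in vitro fold-change table
#'
#' Expected format: tab-delimited, header columns `gene` and `fold_change`
#' (linear-scale experimental/control fold change; > 1 means up in the
#' experimental condition).
#'
#' @param path path to the TSV file.
#' @return Data frame with columns `gene`, `fold_change`.
#' @export
read_invitro <- function(path) {
  if (!file.exists(path)) stop(sprintf("in vitro table not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "fold_change")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("in vitro table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tab$fold_change <- as.numeric(tab$fold_change)
  if (any(!is.na(tab$fold_change) & tab$fold_change <= 0))
    stop("in vitro fold changes must be positive", call. = FALSE)
  tab[, need]
}

.fc_direction <- function(fc) {
  ifelse(is.na(fc), NA_character_,
         ifelse(fc > 1, "up", ifelse(fc < 1, "down", NA_character_)))
}

#' Classify L/R pairs as concordant or discordant between systems
#'
#' A pair is *concordant* when the ligand's direction agrees between the in
#' vitro model and the tumors AND the receptor's direction agrees too;
#' *discordant* when both directions are defined on each side and at least
#' one member disagrees; *undetermined* when any in vitro fold change equals
#' exactly 1 or any tumor direction is missing.
#'
#' @param pairs data frame with one row per pair: columns `ligand`,
#'   `receptor`, `invitro_fc_L`, `invitro_fc_R` (positive linear fold
#'   changes), `tumor_dir_L`, `tumor_dir_R` (`"up"`/`"down"`/`NA`).
#' @return The input plus `invitro_dir_L`, `invitro_dir_R` and `verdict`
#'   (`"concordant"`, `"discordant"`, `"undetermined"`).
#' @export
classify_concordance <- function(pairs) {
  need <- c("ligand", "receptor", "invitro_fc_L", "invitro_fc_R",
            "tumor_dir_L", "tumor_dir_R")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols))
    stop(sprintf("pairs table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  if (any(is.na(pairs$invitro_fc_L)) || any(is.na(pairs$invitro_fc_R)))
    stop("both in vitro fold changes must be present for every pair", call. = FALSE)
  if (any(pairs$invitro_fc_L <= 0 | pairs$invitro_fc_R <= 0))
    stop("in vitro fold changes must be positive", call. = FALSE)
  pairs$invitro_dir_L <- .fc_direction(pairs$invitro_fc_L)
  pairs$invitro_dir_R <- .fc_direction(pairs$invitro_fc_R)
  defined <- !is.na(pairs$invitro_dir_L) & !is.na(pairs$invitro_dir_R) &
    !is.na(pairs$tumor_dir_L) & !is.na(pairs$tumor_dir_R)
  agree <- pairs$invitro_dir_L == pairs$tumor_dir_L &
    pairs$invitro_dir_R == pairs$tumor_dir_R
  pairs$verdict <- ifelse(!defined, "undetermined",
                          ifelse(agree, "concordant", "discordant"))
  pairs
}

#' Summarize concordance verdicts
#'
#' @param records output of [classify_concordance()]; must contain at least
#'   one record.
#' @return Named integer vector with components `concordant`, `discordant`,
#'   `undetermined`; the three counts partition the input.
#' @export
summarize_concordance <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("no concordance records to summarize", call. = FALSE)
  counts <- c(
    concordant = sum(records$verdict == "concordant"),
    discordant = sum(records$verdict == "discordant"),
    undetermined = sum(records$verdict == "undetermined")
  )
  stopifnot(sum(counts) == nrow(records))
  counts
}

#' Tumor direction of one gene from votes and per-dataset calls
#'
#' A member's tumor direction is its qualified vote direction when one of its
#' probes qualifies; otherwise the majority direction among its significant
#' per-dataset calls (pairs are reported even when one member reaches
#' significance in only a single dataset). Returns `NA` when the gene has no
#' significant call or the majority is tied.
#'
#' @param gene gene symbol.
#' @param votes output of [vote_genes()].
#' @param calls pooled differential calls.
#' @return `"up"`, `"down"`, or `NA`.
#' @export
tumor_direction <- function(gene, votes, calls) {
  v <- votes[votes$gene == gene & votes$qualified, ]
  if (nrow(v) > 0) {
    dirs <- unique(v$direction)
    if (length(dirs) == 1) return(dirs)
    # same symbol anchoring both directions through different probes: ambiguous
    return(NA_character_)
  }
  sig <- calls[calls$gene == gene & calls$significant, ]
  n_up <- sum(sig$direction == "up")
  n_dn <- sum(sig$direction == "down")
  if (n_up == n_dn) return(NA_character_)
  if (n_up > n_dn) "up" else "down"
}

#' Build concordance records for reported pairs
#'
#' Joins a reported-pair table with an in vitro fold-change table (matching
#' members by gene symbol) and the tumor directions derived from votes and
#' calls, then classifies each pair. Pairs with either member absent from the
#' in vitro table are skipped.
#'
#' @param reports output of [enumerate_pairs()].
#' @param invitro output of [read_invitro()].
#' @param votes,calls vote and call tables used by [tumor_direction()].
#' @return Output of [classify_concordance()] for the testable pairs.
#' @export
concordance_from_report <- function(reports, invitro, votes, calls) {
  fc <- stats::setNames(invitro$fold_change, invitro$gene)
  keep <- reports$ligand %in% names(fc) & reports$receptor %in% names(fc)
  rep_k <- reports[keep, , drop = FALSE]
  rep_k <- rep_k[!duplicated(paste(rep_k$ligand, rep_k$receptor, sep = "\r")), ]
  if (nrow(rep_k) == 0)
    stop("no reported pair has both members in the in vitro table", call. = FALSE)
  pairs <- data.frame(
    ligand = rep_k$ligand, receptor = rep_k$receptor,
    invitro_fc_L = unname(fc[rep_k$ligand]),
    invitro_fc_R = unname(fc[rep_k$receptor]),
    tumor_dir_L = vapply(rep_k$ligand, tumor_direction, character(1),
                         votes = votes, calls = calls),
    tumor_dir_R = vapply(rep_k$receptor, tumor_direction, character(1),
                         votes = votes, calls = calls),
    stringsAsFactors = FALSE
  )
  classify_concordance(pairs)
}
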