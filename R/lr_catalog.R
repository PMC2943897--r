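# Ligand/receptor catalog: directed gene-symbol pairs and their expansion to
# probe-level test units on a given platform.

#' Construct a ligand/receptor catalog
#'
#' A catalog is an ordered set of directed ligand -> receptor gene-symbol pairs
#' (the direction matters: (A, B) and (B, A) are distinct entries). Gene
#' identity is by exact, case-sensitive symbol; a gene may appear in many
#' pairs. Duplicate (ligand, receptor) rows are collapsed, keeping first-seen
#' order, with the collapsed count reported via `message()`.
#'
#' @param ligand,receptor character vectors of gene symbols.
#' @param category optional character vector of free-text functional classes.
#' @param source_name label recorded on the catalog.
#' @return A data frame of class `lr_catalog` with columns `ligand`,
#'   `receptor`, `category` and attribute `source_name`.
#' @export
lr_catalog <- function(ligand, receptor, category = NA_character_,
                       source_name = "catalog") {
  ligand <- as.character(ligand)
  receptor <- as.character(receptor)
  if (length(ligand) != length(receptor))
    stop("'ligand' and 'receptor' must have equal length", call. = FALSE)
  category <- rep_len(as.character(category), length(ligand))
  bad <- which(is.na(ligand) | is.na(receptor) | ligand == "" | receptor == "")
  if (length(bad))
    stop(sprintf("empty gene symbol in catalog row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  self <- which(ligand == receptor)
  if (length(self))
    stop(sprintf("ligand equals receptor in catalog row(s): %s",
                 paste(self, collapse = ", ")), call. = FALSE)
  key <- paste(ligand, receptor, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sprintf("lr_catalog: collapsed %d duplicate pair(s)", sum(dup)))
  out <- data.frame(ligand = ligand[!dup], receptor = receptor[!dup],
                    category = category[!dup], stringsAsFactors = FALSE)
  attr(out, "source_name") <- source_name
  class(out) <- c("lr_catalog", "data.frame")
  out
}

#' Read a ligand/receptor catalog from a TSV file
#'
#' Expected format: UTF-8, tab-delimited, header row with columns
#' `ligand` and `receptor` and an optional `category` column.
#'
#' @param path path to the catalog file.
#' @param source_name label recorded on the catalog; defaults to the file name.
#' @return An [lr_catalog].
#' @export
read_lr_catalog <- function(path, source_name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("catalog file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ligand", "receptor")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("catalog file %s lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  category <- if ("category" %in% names(tab)) tab$category else NA_character_
  lr_catalog(tab$ligand, tab$receptor, category, source_name = source_name)
}

#' Expand gene-level pairs to probe-level test units
#'
#' On platforms where a gene is measured by several probes (probe sets or
#' clones), each probe is analyzed separately: a pair whose ligand has `a`
#' probes and whose receptor has `b` probes yields `a * b` probe pairs. Pairs
#' with either gene absent from the platform yield no test unit and are
#' reported as unmeasurable via `message()`.
#'
#' @param catalog an [lr_catalog].
#' @param probe_map data frame with columns `probe_id`, `gene` (each probe maps
#'   to a single gene symbol).
#' @return Data frame with columns `ligand`, `receptor`, `category`,
#'   `ligand_probe`, `receptor_probe`, ordered by catalog entry then by probe.
#' @export
expand_to_probe_pairs <- function(catalog, probe_map) {
  stopifnot(inherits(catalog, "lr_catalog"))
  probe_map <- .as_probe_map(probe_map)
  if (nrow(probe_map) == 0) stop("probe map is empty", call. = FALSE)
  probes_of <- split(probe_map$probe_id, probe_map$gene)
  rows <- vector("list", nrow(catalog))
  unmeasurable <- character(0)
  for (i in seq_len(nrow(catalog))) {
    lp <- probes_of[[catalog$ligand[i]]]
    rp <- probes_of[[catalog$receptor[i]]]
    if (is.null(lp) || is.null(rp)) {
      unmeasurable <- c(unmeasurable,
                        paste0(catalog$ligand[i], "/", catalog$receptor[i]))
      next
    }
    grid <- expand.grid(receptor_probe = rp, ligand_probe = lp,
                        stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(
      ligand = catalog$ligand[i], receptor = catalog$receptor[i],
      category = catalog$category[i],
      ligand_probe = grid$ligand_probe, receptor_probe = grid$receptor_probe,
      stringsAsFactors = FALSE
    )
  }
  if (length(unmeasurable))
    message(sprintf("expand_to_probe_pairs: %d pair(s) unmeasurable on this platform: %s",
                    length(unmeasurable), paste(unmeasurable, collapse = ", ")))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(ligand = character(0), receptor = character(0),
                      category = character(0), ligand_probe = character(0),
                      receptor_probe = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.as_probe_map <- function(probe_map) {
  if (is.null(probe_map)) stop("probe map is missing", call. = FALSE)
  if (!is.data.frame(probe_map) || !all(c("probe_id", "gene") %in% names(probe_map)))
    stop("probe map must be a data frame with columns 'probe_id' and 'gene'",
         call. = FALSE)
  probe_map$probe_id <- as.character(probe_map$probe_id)
  probe_map$gene <- as.character(probe_map$gene)
  if (anyDuplicated(probe_map$probe_id))
    stop("probe map assigns some probe id to more than one row", call. = FALSE)
  probe_map
}

#' Read a probe -> gene map from a TSV file
#'
#' Expected format: tab-delimited with header columns `probe_id` and `gene`.
#'
#' @param path path to the probe map file.
#' @return Data frame with columns `probe_id`, `gene`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("probe map file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .as_probe_map(tab)
}
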