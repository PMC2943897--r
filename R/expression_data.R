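# Paired expression datasets: probe x sample intensity matrices with a
# probe -> gene map, sample annotations, and the tumor/normal pairing by
# patient. Intensities are stored on the linear scale as loaded; every
# downstream statistic operates on log2(max(intensity, floor)).

#' Construct a paired tumor/normal expression dataset
#'
#' @param name dataset label (e.g. "I").
#' @param exprs numeric matrix of non-negative linear-scale intensities,
#'   rows = probes (rownames mandatory), columns = samples (colnames mandatory).
#' @param probe_map data frame with columns `probe_id`, `gene`; must cover
#'   every matrix row.
#' @param annotations data frame with columns `sample_id`, `patient_id`,
#'   `tissue` (values `"tumor"` or `"normal"`); one row per matrix column.
#' @param platform_label free-text platform description.
#' @param log_floor intensities are floored at this value (default 1.0)
#'   before any log2 transform, so zero intensities map to log2 value 0.
#'
#' @return An object of class `lr_dataset`: a list with the validated fields
#'   plus `pairs`, the per-patient (tumor sample, normal sample) pairing
#'   computed by [pair_samples()].
#' @export
lr_dataset <- function(name, exprs, probe_map, annotations,
                       platform_label = "", log_floor = 1.0) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("'exprs' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' must have probe rownames and sample colnames", call. = FALSE)
  if (any(!is.finite(exprs)))
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  if (any(exprs < 0))
    stop("expression matrix contains negative intensities", call. = FALSE)
  probe_map <- .as_probe_map(probe_map)
  unmapped <- setdiff(rownames(exprs), probe_map$probe_id)
  if (length(unmapped))
    stop(sprintf("probes absent from probe map: %s",
                 paste(utils::head(unmapped, 5), collapse = ", ")), call. = FALSE)
  annotations <- .validate_annotations(annotations)
  missing_samples <- setdiff(annotations$sample_id, colnames(exprs))
  if (length(missing_samples))
    stop(sprintf("annotated sample(s) absent from matrix: %s",
                 paste(missing_samples, collapse = ", ")), call. = FALSE)
  extra <- setdiff(colnames(exprs), annotations$sample_id)
  if (length(extra))
    stop(sprintf("matrix column(s) lack annotation: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  if (!is.numeric(log_floor) || length(log_floor) != 1 || log_floor <= 0)
    stop("'log_floor' must be a single positive number", call. = FALSE)
  obj <- structure(
    list(name = as.character(name), exprs = exprs, probe_map = probe_map,
         annotations = annotations, platform_label = as.character(platform_label),
         log_floor = log_floor, pairs = NULL),
    class = "lr_dataset"
  )
  obj$pairs <- pair_samples(obj)
  obj
}

.validate_annotations <- function(annotations) {
  need <- c("sample_id", "patient_id", "tissue")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("annotations must have columns sample_id, patient_id, tissue", call. = FALSE)
  annotations <- annotations[, need]
  for (col in need) annotations[[col]] <- as.character(annotations[[col]])
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample_id in annotations", call. = FALSE)
  bad <- setdiff(unique(annotations$tissue), c("tumor", "normal"))
  if (length(bad))
    stop(sprintf("tissue must be 'tumor' or 'normal'; found: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  key <- paste(annotations$patient_id, annotations$tissue)
  if (anyDuplicated(key)) {
    dupd <- unique(annotations$patient_id[duplicated(key)])
    stop(sprintf("patient(s) with more than one sample per tissue: %s",
                 paste(dupd, collapse = ", ")), call. = FALSE)
  }
  annotations
}

#' @export
print.lr_dataset <- function(x, ...) {
  cat(sprintf("<lr_dataset '%s': %d probes x %d samples, %d patient pairs%s>\n",
              x$name, nrow(x$exprs), ncol(x$exprs), nrow(x$pairs),
              if (nzchar(x$platform_label)) paste0(", platform ", x$platform_label) else ""))
  invisible(x)
}

#' Load a paired expression dataset from TSV files
#'
#' File dialects (all UTF-8, tab-delimited, header row mandatory):
#' * matrix: first column `probe_id`, remaining columns one per sample,
#'   linear intensities;
#' * annotation: `sample_id`, `patient_id`, `tissue`;
#' * probe map: `probe_id`, `gene`.
#'
#' @param matrix_path,annotation_path,probe_map_path input file paths.
#' @param name dataset label; defaults to the matrix file name.
#' @param platform_label free-text platform description.
#' @param log_floor intensity floor applied before log2 (default 1.0).
#' @return An [lr_dataset].
#' @export
load_dataset <- function(matrix_path, annotation_path, probe_map_path,
                         name = basename(matrix_path), platform_label = "",
                         log_floor = 1.0) {
  for (p in c(matrix_path, annotation_path, probe_map_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  tab <- utils::read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "probe_id")
    stop(sprintf("matrix file %s must have 'probe_id' as first column", matrix_path),
         call. = FALSE)
  exprs <- as.matrix(tab[, -1, drop = FALSE])
  rownames(exprs) <- tab$probe_id
  storage.mode(exprs) <- "double"
  annotations <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  probe_map <- read_probe_map(probe_map_path)
  lr_dataset(name, exprs, probe_map, annotations,
             platform_label = platform_label, log_floor = log_floor)
}

#' Pair tumor and normal samples by patient
#'
#' One pair per patient contributing both a tumor and a normal sample;
#' patients lacking either tissue are dropped (reported via `message()`), as
#' in compendia where some datasets profile more tumors than paired normals.
#'
#' @param dataset an [lr_dataset] (annotations are used; the stored pairing is
#'   recomputed, so the operation is idempotent).
#' @return Data frame with columns `patient_id`, `tumor_sample`,
#'   `normal_sample`, ordered by patient id.
#' @export
pair_samples <- function(dataset) {
  stopifnot(inherits(dataset, "lr_dataset"))
  ann <- dataset$annotations
  tum <- ann[ann$tissue == "tumor", ]
  nor <- ann[ann$tissue == "normal", ]
  shared <- sort(intersect(tum$patient_id, nor$patient_id))
  dropped <- setdiff(union(tum$patient_id, nor$patient_id), shared)
  if (length(dropped))
    message(sprintf("pair_samples [%s]: dropped %d unpaired patient(s)",
                    dataset$name, length(dropped)))
  if (length(shared) == 0)
    stop(sprintf("dataset %s has no patient with both tissues; paired analysis impossible",
                 dataset$name), call. = FALSE)
  data.frame(
    patient_id = shared,
    tumor_sample = tum$sample_id[match(shared, tum$patient_id)],
    normal_sample = nor$sample_id[match(shared, nor$patient_id)],
    stringsAsFactors = FALSE
  )
}

# log2 matrix with intensity floor; internal single source of the scale rule
.log2_exprs <- function(dataset) {
  log2(pmax(dataset$exprs, dataset$log_floor))
}

#' Extract log2 values for one probe
#'
#' Values are returned as `log2(max(intensity, log_floor))`. For
#' `group = "paired"` a list of two vectors (`tumor`, `normal`) in identical
#' patient order is returned, ready for [paired_t()].
#'
#' @param dataset an [lr_dataset].
#' @param probe_id probe to extract.
#' @param group `"tumor"`, `"normal"`, or `"paired"`.
#' @return Named numeric vector (sample ids), or for `"paired"` a list with
#'   elements `tumor`, `normal` and attribute `patient_id`.
#' @export
get_values <- function(dataset, probe_id, group = c("tumor", "normal", "paired")) {
  stopifnot(inherits(dataset, "lr_dataset"))
  group <- match.arg(group)
  if (!probe_id %in% rownames(dataset$exprs))
    stop(sprintf("unknown probe: %s", probe_id), call. = FALSE)
  vals <- log2(pmax(dataset$exprs[probe_id, ], dataset$log_floor))
  if (group == "paired") {
    out <- list(tumor = unname(vals[dataset$pairs$tumor_sample]),
                normal = unname(vals[dataset$pairs$normal_sample]))
    attr(out, "patient_id") <- dataset$pairs$patient_id
    return(out)
  }
  ids <- dataset$annotations$sample_id[dataset$annotations$tissue == group]
  vals[ids]
}

#' Write a dataset back to the TSV dialect it is loaded from
#'
#' Values round-trip at full precision (written with 17 significant digits).
#'
#' @param dataset an [lr_dataset].
#' @param matrix_path,annotation_path,probe_map_path output file paths.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, matrix_path, annotation_path, probe_map_path) {
  stopifnot(inherits(dataset, "lr_dataset"))
  mat <- data.frame(probe_id = rownames(dataset$exprs),
                    format(dataset$exprs, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(mat) <- c("probe_id", colnames(dataset$exprs))
  utils::write.table(mat, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$probe_map, probe_map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, annotation_path, probe_map_path))
}
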