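# Seeded generator of multi-dataset paired tumor/normal expression compendia
# with planted coordinated L/R pairs: controllable within-group correlation,
# tumor log2 fold changes, multi-probe genes, platform masks and unpaired
# tumor samples. Every pipeline stage can be exercised on its output without
# any external download.

#' Simulation configuration
#'
#' Defaults emulate the structure of a five-dataset paired tumor/normal
#' compendium: paired patient counts 4, 7, 16, 6, 8 (41 pairs in total) with
#' extra unpaired tumors in the first and third datasets, log-normal
#' expression noise, and a patient effect shared between the two tissues of a
#' patient that creates realistic within-pair dependence.
#'
#' The model, on the log2 scale, for gene \eqn{g}, patient \eqn{i}, tissue
#' \eqn{t}: \deqn{y = \mu_g + a_{gi} + \epsilon_{git} + \Delta_g [t =
#' \mathrm{tumor}]} with \eqn{a \sim N(0, \tau^2)} (patient effect, shared
#' between tissues), \eqn{\epsilon \sim N(0, \sigma^2)} (residual), and probe
#' values \eqn{y + N(0, \sigma_p^2)}. For a planted pair with target
#' correlation \eqn{\rho} and `group = "both"`, both the patient effects and
#' the residuals of the two genes are drawn with correlation \eqn{\rho}, so
#' the within-group correlation equals \eqn{\rho} exactly in expectation.
#' When the correlation is planted in a single group, only that group's
#' residuals are correlated (a patient effect shared between tissues cannot
#' carry group-specific correlation), so the realized correlation is
#' attenuated to \eqn{\rho \sigma^2 / (\tau^2 + \sigma^2)}.
#'
#' @param seed mandatory integer seed; all randomness flows from it (gene
#'   baselines under the master seed, then one pre-drawn sub-seed per
#'   dataset, so per-dataset streams are independent and reproducible).
#' @param n_datasets number of datasets.
#' @param n_pairs integer vector (recycled to `n_datasets`): paired patients
#'   per dataset.
#' @param n_unpaired_tumor integer vector: extra tumor-only patients per
#'   dataset (dropped by the pairing stage).
#' @param n_null_pairs number of unplanted ligand/receptor pairs (two null
#'   genes each).
#' @param baseline_mean,baseline_sd per-gene log2 baseline drawn once,
#'   shared across datasets.
#' @param sigma residual log2 noise sd.
#' @param patient_sd sd \eqn{\tau} of the patient effect.
#' @param probe_sd sd of independent per-probe noise around the gene value.
#' @param probe_multiplicity named integer vector giving the probe count of
#'   specific genes (default 1 per gene).
#' @param planted_pairs `NULL` or a data frame with columns `ligand`,
#'   `receptor`, `rho` (target within-group correlation, in \[-1, 1\]),
#'   `delta_l`, `delta_r` (tumor log2 fold changes), `group` (`"normal"`,
#'   `"tumor"` or `"both"`).
#' @param platform_masks `NULL` (every gene on every platform) or a list of
#'   `n_datasets` character vectors of the genes measured on each platform.
#' @param dataset_names labels; default roman numerals.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_datasets = 5,
                              n_pairs = c(4, 7, 16, 6, 8),
                              n_unpaired_tumor = c(3, 0, 7, 0, 0),
                              n_null_pairs = 50,
                              baseline_mean = 8, baseline_sd = 1,
                              sigma = 0.5, patient_sd = 0.5, probe_sd = 0.1,
                              probe_multiplicity = NULL,
                              planted_pairs = NULL,
                              platform_masks = NULL,
                              dataset_names = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  n_pairs <- rep_len(as.integer(n_pairs), n_datasets)
  n_unpaired_tumor <- rep_len(as.integer(n_unpaired_tumor), n_datasets)
  if (any(n_pairs < 2)) stop("each dataset needs >= 2 patient pairs", call. = FALSE)
  if (sigma < 0 || patient_sd < 0 || probe_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (!is.null(planted_pairs)) {
    need <- c("ligand", "receptor", "rho", "delta_l", "delta_r", "group")
    missing_cols <- setdiff(need, names(planted_pairs))
    if (length(missing_cols))
      stop(sprintf("planted_pairs lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    if (any(planted_pairs$rho < -1 | planted_pairs$rho > 1))
      stop("planted rho must lie in [-1, 1]", call. = FALSE)
    bad_group <- setdiff(unique(planted_pairs$group), c("normal", "tumor", "both"))
    if (length(bad_group))
      stop(sprintf("planted group must be normal/tumor/both; found: %s",
                   paste(bad_group, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(probe_multiplicity)) {
    if (is.null(names(probe_multiplicity)) || any(probe_multiplicity < 1))
      stop("'probe_multiplicity' must be a named vector of counts >= 1", call. = FALSE)
  }
  if (is.null(dataset_names))
    dataset_names <- as.character(utils::as.roman(seq_len(n_datasets)))
  if (!is.null(platform_masks) && length(platform_masks) != n_datasets)
    stop("'platform_masks' must have one gene set per dataset", call. = FALSE)
  structure(
    list(seed = seed, n_datasets = n_datasets, n_pairs = n_pairs,
         n_unpaired_tumor = n_unpaired_tumor, n_null_pairs = n_null_pairs,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         sigma = sigma, patient_sd = patient_sd, probe_sd = probe_sd,
         probe_multiplicity = probe_multiplicity,
         planted_pairs = planted_pairs, platform_masks = platform_masks,
         dataset_names = dataset_names),
    class = "simulation_config"
  )
}

# n draws of a standard bivariate normal with correlation rho (two columns)
.rbinorm <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Simulate a paired tumor/normal expression compendium
#'
#' @param config a [simulation_config()].
#' @return A list with elements
#'   * `datasets`: list of [lr_dataset] objects (one per platform);
#'   * `catalog`: the [lr_catalog] of planted plus null pairs;
#'   * `truth`: list with `pairs` (planted parameters per pair) and `genes`
#'     (per-gene `delta` and `modulated` flag);
#'   * `config`: the configuration used.
#'   Identical seeds give identical output.
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  planted <- config$planted_pairs
  null_lig <- sprintf("NLIG%03d", seq_len(config$n_null_pairs))
  null_rec <- sprintf("NREC%03d", seq_len(config$n_null_pairs))
  catalog <- lr_catalog(
    ligand = c(if (!is.null(planted)) planted$ligand, null_lig),
    receptor = c(if (!is.null(planted)) planted$receptor, null_rec),
    category = c(if (!is.null(planted)) rep("planted", nrow(planted)),
                 rep("null", config$n_null_pairs)),
    source_name = "simulated"
  )
  genes <- unique(c(catalog$ligand, catalog$receptor))
  n_genes <- length(genes)
  delta_of <- stats::setNames(rep(0, n_genes), genes)
  if (!is.null(planted)) {
    delta_of[planted$ligand] <- planted$delta_l
    delta_of[planted$receptor] <- planted$delta_r
  }
  multi <- stats::setNames(rep(1L, n_genes), genes)
  if (!is.null(config$probe_multiplicity)) {
    known <- intersect(names(config$probe_multiplicity), genes)
    multi[known] <- as.integer(config$probe_multiplicity[known])
  }

  set.seed(config$seed)
  mu <- stats::setNames(stats::rnorm(n_genes, config$baseline_mean,
                                     config$baseline_sd), genes)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, config$n_datasets)

  masks <- config$platform_masks
  if (!is.null(masks) && !is.null(planted)) {
    measurable <- vapply(seq_len(config$n_datasets), function(d) {
      any(planted$ligand %in% masks[[d]] & planted$receptor %in% masks[[d]])
    }, logical(1))
    if (!any(measurable))
      warning("platform masks remove every planted pair from every dataset",
              call. = FALSE)
  }

  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    set.seed(dataset_seeds[d])
    np <- config$n_pairs[d]
    nu <- config$n_unpaired_tumor[d]
    P <- np + nu                      # patients; first np contribute pairs
    tau <- config$patient_sd
    sg <- config$sigma
    A  <- matrix(stats::rnorm(n_genes * P,  sd = tau), n_genes, P,
                 dimnames = list(genes, NULL))
    ET <- matrix(stats::rnorm(n_genes * P,  sd = sg),  n_genes, P,
                 dimnames = list(genes, NULL))
    EN <- matrix(stats::rnorm(n_genes * np, sd = sg),  n_genes, np,
                 dimnames = list(genes, NULL))
    if (!is.null(planted)) {
      for (k in seq_len(nrow(planted))) {
        lg <- planted$ligand[k]; rg <- planted$receptor[k]
        rho <- planted$rho[k]; grp <- planted$group[k]
        if (grp == "both") {
          za <- .rbinorm(P, rho) * tau
          A[lg, ] <- za[, 1]; A[rg, ] <- za[, 2]
          zt <- .rbinorm(P, rho) * sg
          ET[lg, ] <- zt[, 1]; ET[rg, ] <- zt[, 2]
          zn <- .rbinorm(np, rho) * sg
          EN[lg, ] <- zn[, 1]; EN[rg, ] <- zn[, 2]
        } else if (grp == "tumor") {
          zt <- .rbinorm(P, rho) * sg
          ET[lg, ] <- zt[, 1]; ET[rg, ] <- zt[, 2]
        } else {
          zn <- .rbinorm(np, rho) * sg
          EN[lg, ] <- zn[, 1]; EN[rg, ] <- zn[, 2]
        }
      }
    }
    tum_log2 <- mu + delta_of + A + ET        # column-wise recycling over patients
    nor_log2 <- mu + A[, seq_len(np), drop = FALSE] + EN

    keep_genes <- if (is.null(masks)) genes else intersect(genes, masks[[d]])
    if (length(keep_genes) == 0)
      stop(sprintf("platform mask of dataset %s removes every gene",
                   config$dataset_names[d]), call. = FALSE)
    probe_map <- data.frame(
      probe_id = unlist(lapply(keep_genes, function(g)
        if (multi[g] == 1L) g else paste0(g, "_p", seq_len(multi[g])))),
      gene = rep(keep_genes, times = multi[keep_genes]),
      stringsAsFactors = FALSE
    )
    gm_t <- tum_log2[probe_map$gene, , drop = FALSE]
    gm_n <- nor_log2[probe_map$gene, , drop = FALSE]
    if (config$probe_sd > 0) {
      gm_t <- gm_t + stats::rnorm(length(gm_t), sd = config$probe_sd)
      gm_n <- gm_n + stats::rnorm(length(gm_n), sd = config$probe_sd)
    }
    name <- config$dataset_names[d]
    tum_ids <- sprintf("%s_P%02d_T", name, seq_len(P))
    nor_ids <- sprintf("%s_P%02d_N", name, seq_len(np))
    exprs <- cbind(2^gm_t, 2^gm_n)
    dimnames(exprs) <- list(probe_map$probe_id, c(tum_ids, nor_ids))
    annotations <- data.frame(
      sample_id = c(tum_ids, nor_ids),
      patient_id = c(sprintf("%s_P%02d", name, seq_len(P)),
                     sprintf("%s_P%02d", name, seq_len(np))),
      tissue = c(rep("tumor", P), rep("normal", np)),
      stringsAsFactors = FALSE
    )
    datasets[[d]] <- suppressMessages(
      lr_dataset(name, exprs, probe_map, annotations,
                 platform_label = sprintf("simulated platform %d (%d genes)",
                                          d, length(keep_genes)))
    )
  }

  truth_pairs <- if (is.null(planted)) {
    data.frame(ligand = character(0), receptor = character(0), rho = numeric(0),
               delta_l = numeric(0), delta_r = numeric(0), group = character(0),
               stringsAsFactors = FALSE)
  } else {
    planted[, c("ligand", "receptor", "rho", "delta_l", "delta_r", "group")]
  }
  truth_genes <- data.frame(gene = genes, delta = unname(delta_of[genes]),
                            modulated = unname(delta_of[genes] != 0),
                            stringsAsFactors = FALSE)
  list(datasets = datasets, catalog = catalog,
       truth = list(pairs = truth_pairs, genes = truth_genes),
       config = config)
}

#' Write a simulated compendium as a fixture bundle on disk
#'
#' Emits, per dataset, matrix/annotation/probe-map TSVs in the dialects read
#' by [load_dataset()], plus `catalog.tsv`, `truth_pairs.tsv`,
#' `truth_genes.tsv` and a `manifest.json` recording the seed and file list.
#' The bundle is byte-deterministic for a fixed compendium.
#'
#' @param compendium output of [simulate_compendium()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_bundle <- function(compendium, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", dir), call. = FALSE)
  }
  files <- character(0)
  ds_entries <- list()
  for (ds in compendium$datasets) {
    base <- paste0("dataset_", ds$name)
    paths <- file.path(dir, paste0(base, c("_matrix.tsv", "_annotations.tsv",
                                           "_probe_map.tsv")))
    write_dataset(ds, paths[1], paths[2], paths[3])
    files <- c(files, basename(paths))
    ds_entries[[length(ds_entries) + 1]] <- list(
      name = ds$name, matrix = basename(paths[1]),
      annotations = basename(paths[2]), probe_map = basename(paths[3])
    )
  }
  cat_path <- file.path(dir, "catalog.tsv")
  utils::write.table(as.data.frame(compendium$catalog), cat_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tp_path <- file.path(dir, "truth_pairs.tsv")
  utils::write.table(compendium$truth$pairs, tp_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tg_path <- file.path(dir, "truth_genes.tsv")
  utils::write.table(compendium$truth$genes, tg_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, basename(c(cat_path, tp_path, tg_path)))
  manifest <- list(seed = compendium$config$seed, datasets = ds_entries,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Reload a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir bundle directory containing `manifest.json`.
#' @return A list with `datasets`, `catalog`, `truth` and `seed`; expression
#'   values round-trip exactly.
#' @export
load_fixture_bundle <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop(sprintf("no manifest.json in %s", dir), call. = FALSE)
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  datasets <- lapply(manifest$datasets, function(e) {
    suppressMessages(load_dataset(
      file.path(dir, e$matrix), file.path(dir, e$annotations),
      file.path(dir, e$probe_map), name = e$name
    ))
  })
  catalog <- suppressMessages(read_lr_catalog(file.path(dir, "catalog.tsv")))
  truth <- list(
    pairs = utils::read.delim(file.path(dir, "truth_pairs.tsv"),
                              stringsAsFactors = FALSE),
    genes = utils::read.delim(file.path(dir, "truth_genes.tsv"),
                              stringsAsFactors = FALSE)
  )
  list(datasets = datasets, catalog = catalog, truth = truth,
       seed = manifest$seed)
}
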