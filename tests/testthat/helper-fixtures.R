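# In-code builders for tiny datasets and catalogs used across the suite.

# A dataset built directly from a log2 value matrix (linear = 2^log2),
# one probe per row, paired patients P1..Pn plus optional unpaired tumors.
tiny_dataset <- function(log2_tumor, log2_normal, genes = NULL,
                         name = "T", log_floor = 1.0) {
  stopifnot(nrow(log2_tumor) == nrow(log2_normal))
  probes <- rownames(log2_tumor)
  if (is.null(probes)) probes <- sprintf("probe%02d", seq_len(nrow(log2_tumor)))
  if (is.null(genes)) genes <- probes
  np <- ncol(log2_normal)
  nt <- ncol(log2_tumor)
  tum_ids <- sprintf("%s_P%02d_T", name, seq_len(nt))
  nor_ids <- sprintf("%s_P%02d_N", name, seq_len(np))
  exprs <- cbind(2^log2_tumor, 2^log2_normal)
  dimnames(exprs) <- list(probes, c(tum_ids, nor_ids))
  ann <- data.frame(
    sample_id = c(tum_ids, nor_ids),
    patient_id = c(sprintf("%s_P%02d", name, seq_len(nt)),
                   sprintf("%s_P%02d", name, seq_len(np))),
    tissue = c(rep("tumor", nt), rep("normal", np)),
    stringsAsFactors = FALSE
  )
  pm <- data.frame(probe_id = probes, gene = genes, stringsAsFactors = FALSE)
  suppressMessages(lr_dataset(name, exprs, pm, ann, log_floor = log_floor))
}

# Minimal calls table for meta_selection tests.
calls_row <- function(probe, gene, dataset, ratio, sig) {
  data.frame(probe_id = probe, gene = gene, dataset = dataset,
             tn_ratio = ratio, p = if (sig) 0.001 else 0.5,
             q = if (sig) 0.01 else 0.9,
             direction = ifelse(ratio > 1, "up", ifelse(ratio < 1, "down", "flat")),
             significant = sig, stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up (independent double-loop route).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[o][j] / j), numeric(1))
    q[o[i]] <- min(vals)
  }
  q
}

# Brute-force enumeration of the anchor rule for small instances:
# report every universe pair with a qualified member, directed by the shared
# direction / single qualified member / receptor on conflict.
enumerate_bruteforce <- function(calls, universe, min_datasets = 3) {
  qualified <- function(probe) {
    sub <- calls[calls$probe_id == probe & calls$significant, ]
    if (nrow(sub) < min_datasets) return(NA_character_)
    dirs <- unique(sub$direction)
    if (length(dirs) != 1 || dirs == "flat") return(NA_character_)
    dirs
  }
  out <- list()
  for (i in seq_len(nrow(universe))) {
    ld <- qualified(universe$ligand_probe[i])
    rd <- qualified(universe$receptor_probe[i])
    if (is.na(ld) && is.na(rd)) next
    dir <- if (!is.na(ld) && !is.na(rd)) {
      if (ld == rd) ld else rd     # receptor wins a conflict
    } else if (!is.na(ld)) ld else rd
    out[[length(out) + 1]] <- data.frame(
      ligand_probe = universe$ligand_probe[i],
      receptor_probe = universe$receptor_probe[i],
      direction = dir, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(ligand_probe = character(0),
                                      receptor_probe = character(0),
                                      direction = character(0)))
  do.call(rbind, out)
}
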