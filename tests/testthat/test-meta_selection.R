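fx <- read_table2_fixture()

test_that("voting requires concordant significance in enough datasets", {
  votes <- vote_genes(fx$calls)
  egfr <- votes[votes$probe_id == "EGFR_p1", ]
  expect_true(egfr$qualified)
  expect_equal(egfr$direction, "up")
  expect_equal(egfr$qualifying_datasets, "II,III,IV")
  nrp1 <- votes[votes$probe_id == "NRP1_p1", ]
  expect_false(nrp1$qualified)
  expect_equal(nrp1$n_qualifying, 1)

  # discordant probe: significant up in 2 and down in 2 datasets
  disc <- rbind(calls_row("px", "GX", "I", 2.0, TRUE),
                calls_row("px", "GX", "II", 2.0, TRUE),
                calls_row("px", "GX", "III", 0.5, TRUE),
                calls_row("px", "GX", "IV", 0.5, TRUE))
  v <- vote_genes(disc, selection_config(min_datasets = 3))
  expect_false(v$qualified)
  expect_true(is.na(v$direction))
})

test_that("qualification is monotone in added concordant evidence", {
  base <- rbind(calls_row("px", "GX", "I", 2.0, TRUE),
                calls_row("px", "GX", "II", 2.0, TRUE),
                calls_row("px", "GX", "III", 2.0, TRUE))
  v0 <- vote_genes(base)
  expect_true(v0$qualified)
  more <- rbind(base, calls_row("px", "GX", "IV", 1.5, TRUE))
  v1 <- vote_genes(more)
  expect_true(v1$qualified)
  expect_equal(v1$direction, v0$direction)
})

test_that("anchor enumeration reports all pairings with resolved direction", {
  votes <- vote_genes(fx$calls)
  report <- enumerate_pairs(votes, fx$pairs, fx$calls)

  # receptor-anchored pair: TEK qualified down drags ANGPTL1/TEK into the report
  atk <- report[report$ligand == "ANGPTL1", ]
  expect_equal(nrow(atk), 1)
  expect_equal(atk$direction, "down")
  expect_equal(atk$anchor, "receptor")  # ANGPTL1 is significant in 2 datasets only

  # conflict: TGFB1 qualified up, TGFBR2/TGFBR3 qualified down -> receptor wins
  conflicted <- report[report$ligand == "TGFB1" &
                         report$receptor %in% c("TGFBR2", "TGFBR3"), ]
  expect_equal(nrow(conflicted), 2)
  expect_true(all(conflicted$direction == "down"))
  # while TGFB1/TGFBR1 stays in the up block via the ligand anchor
  expect_equal(report$direction[report$receptor == "TGFBR1"], "up")

  # a pair with no qualified member is absent
  expect_false(any(report$ligand == "NOSUCH"))

  # partition: directions are up/down only, no probe combination twice
  expect_true(all(report$direction %in% c("up", "down")))
  expect_equal(anyDuplicated(paste(report$ligand_probe, report$receptor_probe)), 0)
})

test_that("conflict policy 'both' reports the pair once per direction", {
  votes <- vote_genes(fx$calls)
  both <- enumerate_pairs(votes, fx$pairs, fx$calls,
                          selection_config(conflict = "both"))
  tgfbr2 <- both[both$ligand == "TGFB1" & both$receptor == "TGFBR2", ]
  expect_equal(sort(tgfbr2$direction), c("down", "up"))
})

test_that("enumeration equals a brute-force reading of the anchor rule", {
  set.seed(61)
  for (rep in 1:10) {
    n_pairs <- sample(2:5, 1)
    n_ds <- sample(3:5, 1)
    datasets <- as.character(utils::as.roman(seq_len(n_ds)))
    probes_l <- sprintf("l%d", seq_len(n_pairs))
    probes_r <- sprintf("r%d", seq_len(n_pairs))
    calls <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      do.call(rbind, lapply(datasets, function(ds) {
        rbind(
          calls_row(probes_l[i], toupper(probes_l[i]), ds,
                    sample(c(0.5, 2), 1), runif(1) < 0.5),
          calls_row(probes_r[i], toupper(probes_r[i]), ds,
                    sample(c(0.5, 2), 1), runif(1) < 0.5)
        )
      }))
    }))
    universe <- data.frame(ligand = toupper(probes_l), receptor = toupper(probes_r),
                           ligand_probe = probes_l, receptor_probe = probes_r,
                           stringsAsFactors = FALSE)
    votes <- vote_genes(calls)
    mine <- enumerate_pairs(votes, universe, config = selection_config())
    brute <- enumerate_bruteforce(calls, universe)
    expect_equal(mine[order(mine$ligand_probe), c("ligand_probe", "receptor_probe", "direction")],
                 brute[order(brute$ligand_probe), ],
                 ignore_attr = TRUE)
  }
})

test_that("co-significance counts datasets where both members pass", {
  expect_equal(count_cosignificance(fx$calls, "TGFA_p1", "EGFR_p1"), 2)
  expect_equal(count_cosignificance(fx$calls, "CCL13_p1", "CCR1_p1"), 2)
  # a member significant nowhere contributes zero
  calls <- rbind(calls_row("a", "A", "I", 2, FALSE),
                 calls_row("b", "B", "I", 2, TRUE))
  expect_equal(count_cosignificance(calls, "a", "b"), 0)
})

test_that("the long report is deterministic and handles empty input", {
  votes <- vote_genes(fx$calls)
  report <- enumerate_pairs(votes, fx$pairs, fx$calls)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  emit_report(report, fx$calls, f1)
  emit_report(report, fx$calls, f2)
  expect_identical(readLines(f1), readLines(f2))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  emit_report(report[0, ], fx$calls, f3)
  expect_equal(length(readLines(f3)), 1)  # header only
})
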