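test_that("read_pdb_calpha extracts C-alpha coordinates and flags chains", {
  path <- withr::local_tempfile(fileext = ".pdb")
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  write_toy_pdb(path, coords)

  cf <- read_pdb_calpha(path, "A")
  expect_s3_class(cf, "conformation")
  expect_equal(unname(cf$coords), coords)
  expect_true(all(cf$present))
  expect_equal(attr(cf, "resno"), c("1", "2", "3"))

  expect_error(read_pdb_calpha(path, "Z"), "available: A")
})

test_that("alternate locations are resolved by the requested policy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    pdb_atom_line(1, 1, 0, 0, 0),
    pdb_atom_line(2, 2, 1, 0, 0, alt = "A", occ = 0.3),
    pdb_atom_line(3, 2, 9, 9, 9, alt = "B", occ = 0.7),
    pdb_atom_line(4, 3, 0, 1, 0),
    "END")
  writeLines(lines, path)

  first <- read_pdb_calpha(path, "A", altloc_policy = "first")
  expect_equal(unname(first$coords[2, ]), c(1, 0, 0))
  occ <- read_pdb_calpha(path, "A", altloc_policy = "occupancy")
  expect_equal(unname(occ$coords[2, ]), c(9, 9, 9))
})

test_that("residues without a C-alpha are masked absent, and a chain without
           any C-alpha errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    pdb_atom_line(1, 1, 0, 0, 0),
    pdb_atom_line(2, 2, 5, 5, 5, elety = " CB "),  # residue 2: no CA
    pdb_atom_line(3, 3, 0, 1, 0),
    "END")
  writeLines(lines, path)
  cf <- read_pdb_calpha(path, "A")
  expect_equal(cf$present, c(TRUE, FALSE, TRUE))

  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, 1, 0, 0, 0, elety = " CB "), "END"), path2)
  expect_error(read_pdb_calpha(path2, "A"), "no C-alpha")
})

test_that("apply_alignment re-indexes residues onto common columns", {
  cf <- conformation("c1", matrix(seq_len(15), 5, 3))

  identity_map <- data.frame(chain_key = "c1", source_resnum = as.character(1:5),
                             column = 0:4)
  out <- apply_alignment(cf, identity_map, 5)
  expect_equal(out$coords, cf$coords)
  expect_true(all(out$present))

  # residues {1,2,3} of a 3-residue chain sent to columns {0,2,4}
  cf3 <- conformation("c3", matrix(1:9, 3, 3))
  map3 <- data.frame(chain_key = "c3", source_resnum = as.character(1:3),
                     column = c(0L, 2L, 4L))
  out3 <- apply_alignment(cf3, map3, 5)
  expect_equal(out3$present, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out3$coords[c(1, 3, 5), ], cf3$coords)

  # two chains with offset numbering mapped to the same columns
  cfA <- conformation("a", matrix(rnorm(9), 3))
  attr(cfA, "resno") <- c("10", "11", "12")
  cfB <- conformation("b", matrix(rnorm(9), 3))
  attr(cfB, "resno") <- c("210", "211", "212")
  map <- rbind(
    data.frame(chain_key = "a", source_resnum = as.character(10:12), column = 1:3),
    data.frame(chain_key = "b", source_resnum = as.character(210:212), column = 1:3))
  outA <- apply_alignment(cfA, map, 5)
  outB <- apply_alignment(cfB, map, 5)
  expect_equal(outA$present, outB$present)

  dup <- data.frame(chain_key = "a", source_resnum = c("10", "11"),
                    column = c(2L, 2L))
  expect_error(apply_alignment(cfA, dup, 5), "twice")
})

test_that("apply_alignment never invents coordinates", {
  cf <- conformation("c1", matrix(rnorm(12), 4), present = c(TRUE, FALSE, TRUE, TRUE))
  map <- data.frame(chain_key = "c1", source_resnum = as.character(1:4),
                    column = 0:3)
  out <- apply_alignment(cf, map, 6)
  expect_true(all(which(out$present) %in% 1:4))
  expect_equal(out$present[1:4], cf$present)
})

test_that("complete_case_filter drops incomplete conformations, then columns,
           then excluded ids", {
  full <- function(id) conformation(id, matrix(rnorm(12), 4))
  set0 <- ensemble_set(list(e1 = list(full("a"), full("b")),
                            e2 = list(full("c"))))
  res0 <- complete_case_filter(set0)
  expect_equal(res0$set$n_atoms, 4L)
  expect_equal(res0$report$dropped_incomplete_conformations, 0L)
  expect_equal(res0$report$dropped_columns, 0L)
  expect_equal(res0$report$dropped_excluded, 0L)

  # conformation missing 3 of 4 columns at threshold 0.5 is dropped whole
  nearly_empty <- conformation("bad", matrix(rnorm(12), 4),
                               present = c(TRUE, FALSE, FALSE, FALSE))
  set1 <- ensemble_set(list(e1 = list(full("a"), full("b")),
                            e2 = list(nearly_empty)))
  res1 <- complete_case_filter(set1, max_missing_frac_conf = 0.5)
  expect_equal(res1$report$dropped_incomplete_conformations, 1L)
  expect_equal(res1$report$dropped_columns, 0L)
  expect_equal(res1$set$n_atoms, 4L)

  # one conformation missing only column 2: the column is dropped instead
  miss2 <- conformation("m", matrix(rnorm(12), 4),
                        present = c(TRUE, FALSE, TRUE, TRUE))
  set2 <- ensemble_set(list(e1 = list(full("a"), miss2), e2 = list(full("c"))))
  res2 <- complete_case_filter(set2, max_missing_frac_conf = 0.5)
  expect_equal(res2$report$dropped_incomplete_conformations, 0L)
  expect_equal(res2$report$dropped_columns, 1L)
  expect_equal(res2$set$n_atoms, 3L)
  expect_equal(sum(res2$set$sizes), 3L)

  # manual outlier exclusion
  res3 <- complete_case_filter(set0, exclude_ids = "c")
  expect_equal(res3$report$dropped_excluded, 1L)
  expect_equal(res3$set$n_ensembles, 1L)

  expect_error(complete_case_filter(set0, exclude_ids = c("a", "b", "c")),
               "no complete cases")
})

test_that("filtering is idempotent", {
  set.seed(7)
  confs <- lapply(1:5, function(i) {
    pres <- runif(6) > 0.25
    conformation(paste0("c", i), matrix(rnorm(18), 6), present = pres)
  })
  set <- ensemble_set(list(e1 = confs[1:3], e2 = confs[4:5]))
  once <- complete_case_filter(set)
  twice <- complete_case_filter(once$set)
  expect_equal(twice$set, once$set)
  expect_equal(sum(unlist(twice$report[, 2:4])), 0)
})

test_that("write_superposed_pdb applies transforms and round-trips to PDB
           precision", {
  set.seed(1)
  X <- matrix(round(rnorm(15, sd = 5), 3), 5)
  path <- withr::local_tempfile(fileext = ".pdb")

  # identity transform: coordinates echoed at 3 decimals
  write_superposed_pdb(list(conformation("a", X)), list(rigid_transform()), path)
  back <- read_pdb_calpha(path, "A")
  expect_equal(unname(back$coords), X, tolerance = 1e-9)

  # pure translation by (10, 0, 0): all x shifted by -10
  tr <- rigid_transform(c(10, 0, 0), diag(3))
  write_superposed_pdb(list(conformation("a", X)), list(tr), path)
  back <- read_pdb_calpha(path, "A")
  expect_equal(unname(back$coords[, 1]), X[, 1] - 10, tolerance = 1e-9)

  # 90-degree z-rotation acting on a unit-x point: (X - 1 t^T) R sends
  # e_x to (0, -1, 0) for the counterclockwise rotation matrix
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  P <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1))
  write_superposed_pdb(list(conformation("p", P)),
                       list(rigid_transform(c(0, 0, 0), Rz)), path)
  back <- read_pdb_calpha(path, "A")
  expect_equal(unname(back$coords[1, ]), c(0, -1, 0), tolerance = 1e-9)
})

test_that("coordinate tables round-trip ensembles exactly at written
           precision", {
  set.seed(2)
  set <- set_from_matrices(list(
    lapply(1:2, function(j) round(matrix(rnorm(12), 4), 6)),
    lapply(1:3, function(j) round(matrix(rnorm(12), 4), 6))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coord_table(set, path)
  back <- read_coord_table(path)
  expect_equal(back$sizes, set$sizes)
  expect_equal(back$ensembles$g1[[1]]$coords, set$ensembles$g1[[1]]$coords)
  expect_equal(back$ensembles$g2[[3]]$coords, set$ensembles$g2[[3]]$coords)
})

test_that("build_dataset drives the whole import path from a manifest", {
  dir <- withr::local_tempdir()
  set.seed(3)
  base <- matrix(rnorm(15, sd = 4), 5)
  paths <- character(4)
  for (k in 1:4) {
    paths[k] <- file.path(dir, sprintf("s%d.pdb", k))
    write_toy_pdb(paths[k], round(base + rnorm(15, sd = 0.3), 3))
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(data.frame(ensemble_id = c("e1", "e1", "e2", "e2"),
                         conformation_id = paste0("c", 1:4),
                         path = paths, chain = "A"),
              manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  amap <- file.path(dir, "map.tsv")
  write.table(data.frame(chain_key = rep(paste0("c", 1:4), each = 5),
                         source_resnum = rep(1:5, 4),
                         column = rep(0:4, 4)),
              amap, sep = "\t", row.names = FALSE, quote = FALSE)

  res <- build_dataset(manifest, amap)
  expect_s3_class(res, "filter_result")
  expect_equal(res$set$n_ensembles, 2L)
  expect_equal(res$set$n_atoms, 5L)

  bad <- file.path(dir, "bad_manifest.tsv")
  write.table(data.frame(ensemble_id = "e1", conformation_id = "cX",
                         path = file.path(dir, "missing.pdb"), chain = "A"),
              bad, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(build_dataset(bad, amap), "missing.pdb")
})
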