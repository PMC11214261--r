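test_that("SMILES parsing builds the expected heavy-atom graphs", {
  b <- parseStructure("c1ccccc1")
  expect_equal(nrow(b$atoms), 6)
  expect_equal(nrow(b$bonds), 6)
  expect_true(all(b$bonds$aromatic))
  expect_true(all(b$atoms$element == "C"))

  e <- parseStructure("CCO")
  expect_equal(nrow(e$atoms), 3)
  expect_equal(sort(e$atoms$element), c("C", "C", "O"))
  expect_equal(nrow(e$bonds), 2)
  expect_true(all(e$bonds$order == 1L & !e$bonds$aromatic))

  expect_error(parseStructure("not-a-smiles"), "unparseable")
  expect_error(parseStructure(""), "non-empty")

  # formal charges land in atom tokens via the charge column
  ac <- parseStructure("CC(=O)[O-]")
  expect_equal(sum(ac$atoms$charge == -1L), 1)
  expect_equal(ac$atoms$element[ac$atoms$charge == -1L], "O")
})

test_that("CSV reading keeps valid rows, skips bad ones, orders labels by appearance", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("smiles,activity",
               "CCO,active",
               "c1ccccc1,inactive",
               "xxxx,active",
               "CCN,active"), csv)
  expect_message(
    ds <- readChemDataset(csv, "csv", labelColumn = "activity",
                          task = "classification"),
    "skipped 1")
  expect_equal(length(ds), 3)
  expect_equal(labelDomain(ds), c("active", "inactive"))
  expect_error(readChemDataset(csv, "csv", labelColumn = "nope"),
               "not found")

  allBad <- tempfile(fileext = ".csv")
  writeLines(c("smiles,activity", "xx,1", "yy,2"), allBad)
  expect_error(suppressMessages(
    readChemDataset(allBad, "csv", labelColumn = "activity")),
    "no valid records")
})

test_that("SDF reading pulls labels from named properties", {
  ds0 <- genToyMolecules(3, "aromatic-count", seed = 2)
  smiles <- attr(ds0, "smiles")
  sdf <- tempfile(fileext = ".sdf")
  blocks <- vapply(seq_along(smiles), function(i) {
    conv <- conformalsig:::.obConvertSmiles(smiles[i])
    body <- sub("\\$\\$\\$\\$\\n?$", "", conv$sdf)
    paste0(body, "> <activity>\n", i * 1.5, "\n\n$$$$\n")
  }, character(1))
  writeLines(paste(blocks, collapse = ""), sdf)
  ds <- readChemDataset(sdf, "sdf", labelColumn = "activity",
                        task = "regression")
  expect_equal(length(ds), 3)
  expect_equal(datasetLabels(ds), c(1.5, 3.0, 4.5))
})

test_that("duplicate structures are kept but reported", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("smiles,y", "CCO,1", "OCC,1", "CC,0"), csv)
  expect_warning(
    ds <- readChemDataset(csv, "csv", labelColumn = "y",
                          task = "classification"),
    "duplicate")
  expect_equal(length(ds), 3)
})

test_that("external descriptors attach by id and respect policy", {
  ds <- toyMolecules()[1:3]
  tab <- data.frame(id = recordIds(ds), logp = c(1.1, 2.2, 3.3),
                    tpsa = c(10, 20, 30))
  ds2 <- attachDescriptors(ds, tab)
  expect_equal(ncol(ds2@extra), 2)
  expect_equal(ds2@extra$logp, c(1.1, 2.2, 3.3))

  expect_error(attachDescriptors(ds, tab[1:2, ]), "missing")
  ds3 <- attachDescriptors(ds, tab[1:2, ], policy = "drop-missing")
  expect_equal(length(ds3), 2)

  bad <- data.frame(id = recordIds(ds), val = c("a", "b", "c"))
  expect_error(attachDescriptors(ds, bad), "non-numeric")
  expect_identical(attachDescriptors(ds, data.frame()), ds)
})

test_that("random splits are reproducible, disjoint and exhaustive", {
  st <- samplingStrategy("random", 0.2, seed = 7)
  sp1 <- splitSampling(st, 100)
  sp2 <- splitSampling(st, 100)
  expect_identical(sp1, sp2)
  expect_equal(length(sp1[[1]]$calibration), 20)
  expect_equal(sort(c(sp1[[1]]$properTrain, sp1[[1]]$calibration)), 1:100)

  expect_error(splitSampling(samplingStrategy("random", 0.00001), 10),
               "infeasible")
})

test_that("stratified splits preserve class proportions", {
  labels <- factor(rep(c("a", "b"), c(90, 10)))
  st <- samplingStrategy("random-stratified", 0.2, seed = 3)
  sp <- splitSampling(st, 100, labels)
  calClasses <- table(labels[sp[[1]]$calibration])
  expect_equal(as.integer(calClasses), c(18, 2))
})

test_that("fold splits partition the data into k disjoint calibration parts", {
  st <- samplingStrategy("fold", nSplits = 5, seed = 9)
  sp <- splitSampling(st, 100)
  expect_length(sp, 5)
  cal <- lapply(sp, `[[`, "calibration")
  expect_equal(sort(unlist(cal)), 1:100)
  expect_equal(sum(duplicated(unlist(cal))), 0)
  for (s in sp)
    expect_equal(sort(c(s$properTrain, s$calibration)), 1:100)
})

test_that("sparse text dialect round-trips exactly", {
  x <- Matrix::sparseMatrix(i = c(1, 1, 2, 4), j = c(1, 3, 2, 5),
                            x = c(1.5, 2, 1 / 3, -7.25), dims = c(4, 5))
  sfs <- sparseFeatureSet(x, c(0.1, -2, 1 / 7, 4), "regression")
  f <- tempfile()
  writeSparseMatrix(sfs, f)
  back <- readSparseMatrix(f, "regression", nFeatures = 5)
  expect_identical(as.matrix(back@x), as.matrix(sfs@x))
  expect_identical(back@y, sfs@y)
  # row 3 has no features: label-only line
  expect_equal(strsplit(readLines(f)[3], " ")[[1]][1],
               sprintf("%.17g", 1 / 7))

  clf <- sparseFeatureSet(x, c("b", "a", "b", "a"), "classification")
  writeSparseMatrix(clf, f)
  back2 <- readSparseMatrix(f, "classification", nFeatures = 5)
  expect_identical(levels(back2@y), c("b", "a"))
  expect_identical(as.character(back2@y), c("b", "a", "b", "a"))

  writeLines("1.0 3:2 2:1", f)
  expect_error(readSparseMatrix(f, "regression"), "non-ascending.*line 1")
})
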