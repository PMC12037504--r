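test_that("packaged atlas loads with 35 ordered nodes and verbatim anomalies", {
  nt <- avhNodeTable()
  tab <- as.data.frame(nt)
  expect_equal(nrow(tab), 35)
  expect_equal(tab$index, 1:35)
  expect_equal(tab$abbrev[26], "TPJ.L")
  expect_equal(unlist(tab[26, c("x", "y", "z")], use.names = FALSE),
               c(-50, -40, 20))
  rep <- validationReport(nt)
  dup <- rep[rep$issue == "duplicate_coordinates", ]
  expect_setequal(dup$rows, c("20,33", "8,34"))
  expect_true("(3,-39,20)" %in% dup$detail)
  # the printed atlas's mislabeled abbreviations are preserved, flagged
  expect_equal(tab$abbrev[13], "INS.L")
  expect_equal(tab$abbrev[34], "PUT.L")
  expect_true(any(rep$issue == "duplicate_abbreviation"))
})

test_that("dedupe collapses exact-coordinate duplicates and re-indexes", {
  nt <- avhNodeTable(dedupe = TRUE)
  tab <- as.data.frame(nt)
  expect_equal(nrow(tab), 33)  # rows 33 and 34 collapse into 20 and 8
  expect_equal(tab$index, seq_len(33))
  key <- paste(tab$x, tab$y, tab$z)
  expect_false(anyDuplicated(key) > 0)
})

test_that("node table loading validates format and reports parse errors", {
  one <- tempfile(fileext = ".csv")
  writeLines(c("index,label,abbrev,x,y,z", "1,Some region,SR,1,2,3"), one)
  nt1 <- loadNodeTable(one)
  expect_equal(nodeCount(nt1), 1)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("index,label,x,y,z", "1,Some region,1,2,3"), bad)
  expect_error(loadNodeTable(bad), "missing column.*abbrev")

  nonnum <- tempfile(fileext = ".csv")
  writeLines(c("index,label,abbrev,x,y,z",
               "1,A,A1,1,2,3", "2,B,B1,1,oops,3"), nonnum)
  expect_error(loadNodeTable(nonnum), "row 2")
})

test_that("node tables and matrices survive a write/read round trip", {
  nt <- avhNodeTable()
  f <- tempfile(fileext = ".tsv")
  writeNodeTable(nt, f)
  nt2 <- loadNodeTable(f)
  expect_equal(as.data.frame(nt2), as.data.frame(nt))

  set.seed(1)
  cm <- randomCorr(8, 40)
  g <- tempfile(fileext = ".tsv")
  writeCorrMatrix(cm, g)
  cm2 <- readCorrMatrix(g)
  expect_equal(unname(cm2), unname(cm), tolerance = 1e-12)
})

test_that("time-series loading enforces the node-table dimension", {
  nt <- avhNodeTable()
  f <- tempfile(fileext = ".tsv")
  set.seed(2)
  ts <- matrix(rnorm(180 * 35), 180, 35)
  writeTimeseries(ts, f)
  got <- loadTimeseries(f, nt)
  expect_equal(dim(got), c(180L, 35L))
  expect_equal(unname(got), unname(ts), tolerance = 1e-12)

  short <- tempfile(fileext = ".tsv")
  writeTimeseries(ts[1:10, ], short)
  expect_warning(loadTimeseries(short, nt), "10 timepoints")

  narrow <- tempfile(fileext = ".tsv")
  writeTimeseries(ts[, 1:34], narrow)
  expect_error(loadTimeseries(narrow, nt), "34 columns.*35")
})

test_that("clinical fixture yields 80 stubs forming 40 pre/post pairs", {
  stubs <- loadClinical(fixturePath("clinical_fixture_synthetic.csv"))
  expect_length(stubs, 80)
  ids <- vapply(stubs, function(r) r@subjectId, character(1))
  ses <- vapply(stubs, function(r) r@session, character(1))
  expect_equal(sum(ses == "baseline"), 40)
  expect_setequal(ids[ses == "post"], ids[ses == "baseline"])
})

test_that("clinical loading rejects malformed tables", {
  hdr <- paste("subject_id,group,session,age,sex,fd,ahrs,panss_pos",
               "panss_neg,panss_gen,panss_total", sep = ",")
  empty <- tempfile(fileext = ".csv")
  writeLines(hdr, empty)
  expect_length(loadClinical(empty), 0)

  dup <- tempfile(fileext = ".csv")
  writeLines(c(hdr,
    "P1,SZ,baseline,25,male,0.2,20,20,20,40,80",
    "P1,SZ,baseline,25,male,0.2,20,20,20,40,80"), dup)
  expect_error(loadClinical(dup), "duplicate")

  orphan <- tempfile(fileext = ".csv")
  writeLines(c(hdr, "P1,SZ,post,25,male,0.2,10,18,20,40,78"), orphan)
  expect_error(loadClinical(orphan), "pairing error")
})

test_that("spherical ROI extraction averages voxels within the radius", {
  dm <- c(12L, 12L, 12L, 4L)
  arr <- array(5, dim = dm)
  img <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), img)
  # default affine maps voxel (0-based) indices to world mm one-to-one
  ntf <- tempfile(fileext = ".csv")
  writeLines(c("index,label,abbrev,x,y,z", "1,center,C,5,5,5"), ntf)
  nt <- loadNodeTable(ntf)
  out <- extractRoiTimeseries(img, nt, radius = 3)
  expect_equal(dim(out), c(4L, 1L))
  expect_true(all(out == 5))

  # gradient fixture: signal equals the voxel's world x coordinate, so
  # the expected sphere mean comes from a brute-force voxel scan
  aff <- RNifti::xform(RNifti::readNifti(img))
  grid <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                                k = 0:(dm[3] - 1)))
  world <- cbind(grid, 1) %*% t(aff)
  d2 <- rowSums(sweep(world[, 1:3], 2, c(5, 5, 5))^2)
  xfield <- array(world[, 1], dim = dm[1:3])
  vol <- array(0, dim = dm)
  for (t in 1:4) vol[, , , t] <- xfield
  img2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), img2)
  out2 <- extractRoiTimeseries(img2, nt, radius = 6)
  expect_equal(unname(out2[1, 1]), mean(world[d2 <= 36, 1]),
               tolerance = 1e-6)
  expect_equal(attr(out2, "voxel_counts"), sum(d2 <= 36))

  # degenerate radius smaller than the voxel grid spacing
  ntq <- tempfile(fileext = ".csv")
  writeLines(c("index,label,abbrev,x,y,z", "1,off,O,5.5,5.5,5.5"), ntq)
  expect_warning(out3 <- extractRoiTimeseries(img, loadNodeTable(ntq),
                                              radius = 0.1),
                 "no voxels")
  expect_true(all(out3 == 0))
})
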