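test_that("DICOM write/read round trips pixels and the tags that matter", {
  set.seed(91)
  px <- matrix(sample(0:4095, 24 * 20, replace = TRUE), 24, 20)
  path <- tempfile(fileext = ".dcm")
  relaxmap:::dicom_write(path, list(
    SOPInstanceUID = "2.25.111", StudyInstanceUID = "2.25.222",
    SeriesInstanceUID = "2.25.333", InstanceNumber = 5L,
    SeriesDescription = "unit test", InversionTime = 350.5,
    EchoTime = 1.1, PixelSpacing = c(1.25, 1.25)), px)
  obj <- relaxmap:::dicom_read(path)
  expect_identical(obj$stored, px)
  expect_equal(obj$elements$InversionTime, 350.5)
  expect_equal(obj$elements$Rows, 24)
  expect_equal(obj$elements$Columns, 20)
  expect_equal(obj$elements$PixelSpacing, c(1.25, 1.25))
  expect_identical(obj$elements$SeriesDescription, "unit test")
  expect_identical(obj$elements$SOPInstanceUID, "2.25.111")
})

test_that("read_series assembles a stack and infers layout from series UIDs", {
  dir1 <- file.path(tempdir(), "fix_molli")
  set <- simulate_series(tiny_phantom(noise_sigma = 0, seed = 5), "T1_MOLLI",
                         out_dir = dir1)
  got <- read_series(attr(set, "paths"))
  expect_equal(length(got$images), 8)
  expect_identical(got$layout, "one_series_multi_image")
  expect_identical(got$time_kind, "TI")
  expect_equal(got$times_ms, seq(100, 1400, length.out = 8))
  # stored pixels are the rounded simulated intensities
  expect_equal(got$images[[3]], round(set$images[[3]]))

  dir2 <- file.path(tempdir(), "fix_ir")
  set2 <- simulate_series(tiny_phantom(noise_sigma = 0, seed = 6), "T1_IR",
                          out_dir = dir2)
  got2 <- read_series(attr(set2, "paths"))
  expect_identical(got2$layout, "multi_series_one_image")

  dir3 <- file.path(tempdir(), "fix_me")
  set3 <- simulate_series(tiny_phantom(noise_sigma = 0, seed = 7), "T2_ME",
                          out_dir = dir3)
  expect_identical(read_series(attr(set3, "paths"))$time_kind, "TE")
})

test_that("read_series rejects missing files, mixed geometry and absent timing", {
  expect_error(read_series(character(0)), "no input files")
  expect_error(read_series("/nonexistent/file.dcm"), "cannot read")

  d <- file.path(tempdir(), "fix_bad")
  dir.create(d, showWarnings = FALSE)
  p1 <- file.path(d, "a.dcm"); p2 <- file.path(d, "b.dcm")
  relaxmap:::dicom_write(p1, list(SOPInstanceUID = "2.25.1",
                                  StudyInstanceUID = "2.25.9",
                                  SeriesInstanceUID = "2.25.10",
                                  EchoTime = 10), matrix(1:16, 4, 4))
  relaxmap:::dicom_write(p2, list(SOPInstanceUID = "2.25.2",
                                  StudyInstanceUID = "2.25.9",
                                  SeriesInstanceUID = "2.25.10",
                                  EchoTime = 20), matrix(1:36, 6, 6))
  expect_error(read_series(c(p1, p2)), "common field-of-view")

  p3 <- file.path(d, "c.dcm")
  relaxmap:::dicom_write(p3, list(SOPInstanceUID = "2.25.3",
                                  StudyInstanceUID = "2.25.9",
                                  SeriesInstanceUID = "2.25.10"),
                         matrix(1:16, 4, 4))
  expect_error(read_series(c(p3, p3)), "timing information")
})

test_that("validation catches too few images, duplicate times and layout mismatch", {
  set <- simulate_series(tiny_phantom(noise_sigma = 0, seed = 8), "T1_MOLLI")
  expect_length(validate_source_set(set, "T1_MOLLI"), 0)

  short <- set
  short$images <- short$images[1:2]
  short$times_ms <- short$times_ms[1:2]
  short$identifiers <- short$identifiers[1:2, ]
  v <- validate_source_set(short, "T1_IR")
  expect_true(any(grepl("number of source images", v)))

  dup <- set
  dup$times_ms[2] <- dup$times_ms[1]
  expect_true(any(grepl("duplicate", validate_source_set(dup, "T1_MOLLI"))))

  # MOLLI requires one multi-image series
  wrong <- set
  wrong$layout <- "multi_series_one_image"
  expect_true(any(grepl("layout", validate_source_set(wrong, "T1_MOLLI"))))
  # T2* with offset needs 3+ images even though plain T2 needs only 2
  te3 <- simulate_series(tiny_phantom(noise_sigma = 0, seed = 9), "T2STAR_ME",
                         times_ms = c(10, 30))
  expect_true(any(grepl("number of source images",
                        validate_source_set(te3, "T2STAR_ME", use_offset = TRUE))))
  expect_length(validate_source_set(te3, "T2STAR_ME", use_offset = FALSE), 0)
})

test_that("sorting by time is stable, rejects duplicates, and mapping is order-invariant", {
  set <- simulate_series(tiny_phantom(noise_sigma = 5, seed = 10), "T1_MOLLI")
  shuffled <- set
  o <- c(5, 1, 8, 3, 7, 2, 6, 4)
  shuffled$images <- shuffled$images[o]
  shuffled$times_ms <- shuffled$times_ms[o]
  shuffled$identifiers <- shuffled$identifiers[o, ]
  sorted <- sort_by_time(shuffled)
  expect_identical(sorted$times_ms, set$times_ms)
  expect_identical(sorted$images, set$images)

  cfg <- mapping_config("T1_MOLLI", 3000, 40)
  expect_identical(compute_map(shuffled, cfg)$values,
                   compute_map(set, cfg)$values)

  dup <- set; dup$times_ms[3] <- dup$times_ms[2]
  expect_error(sort_by_time(dup), "duplicate")
})

test_that("map export to DICOM is a lossless integer-millisecond round trip", {
  spec <- tiny_phantom(noise_sigma = 0, seed = 11)
  set <- simulate_series(spec, "T2_ME")
  map <- compute_map(set, mapping_config("T2_ME", 500, 40))
  out <- tempfile(fileext = ".dcm")
  export_map_dicom(map, set, out)
  back <- read_map_dicom(out)
  expect_identical(back, round(map$values))

  # fractional milliseconds round to the nearest integer
  map2 <- map
  map2$values[5, 5] <- 600.4
  map2$config$limit_ms <- 1000
  export_map_dicom(map2, set, out)
  expect_equal(read_map_dicom(out)[5, 5], 600)

  map3 <- map
  map3$config$limit_ms <- 70000
  expect_error(export_map_dicom(map3, set, out), "65535")
})

test_that("exported files parse under pydicom with matching pixels and tags", {
  spec <- tiny_phantom(noise_sigma = 0, seed = 12)
  d <- file.path(tempdir(), "fix_pydicom")
  set <- simulate_series(spec, "T1_MOLLI", out_dir = d)
  map <- compute_map(set, mapping_config("T1_MOLLI", 3000, 40))
  out <- file.path(d, "map.dcm")
  export_map_dicom(map, set, out)

  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "arr = ds.pixel_array",
    "print(ds.Modality, ds.Rows, ds.Columns, int(arr.sum()), ds.SeriesDescription)",
    sep = "\n")
  res <- system2("python", c("-c", shQuote(script), shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status"), NULL)
  parts <- strsplit(paste(res, collapse = " "), " ")[[1]]
  expect_identical(parts[1], "MR")
  expect_equal(as.integer(parts[2:3]), c(32L, 32L))
  expect_equal(as.numeric(parts[4]), sum(round(map$values)))

  # a source fixture parses too, with the inversion time intact
  script2 <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(float(ds.InversionTime), ds.BitsAllocated)",
    sep = "\n")
  res2 <- system2("python", c("-c", shQuote(script2),
                              shQuote(attr(set, "paths")[3])),
                  stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res2, "status"), NULL)
  vals <- strsplit(trimws(paste(res2, collapse = " ")), " ")[[1]]
  expect_equal(as.numeric(vals[1]), set$times_ms[3], tolerance = 1e-6)
  expect_equal(as.integer(vals[2]), 16L)
})

test_that("graphics export quantizes as documented", {
  map <- structure(list(values = matrix(600, 8, 8), technique = "T1_MOLLI",
                        config = list(limit_ms = 1200)),
                   class = "relaxation_map")
  p <- tempfile(fileext = ".png")
  export_map_graphic(map, p)
  img <- png::readPNG(p)
  expect_true(all(round(img * 255) == 128))

  map$values <- matrix(0, 8, 8)
  export_map_graphic(map, p)
  expect_true(all(png::readPNG(p) == 0))

  # 16-bit TIFF round trip stays within the documented quantization bound
  set.seed(14)
  map$values <- matrix(runif(64, 0, 1200), 8, 8)
  tp <- tempfile(fileext = ".tiff")
  export_map_graphic(map, tp)
  back <- tiff::readTIFF(tp) * 1200
  expect_lt(max(abs(back - map$values)), 0.0002 * 1200)

  cp <- tempfile(fileext = ".png")
  map$config$limit_ms <- 1200
  export_map_graphic(map, cp, colormap = grDevices::hcl.colors(64))
  expect_equal(dim(png::readPNG(cp))[3], 3)
  expect_error(export_map_graphic(map, tempfile(fileext = ".bmp")),
               "unsupported")
})

test_that("header tables list one row per instance, grouped by series", {
  d <- file.path(tempdir(), "fix_headers")
  set <- simulate_series(tiny_phantom(noise_sigma = 0, seed = 15), "T1_MOLLI",
                         out_dir = d)
  tbl <- dump_headers(attr(set, "paths"))
  expect_equal(nrow(tbl), 8)
  expect_true(all(c("InversionTime", "SeriesInstanceUID", "Rows") %in% names(tbl)))
  expect_equal(as.numeric(tbl$InversionTime), sort(set$times_ms))

  expect_warning(tbl2 <- dump_headers(attr(set, "paths")[1],
                                      attributes = c("Rows", "NoSuchTag")),
                 "NoSuchTag")
  expect_true(all(is.na(tbl2$NoSuchTag)))

  # two different series interleaved: rows regroup by series UID
  d2 <- file.path(tempdir(), "fix_headers2")
  set2 <- simulate_series(tiny_phantom(noise_sigma = 0, seed = 16), "T2_ME",
                          out_dir = d2)
  mixed <- c(attr(set, "paths")[1], attr(set2, "paths")[1],
             attr(set, "paths")[2], attr(set2, "paths")[2])
  tbl3 <- dump_headers(mixed)
  expect_equal(rle(tbl3$SeriesInstanceUID)$lengths, c(2, 2))

  csv <- tempfile(fileext = ".csv")
  write_header_table(tbl, csv)
  expect_equal(nrow(utils::read.csv(csv)), 8)
})
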