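# Encoding of categorical tongue features into classifier inputs.

test_that("full vocabulary sweep matches the hand-built ordinal code table", {
  # written out independently of the implementation
  expected <- list(
    tongue_color = c(mild_red = 0, red = 1 / 3, pale = 2 / 3, bluish = 1),
    tongue_body = c(medium = 0, enlarged = 1 / 2, small = 1),
    fur_color = c(white = 0, black = 1 / 3, yellow = 2 / 3, none = 1),
    fur_thickness = c(thin = 0, thick = 1 / 2, no_fur = 1),
    saliva = c(normal = 0, dry = 1 / 2, wet = 1)
  )
  column_of <- c(tongue_color = 1, tongue_body = 2, fur_color = 3,
                 fur_thickness = 4, saliva = 6)
  for (feat in names(expected)) {
    for (cat in names(expected[[feat]])) {
      rec <- reference_record()
      rec[[feat]] <- cat
      if (feat == "fur_color" && cat == "none") rec$fur_thickness <- "no_fur"
      v <- encode_record(rec)
      expect_equal(unname(v[column_of[feat]]), unname(expected[[feat]][cat]),
                   info = paste(feat, cat))
    }
  }
  # every encoded vector over the vocabulary stays in [0,1]^8 and the
  # category sweep produces pairwise distinct codes per feature
  for (feat in names(expected)) {
    codes <- tongue_schema()$codes[[feat]]
    expect_equal(sort(names(codes)), sort(tongue_schema()$levels[[feat]]))
    expect_equal(anyDuplicated(codes), 0)
    expect_true(all(codes >= 0 & codes <= 1))
  }
})

test_that("reference record encodes to the baseline (all-zero) codes", {
  v <- encode_record(reference_record())
  expect_equal(as.numeric(v), rep(0, 8))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("encoding is local: one changed feature moves one coordinate", {
  a <- encode_record(reference_record())
  rec <- reference_record()
  rec$fur_thickness <- "thick"
  b <- encode_record(rec)
  expect_equal(sum(a != b), 1)
  expect_equal(unname(which(a != b)), 4)
})

test_that("spot score counts the three countable surface marks", {
  rec <- reference_record()
  rec$red_spots <- TRUE
  rec$petechiae <- TRUE
  v <- encode_record(rec)
  expect_equal(unname(v["spot_score"]), 2 / 3)
  expect_equal(unname(v["fissures"]), 0) # fissures not in the count
  rec$fissures <- TRUE
  expect_equal(unname(encode_record(rec)["fissures"]), 1)
})

test_that("decoding recovers every single-valued category", {
  schema <- tongue_schema()
  for (feat in names(schema$levels)) {
    for (cat in schema$levels[[feat]]) {
      rec <- reference_record()
      rec[[feat]] <- cat
      if (feat == "fur_color" && cat == "none") rec$fur_thickness <- "no_fur"
      if (feat == "fur_thickness" && cat == "no_fur") rec$fur_color <- "none"
      dec <- decode_vector(encode_record(rec))
      expect_equal(dec[[feat]], cat)
    }
  }
})

test_that("severity scheme reorders categories by clinical severity", {
  v_ord <- encode_record(reference_record(), "ordinal")
  v_sev <- encode_record(reference_record(), "severity")
  expect_equal(unname(v_sev), unname(v_ord)) # reference stays the baseline
  rec <- reference_record()
  rec$fur_thickness <- "thick"
  expect_equal(unname(encode_record(rec, "severity")["fur_thickness"]), 1)
})

test_that("unknown categories and missing columns are rejected with context", {
  rec <- reference_record()
  rec$tongue_color <- "purple"
  expect_error(encode_record(rec), "purple", class = "tonguenet_schema_error")
  expect_error(encode_records(reference_record()[-1]),
               "tongue_body", class = "tonguenet_schema_error")
})

test_that("feature tables round-trip byte-identically and report bad rows", {
  recs <- mixed_records(5, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(recs, path)
  back <- read_feature_table(path, require_label = TRUE)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  expect_equal(nrow(back), 5)

  # header-only file parses to an empty table
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("tongue_body", "tongue_color", "red_spots", "black_spots",
                     "fissures", "petechiae", "teeth_markings", "fur_color",
                     "saliva", "fur_thickness", "label"), collapse = ","), empty)
  expect_equal(nrow(read_feature_table(empty)), 0)

  # a bad category names the row and the offending value
  bad <- recs
  bad$tongue_color[3] <- "purple"
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(bad, pb, sep = ",", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(pb), "row 3.*purple",
               class = "tonguenet_schema_error")
})

test_that("tab dialect and prediction-mode tables are supported", {
  recs <- mixed_records(4, seed = 2)
  recs$label <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(recs, path, dialect = "tsv")
  back <- read_feature_table(path, dialect = "tsv")
  expect_equal(back$fur_color, recs$fur_color)
  expect_error(read_feature_table(path, dialect = "tsv", require_label = TRUE),
               "label", class = "tonguenet_schema_error")
  expect_null(attr(encode_records(back), "label"))
})
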