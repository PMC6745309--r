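profile_fixture <- function(stp_slope_values) {
  keys <- region_roles()
  feat <- data.frame(
    region = sub("\\..*$", "", keys), role = sub("^.*\\.", "", keys),
    feature = "stp_slope_late", value = stp_slope_values, flag = "")
  structure(list(subject_id = "fx", group_label = NA, features = feat),
            class = "tep_profile")
}

test_that("profile assembly is deterministic with the full feature schema", {
  ph <- subject_phenotype("young")
  rec <- simulate_recording(ph, tiny_protocol(), seed = 3, fs = 1000)
  p1 <- assemble_profile(rec)
  p2 <- assemble_profile(rec)
  expect_identical(p1$features, p2$features)
  expect_equal(nrow(p1$features), 8 * 7)
  expect_setequal(unique(p1$features$feature),
                  c("early_slope", "late_slope", "slope_ratio", "q",
                    "stp_q", "stp_slope_late", "stp_ratio"))
  # canonical healthy directions
  f <- p1$features
  expect_true(all(f$value[f$feature == "q"] > 0))
  # weak far-field channels may miss components at this trial count;
  # every defined region value must still have the canonical direction
  early <- f$value[f$feature == "early_slope"]
  expect_gte(sum(!is.na(early)), 6)
  expect_true(all(early < 0, na.rm = TRUE))
  expect_true(all(f$value[f$feature == "stp_slope_late"] < 0, na.rm = TRUE))
  expect_match(p1$config_hash, "^[0-9a-f]{8}$")
})

test_that("QC hard failure raises a structured error with the report attached", {
  ph <- subject_phenotype("young")
  rec <- simulate_recording(ph, tiny_protocol(), seed = 3, fs = 1000)
  cfg <- default_config()
  cfg$reject$amp_uv <- 1e9
  cfg$reject$flat_uv <- 1e6  # everything is "flat": all trials rejected
  expect_error(assemble_profile(rec, cfg), class = "tepnet_qc_error")
})

test_that("the sign-rule classifier follows the median late-slope STP sign", {
  expect_equal(classify_profile(profile_fixture(rep(-0.4, 8)))$label,
               "normal")
  expect_equal(classify_profile(profile_fixture(rep(0.3, 8)))$label,
               "abnormal")
  mixed <- classify_profile(profile_fixture(c(rep(0.3, 5), rep(-0.2, 3))))
  expect_equal(mixed$label, "abnormal")
  few <- classify_profile(profile_fixture(c(0.3, -0.2, rep(NA, 6))))
  expect_equal(few$label, "indeterminate")
  expect_length(classify_profile(profile_fixture(rep(-1, 8)))$evidence, 8)
})

test_that("region maps render deterministic PNGs with faithful sidecars", {
  keys <- region_roles()
  p <- profile_fixture(rep(-0.4, 8))
  p$features$feature <- "slope_ratio"
  m <- region_value_map(p, "slope_ratio")
  d <- withr::local_tempdir()
  f1 <- file.path(d, "m1.png")
  render_region_map(m, f1)
  expect_true(file.exists(f1))
  expect_true(file.exists(paste0(f1, ".json")))
  side <- jsonlite::read_json(paste0(f1, ".json"))
  # all regions equal value: all patches identical color
  expect_length(unique(unlist(side$colors)), 1)

  # scale midpoint maps to the middle colormap entry
  vals <- rep(-1, 8)  # midpoint of the fixed (-2, 0) slope_ratio scale
  p2 <- profile_fixture(vals); p2$features$feature <- "slope_ratio"
  m2 <- region_value_map(p2, "slope_ratio")
  f2 <- file.path(d, "m2.png")
  render_region_map(m2, f2)
  side2 <- jsonlite::read_json(paste0(f2, ".json"))
  cmap <- colormap_table("red-blue")
  expect_equal(unlist(side2$colors[[1]]),
               cmap[round(0.5 * 255) + 1])

  # independent colormap lookup for random values
  set.seed(5)
  rv <- runif(8, -2, 0)
  p3 <- profile_fixture(rv); p3$features$feature <- "slope_ratio"
  m3 <- region_value_map(p3, "slope_ratio")
  f3 <- file.path(d, "m3.png")
  render_region_map(m3, f3)
  side3 <- jsonlite::read_json(paste0(f3, ".json"))
  oracle <- cmap[round((rv - (-2)) / 2 * 255) + 1]
  expect_equal(unname(unlist(side3$colors)), oracle)

  # identical input renders identical bytes
  f4 <- file.path(d, "m4.png")
  render_region_map(m3, f4)
  expect_identical(readBin(f3, raw(), file.size(f3)),
                   readBin(f4, raw(), file.size(f4)))

  # out-of-scale values are clipped and flagged
  p5 <- profile_fixture(c(5, rep(-0.5, 7)))
  p5$features$feature <- "slope_ratio"
  m5 <- region_value_map(p5, "slope_ratio")
  expect_true(m5$clipped[[1]])
})

test_that("feature tables round-trip exactly with schema validation", {
  mk_profile <- function(id, offset) {
    keys <- region_roles()
    feats <- c("early_slope", "late_slope", "slope_ratio", "q", "stp_q",
               "stp_slope_late")
    feat <- expand.grid(key = keys, feature = feats,
                        stringsAsFactors = FALSE)
    set.seed(offset)
    structure(list(
      subject_id = id, group_label = "g1",
      features = data.frame(
        region = sub("\\..*$", "", feat$key),
        role = sub("^.*\\.", "", feat$key),
        feature = feat$feature,
        value = rnorm(nrow(feat)) * exp(rnorm(nrow(feat), 0, 5)),
        flag = "")),
      class = "tep_profile")
  }
  d <- withr::local_tempdir()
  path <- file.path(d, "features.csv")
  p1 <- mk_profile("s1", 1); p2 <- mk_profile("s2", 2)
  write_feature_table(list(p1, p2), path)
  tab <- read_feature_table(path)
  expect_equal(nrow(tab), 2 * 8 * 6)
  expect_identical(tab$value,
                   c(p1$features$value, p2$features$value))

  write_feature_table(list(), path)
  expect_equal(readLines(path),
               "subject_id,group_label,region,role,feature,value")

  p3 <- mk_profile("s3", 3)
  p3$features <- p3$features[-1, ]
  expect_error(write_feature_table(list(p1, p3), path),
               "inconsistent feature schema.*s3")
})

test_that("sham recordings yield floor-level profiles", {
  ph <- subject_phenotype("young")
  real <- simulate_recording(ph, tiny_protocol(), seed = 13, fs = 1000)
  sham <- simulate_sham(ph, tiny_protocol(), seed = 13, fs = 1000)
  pr <- assemble_profile(real)
  ps <- assemble_profile(sham)
  qr <- pr$features$value[pr$features$feature == "q"]
  qs <- ps$features$value[ps$features$feature == "q"]
  expect_lt(mean(qs) / mean(qr), 0.25)
  expect_lt(mean(ps$peaks$found), 0.3)
  expect_gte(mean(pr$peaks$found), 0.85)
})
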