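test_that("Fisher r-to-z matches closed form and is odd and monotone", {
  expect_identical(fisher_r_to_z(0), 0)
  # 0.5 * log(19), evaluated independently at high precision
  expect_equal(fisher_r_to_z(0.9), 1.47221948958322, tolerance = 1e-12)
  grid <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_r_to_z(grid)
  expect_equal(fisher_r_to_z(-grid), -z)
  expect_true(all(diff(z) > 0))
  expect_error(fisher_r_to_z(1.0), "\\|r\\| >= 1")
  expect_error(fisher_r_to_z(c(0.2, -1.2), id = c("a", "b")), "b")
})

test_that("qualitative direction classifies increases and decreases", {
  recs <- record_set(rec_df(
    rec_row("s1", "A", "B", raw_r = 0.35),
    rec_row("s2", "A", "C", direction = -1)
  ))
  expect_identical(qualitative_direction(recs), c(1L, -1L))

  zero <- record_set(rec_row("s1", "A", "B", raw_r = 0))
  expect_error(qualitative_direction(zero), "z = 0")

  # sensitivity threshold: |z| below tau is sub-threshold, dropped
  weak <- record_set(rec_df(
    rec_row("s1", "A", "B", raw_r = 0.05),
    rec_row("s1", "A", "C", raw_r = 0.8)
  ))
  expect_identical(qualitative_direction(weak, tau = 0.2), c(NA_integer_, 1L))
  signed <- suppressMessages(sign_records(weak, tau = 0.2))
  expect_identical(nrow(signed), 1L)
  expect_identical(attr(signed, "n_dropped_subthreshold"), 1L)
})

test_that("record sets enforce pair canonicalization and uniqueness", {
  r <- record_set(rec_row("s1", "Tha", "BG", direction = 1))
  expect_identical(r$region_a, "BG")
  expect_identical(r$region_b, "Tha")

  expect_error(record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s1", "B", "A", direction = 1)
  )), "duplicate")
  expect_error(record_set(rec_row("s1", "A", "A", direction = 1)),
               "self-pair")
  expect_error(record_set(rec_row("s1", "A", "B", direction = 1,
                                  raw_r = 0.5)),
               "exactly one")
  expect_error(record_set(rec_row("s1", "A", "B")), "exactly one")
})

test_that("region registry lookups are case-insensitive and closed", {
  reg <- region_registry()
  expect_identical(nrow(reg), 20L)
  expect_identical(normalize_region(c("tha", "CERE"), reg),
                   c("Tha", "Cere"))
  expect_error(normalize_region("Amyg", reg), "unknown region code")

  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("regions:",
               "  - code: OFC",
               "    name: orbitofrontal cortex",
               "merge:",
               "  orbital gyrus: OFC"), cfgfile)
  rc <- read_region_config(cfgfile)
  expect_identical(normalize_region("ofc", rc$registry), "OFC")
  expect_identical(unname(rc$merge_map["orbital gyrus"]), "OFC")
})

test_that("region merging follows the anatomical conventions", {
  recs <- record_set(rec_df(
    rec_row("s1", "anterior central gyrus", "Tha", direction = 1),
    rec_row("s2", "putamen", "caudate", direction = -1),
    rec_row("s3", "Tha", "VC", direction = 1)
  ))
  merged <- suppressMessages(merge_regions(recs))
  expect_identical(nrow(merged), 2L)  # putamen-caudate collapses into BG
  expect_identical(attr(merged, "n_dropped_self"), 1L)
  expect_true(any(merged$region_a == "SMC" & merged$region_b == "Tha"))

  # identity on registry-only labels with an empty map
  clean <- record_set(rec_row("s3", "Tha", "VC", direction = 1))
  out <- merge_regions(clean, merge_map = character(0))
  expect_identical(df_of(out), df_of(clean))

  # idempotence
  twice <- suppressMessages(merge_regions(merged))
  expect_identical(df_of(twice), df_of(merged))

  expect_error(suppressMessages(
    merge_regions(record_set(rec_row("s1", "mystery region", "Tha",
                                     direction = 1)))),
    "unmatched raw label")
})

test_that("conflicting pairs are detected and resolvable", {
  recs <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "A", "B", direction = -1),
    rec_row("s3", "A", "C", direction = 1)
  ))
  conf <- detect_conflicts(recs)
  expect_identical(nrow(conf), 1L)
  expect_identical(conf$region_a, "A")
  expect_identical(conf$region_b, "B")

  clean <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "A", "B", direction = 1)
  ))
  expect_identical(nrow(detect_conflicts(clean)), 0L)

  resolved <- suppressMessages(resolve_conflicts(recs))
  expect_identical(nrow(resolved), 1L)  # both A-B records excluded
  expect_identical(attr(resolved, "n_excluded_records"), 2L)

  # majority policy keeps the dominant sign
  maj <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "A", "B", direction = 1),
    rec_row("s3", "A", "B", direction = -1)
  ))
  kept <- suppressMessages(resolve_conflicts(maj, policy = "majority"))
  expect_identical(nrow(kept), 2L)
  expect_true(all(kept$direction == 1L))
})

test_that("planted conflicts are recovered exactly by detect_conflicts", {
  spec <- synthetic_spec(conflict_rate = 0.2, seed = 33)
  sim <- generate_records(spec)
  signed <- sign_records(sim$records)
  conf <- detect_conflicts(signed)
  found <- sort(paste(conf$region_a, conf$region_b, sep = "|"))
  expect_identical(found, sort(sim$truth$conflict_pairs))
  expect_identical(nrow(conf),
                   as.integer(round(0.2 * nrow(sim$truth$edges))))
})

test_that("cohort summaries count each study once", {
  recs <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1, n_patients = 10, n_controls = 8),
    rec_row("s1", "A", "C", direction = 1, n_patients = 10, n_controls = 8),
    rec_row("s2", "B", "C", direction = -1, n_patients = 5, n_controls = 5)
  ))
  cs <- summarize_cohort(recs)
  expect_identical(cs$n_studies, 2L)
  expect_identical(cs$total_patients, 15L)
  expect_identical(cs$total_controls, 13L)

  # invariance under record reordering
  cs2 <- summarize_cohort(record_set(as.data.frame(recs)[c(3, 1, 2), ]))
  expect_identical(cs2$total_patients, cs$total_patients)

  empty <- summarize_cohort(record_set(rec_row("s", "A", "B",
                                               direction = 1)[0, ]))
  expect_identical(empty$n_studies, 0L)
  expect_identical(empty$total_patients, 0L)

  bad <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1, n_patients = 10),
    rec_row("s1", "A", "C", direction = 1, n_patients = 12)
  ))
  expect_error(summarize_cohort(bad), "inconsistent cohort sizes")
})

test_that("the study-corpus fixture reproduces the published totals", {
  path <- system.file("extdata", "synthetic-cohort.csv", package = "jmenet")
  recs <- read_records(path, registry = region_registry())
  cs <- summarize_cohort(recs)
  expect_identical(cs$n_studies, 15L)
  expect_identical(cs$total_patients, 462L)
  expect_identical(cs$total_controls, 387L)
})

test_that("records round-trip through CSV and JSON", {
  recs <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "A", "C", raw_r = -0.4)
  ))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, csv)
  back <- read_records(csv)
  expect_equal(df_of(back), df_of(recs))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.data.frame(recs), js)
  back2 <- read_records(js)
  expect_equal(back2$raw_r, recs$raw_r)
})
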