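test_that("hazard categorization matches the keyword table", {
  expect_equal(as.character(categorize_hazard("Aflatoxin B1 in pistachio kernels")),
               "mycotoxin")
  expect_equal(as.character(categorize_hazard("Cadmium in frozen squid")),
               "metal")
  expect_equal(as.character(categorize_hazard("incorrect labelling of allergens")),
               "uncategorized")
  expect_equal(as.character(categorize_hazard("")), "uncategorized")
  expect_equal(as.character(categorize_hazard(NA_character_)), "uncategorized")
})

test_that("every keyword maps verbatim to its own category", {
  table <- rasff_keywords()
  for (cat in names(table)) {
    got <- categorize_hazard(table[[cat]], table)
    expect_equal(unname(as.character(got)), rep(cat, length(table[[cat]])),
                 label = paste("keywords of", cat))
    # case-insensitivity on upper-cased keyword
    expect_equal(as.character(categorize_hazard(toupper(table[[cat]][1]), table)),
                 cat)
  }
})

test_that("categorization is total, idempotent and resolves conflicts by table order", {
  # 'lead' (metal) and 'aflatoxin' (mycotoxin) both present: metal is first
  expect_warning(
    got <- categorize_hazard("lead and aflatoxin in spice mix"),
    "more than one category")
  expect_equal(as.character(got), "metal")
  expect_setequal(attr(got, "matches")[[1]], c("metal", "mycotoxin"))
  # applying the categorizer to its own output labels is stable nonsense-in,
  # nonsense-out: a category name is not a keyword
  expect_equal(as.character(categorize_hazard("mycotoxin", quiet = TRUE)),
               "uncategorized")
  # determinism
  texts <- c("aflatoxin", "nothing here", "mercury rising", "")
  expect_identical(categorize_hazard(texts, quiet = TRUE),
                   categorize_hazard(texts, quiet = TRUE))
})

test_that("keyword table validation rejects malformed tables", {
  expect_error(rasff_keywords(list(metal = character(0))), "non-empty")
  expect_error(rasff_keywords(list(metal = c("lead", "lead"))), "unique")
  expect_error(rasff_keywords(list(c("lead"))), "named list")
})

test_that("log construction validates types, dates and codes", {
  expect_error(
    notification_log("2007-01-01", "DEU", "IRN", "recall", "aflatoxin"),
    "unknown notification type.*row.*1")
  expect_error(
    notification_log("01/02/2007", "DEU", "IRN", "alert", "aflatoxin"),
    "ISO-8601")
  expect_warning(
    notification_log("2007-01-01", "XXA", "IRN", "alert", "aflatoxin"),
    "unknown detector code")
  expect_error(
    notification_log("2007-01-01", "XXA", "IRN", "alert", "aflatoxin",
                     allow_unknown_codes = FALSE),
    "unknown detector code")
  # self-reports allowed but flagged
  log <- notification_log("2007-01-01", "DEU", "DEU", "alert", "dioxins")
  expect_true(log$self_report)
})

test_that("read_log parses well-formed files and rejects broken ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "date,detector,transgressor,type,hazard",
    "2007-01-01,DEU,IRN,alert,aflatoxin in pistachios",
    "2007-02-01,ITA,CHN,border_rejection,mercury in swordfish",
    "2007-03-01,ESP,BRA,information,undeclared gluten"
  ), path)
  log <- read_log(path)
  expect_s3_class(log, "notification_log")
  expect_equal(nrow(log), 3L)
  expect_equal(log$category, c("mycotoxin", "metal", "uncategorized"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,transgressor,type,hazard",
               "2007-01-01,IRN,alert,aflatoxin"), bad)
  expect_error(read_log(bad), "missing column.*detector")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("date,detector,transgressor,type,hazard", empty)
  expect_error(read_log(empty), "empty")
  expect_error(read_log(file.path(tempdir(), "no-such-file.csv")), "not found")
})

test_that("the shipped example log parses with the expected categories", {
  p <- system.file("extdata", "example_log.csv", package = "rasffnet")
  log <- read_log(p)
  expect_equal(nrow(log), 12L)
  expect_equal(sum(log$category == "mycotoxin"), 4L)
  expect_equal(sum(log$self_report), 1L)  # the DEU self-report row
  expect_equal(nrow(filter_log(log, "microorganism")), 6L)
})

test_that("write_log / read_log round-trips records and categories", {
  log <- toy_log()
  path <- withr::local_tempfile(fileext = ".csv")
  write_log(log, path)
  back <- read_log(path)
  expect_equal(back$date, log$date)
  expect_equal(back$detector, log$detector)
  expect_equal(back$transgressor, log$transgressor)
  expect_equal(back$type, log$type)
  expect_equal(back$hazard, log$hazard)
  expect_equal(back$category, log$category)
  # TSV dialect
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_log(log, tsv, sep = "\t")
  expect_equal(read_log(tsv, sep = "\t")$hazard, log$hazard)
})

test_that("filter_log applies category and type filters", {
  log <- toy_log()  # 2 mycotoxin, 1 bacteria, 1 metal, 1 uncategorized
  expect_equal(nrow(filter_log(log, "mycotoxin")), 2L)
  expect_equal(nrow(filter_log(log, "microorganism")), 3L)
  expect_equal(nrow(filter_log(log, "metal")), 1L)
  # 'all' includes uncategorized and is the identity
  all_log <- filter_log(log, "all")
  expect_equal(nrow(all_log), 5L)
  expect_equal(all_log$hazard, log$hazard)
  # type filter composes with category filter
  expect_equal(nrow(filter_log(log, ntype = "border_rejection")), 1L)
  expect_equal(nrow(filter_log(log, "mycotoxin", "border_rejection")), 0L)
  expect_s3_class(filter_log(log, "mycotoxin", "border_rejection"),
                  "notification_log")
  expect_error(filter_log(log, "radioactivity"), "unknown category")
})

test_that("microorganism filter equals mycotoxin plus bacteria on generated logs", {
  log <- generate_log(default_scenario(n_notifications = 800, seed = 11))
  n_myco <- nrow(filter_log(log, "mycotoxin"))
  n_bact <- nrow(filter_log(log, "bacteria"))
  expect_equal(nrow(filter_log(log, "microorganism")), n_myco + n_bact)
  # and 'all' keeps every record
  expect_equal(nrow(filter_log(log, "all", "all")), nrow(log))
})
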