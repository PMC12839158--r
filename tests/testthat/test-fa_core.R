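# Panel metadata, cohort I/O, molar-percent conversion.

test_that("default panel carries the 24 analytes with the study's class assignment", {
  p <- default_panel()
  expect_equal(nrow(p), 24)
  expect_equal(anyDuplicated(p$name), 0)
  expect_true(all(p$molecular_weight > 0))
  cls <- split(p$name, p$lipid_class)
  expect_setequal(cls$SFA, c("C12:0", "C14:0", "C16:0", "C17:0", "C18:0",
                             "C20:0", "C22:0", "C24:0"))
  expect_setequal(cls$MUFA, c("C16:1n-7", "C18:1n-9", "C20:1n-9", "C24:1n-9"))
  expect_setequal(cls$TRANS, c("C16:1n-7t", "C18:1n-9t", "C18:2n-6t"))
  expect_setequal(cls$`PUFA-n6`, pufa_sets()$n6)
  expect_setequal(cls$`PUFA-n3`, pufa_sets()$n3)
})

test_that("panel validation enforces invariants", {
  p <- default_panel()
  bad <- p; bad$molecular_weight[1] <- -1
  expect_error(validate_panel(bad), "positive")
  bad <- p; bad$name[2] <- bad$name[1]
  expect_error(validate_panel(bad), "unique")
  expect_error(default_panel(loq = c(nonsense = 1)), "not in the panel")
})

test_that("to_molar_percent matches hand arithmetic and applies the below-LOQ exclusion", {
  panel <- default_panel()
  # single quantified analyte -> 100
  one <- data.frame(sample_id = "a", group = "g", `C18:0` = 7,
                    check.names = FALSE)
  expect_equal(to_molar_percent(one, panel)$`C18:0`, 100)
  # both analytes at 1 nmol/mL -> 50/50
  two <- data.frame(sample_id = "a", group = "g",
                    `C18:0` = 284.48, `C18:1n-9` = 282.46,
                    check.names = FALSE)
  m <- to_molar_percent(two, panel)
  expect_equal(m$`C18:0`, 50)
  expect_equal(m$`C18:1n-9`, 50)
  # third analyte below LOQ: excluded from the total, stays NA
  three <- two
  three$`C20:5n-3` <- NA_real_
  m3 <- to_molar_percent(three, panel)
  expect_equal(m3$`C18:0`, 50)
  expect_true(is.na(m3$`C20:5n-3`))
})

test_that("to_molar_percent error contracts", {
  panel <- default_panel()
  unk <- data.frame(sample_id = "a", group = "g", bogus = 1)
  expect_error(to_molar_percent(unk, panel), "not present in the panel")
  empty <- data.frame(sample_id = "a", group = "g",
                      `C18:0` = NA_real_, check.names = FALSE)
  expect_error(to_molar_percent(empty, panel), "no quantified analyte")
  neg <- data.frame(sample_id = "a", group = "g", `C18:0` = -1,
                    check.names = FALSE)
  expect_error(to_molar_percent(neg, panel), "non-negative")
})

test_that("molar profiles sum to 100, are scale-invariant and column-order invariant", {
  panel <- default_panel()
  set.seed(42)
  for (i in 1:20) {
    conc <- stats::runif(24, 1, 500)
    df <- data.frame(sample_id = "s", group = "g", check.names = FALSE)
    df[panel$name] <- as.list(conc)
    m <- to_molar_percent(df, panel)
    expect_equal(sum(unlist(m[panel$name])), 100, tolerance = 1e-9)
    # scale invariance
    df2 <- df
    df2[panel$name] <- as.list(conc * stats::runif(1, 0.01, 100))
    m2 <- to_molar_percent(df2, panel)
    expect_equal(unlist(m2[panel$name]), unlist(m[panel$name]),
                 tolerance = 1e-12)
    # column permutation invariance
    perm <- sample(panel$name)
    df3 <- df[c("sample_id", "group", perm)]
    m3 <- to_molar_percent(df3, panel)
    expect_equal(unlist(m3[panel$name]), unlist(m[panel$name]))
  }
})

test_that("cohort CSV round-trips, preserving the below-LOQ marker", {
  panel <- default_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tiny_cohort(), path)
  back <- read_cohort(path, panel)
  expect_equal(nrow(back), 3)
  expect_equal(back$sample_id, c("s1", "s2", "s3"))
  expect_true(is.na(back$`C18:1n-9`[3]))
  expect_equal(back$`C18:0`, tiny_cohort()$`C18:0`)
})

test_that("read_cohort schema and parse errors name the offender", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,C18:0", "s1,5"), path)
  expect_error(read_cohort(path), "'group'")
  writeLines(c("sample_id,group,C18:0", "s1,g,abc"), path)
  expect_error(read_cohort(path), "row 1.*C18:0")
  writeLines(c("sample_id,group,unheard-of", "s1,g,5"), path)
  expect_error(read_cohort(path), "unheard-of")
})

test_that("panel LOQ censors concentrations on read", {
  panel <- default_panel(loq = c(`C20:5n-3` = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,C20:5n-3,C18:0",
               "s1,g,15,100", "s2,g,25,100"), path)
  got <- read_cohort(path, panel)
  expect_true(is.na(got$`C20:5n-3`[1]))  # below LOQ 20
  expect_equal(got$`C20:5n-3`[2], 25)
})

test_that("panel TSV round-trips", {
  p <- default_panel(loq = c(`C18:0` = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p, path)
  back <- read_panel(path)
  expect_equal(back$name, p$name)
  expect_equal(back$molecular_weight, p$molecular_weight)
  expect_equal(back$loq, p$loq)
})
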