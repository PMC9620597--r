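test_that("adjudication drops uninformative values before testing discordance", {
  expect_equal(adjudicate_category(c("Female", "Other/Missing"), "sex_race"),
               "Female")
  expect_equal(adjudicate_category(c("Female", "Male"), "sex_race"),
               "Discordant")
  expect_equal(adjudicate_category(rep("White", 3), "sex_race"), "White")
  expect_equal(adjudicate_category(c("Other/Missing", NA), "sex_race"),
               "Other/Missing")
  expect_equal(adjudicate_category(c("White", "Asian", "Other/Missing"),
                                   "sex_race"), "Discordant")
  # age conflicts resolve to the oldest category (no Discordant age row)
  expect_equal(adjudicate_category(c("12-19", "20-34"), "age"), "20-34")
  expect_equal(adjudicate_category(c(">=75", "0-11", NA), "age"), ">=75")
  expect_equal(adjudicate_category(NA_character_, "age"), "Other/Missing")
  # permutation invariance
  vals <- c("White", "Black or African American", "Other/Missing")
  expect_equal(adjudicate_category(vals, "sex_race"),
               adjudicate_category(rev(vals), "sex_race"))
  expect_error(adjudicate_category("Purple", "sex_race"), "vocabulary")
})

test_that("percent reduction matches the published worked examples", {
  expect_equal(percent_reduction(3111792, 3108515, "round", 2), 0.11)
  expect_equal(percent_reduction(198, 163, "truncate", 1), 17.6)
  # the same pair rounds (not truncates) to 17.7
  expect_equal(percent_reduction(198, 163, "round", 1), 17.7)
  expect_equal(percent_reduction(50, 50, "round", 2), 0)
  expect_error(percent_reduction(0, 0), "undefined")
  expect_error(percent_reduction(5, 6), "before >= after")
})

test_that("demographic extracts accept CDM codes and reject unknown values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("DMID,PATID,AGE_GROUP,SEX,RACE",
               "A,P1,0-11,F,05",
               "A,P2,>=75,M,03",
               "A,P3,20-34,OT,01",
               "A,P4,35-49,Female,White",
               "A,P5,,NI,"), f)
  d <- read_demographic_extract(f)
  expect_equal(d$SEX, c("Female", "Male", "Other/Missing", "Female",
                        "Other/Missing"))
  expect_equal(d$RACE[1:3], c("White", "Black or African American",
                              "American Indian or Alaska Native"))
  expect_equal(d$RACE[5], "Other/Missing")
  expect_true(is.na(d$AGE_GROUP[5]))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("DMID,PATID,AGE_GROUP,SEX,RACE", "A,P1,0-11,F,banana"), f2)
  expect_error(read_demographic_extract(f2), "RACE value")
})

make_tf <- function(match_id, ref_id) {
  structure(data.frame(MATCH_ID = match_id, DMID_PATID = ref_id,
                       stringsAsFactors = FALSE),
            token_free = TRUE, class = c("match_index", "data.frame"))
}

test_that("an all-singleton index leaves aggregated and deduplicated identical", {
  demo <- data.frame(DMID = "A", PATID = paste0("P", 1:6),
                     AGE_GROUP = c("0-11", "12-19", "20-34", "35-49",
                                   "50-64", ">=75"),
                     SEX = c("Female", "Male", "Female", "Male", "Female",
                             "Male"),
                     RACE = c("White", "Asian", "White", "White",
                              "Other/Missing", "White"),
                     stringsAsFactors = FALSE)
  mi <- make_tf(sprintf("M%d", 1:6), paste0("A_P", 1:6))
  ct <- build_characteristics_table(demo, mi)
  expect_equal(ct$total$aggregated_n, ct$total$deduplicated_n)
  for (dim in c("age", "sex", "race")) {
    expect_equal(ct[[dim]]$aggregated_n, ct[[dim]]$deduplicated_n)
  }
  expect_equal(ct$reduction_pct, 0)
})

test_that("merged clusters are adjudicated and conservation holds", {
  demo <- data.frame(
    DMID = c("A", "A", "B", "B", "B"),
    PATID = c("P1", "P2", "P1", "P2", "P3"),
    AGE_GROUP = c("20-34", "35-49", "20-34", "0-11", "0-11"),
    SEX = c("Female", "Other/Missing", "Female", "Male", "Female"),
    RACE = c("White", "White", "Asian", "Other/Missing",
             "Black or African American"),
    stringsAsFactors = FALSE)
  # cluster M1 = {A_P1, A_P2, B_P1}; M2 = {B_P2}; M3 = {B_P3}
  mi <- make_tf(c("M1", "M1", "M1", "M2", "M3"),
                c("A_P1", "A_P2", "B_P1", "B_P2", "B_P3"))
  ct <- build_characteristics_table(demo, mi)
  expect_equal(ct$total$aggregated_n, 5)
  expect_equal(ct$total$deduplicated_n, 3)
  # M1: sex {Female, Other/Missing, Female} -> Female (missing-aware)
  expect_equal(ct$sex[ct$sex$category == "Female", "deduplicated_n"], 2)
  expect_equal(ct$sex[ct$sex$category == "Discordant", "deduplicated_n"], 0)
  # M1: race {White, White, Asian} -> Discordant
  expect_equal(ct$race[ct$race$category == "Discordant", "deduplicated_n"], 1)
  # M1: age {20-34, 35-49, 20-34} -> oldest = 35-49
  expect_equal(ct$age[ct$age$category == "35-49", "deduplicated_n"], 1)
  # conservation: every dimension sums to its column total in both columns
  for (dim in c("age", "sex", "race")) {
    expect_equal(sum(ct[[dim]]$aggregated_n), ct$total$aggregated_n)
    expect_equal(sum(ct[[dim]]$deduplicated_n), ct$total$deduplicated_n)
  }
  # deduplicated never exceeds aggregated except in the Discordant rows
  for (dim in c("age", "sex", "race")) {
    reg <- ct[[dim]]$category != "Discordant"
    expect_true(all(ct[[dim]]$deduplicated_n[reg] <=
                      ct[[dim]]$aggregated_n[reg]))
  }
})

test_that("reconciliation lists unmatched ids; strict mode drops them", {
  demo <- data.frame(DMID = "A", PATID = c("P1", "P2"),
                     AGE_GROUP = "20-34", SEX = "Female", RACE = "White",
                     stringsAsFactors = FALSE)
  mi <- make_tf(c("M1", "M2"), c("A_P1", "A_P9"))
  ct <- build_characteristics_table(demo, mi)
  expect_equal(ct$reconciliation$demo_not_in_index, "A_P2")
  expect_equal(ct$reconciliation$index_not_in_demo, "A_P9")
  expect_equal(ct$total$deduplicated_n, 2)  # orphan kept as singleton
  ct2 <- build_characteristics_table(demo, mi, strict = TRUE)
  expect_equal(ct2$total$deduplicated_n, 1)
})

test_that("characteristics tables refuse token-bearing indexes and write cleanly", {
  set.seed(21)
  inst <- random_token_instance(8)
  mi <- build_match_index(inst)
  demo <- data.frame(DMID = "S1", PATID = paste0("P", 1:3),
                     AGE_GROUP = "0-11", SEX = "F", RACE = "05",
                     stringsAsFactors = FALSE)
  expect_error(build_characteristics_table(demo, mi),
               class = "pprl_privacy_error")
  ct <- build_characteristics_table(
    data.frame(DMID = "A", PATID = "P1", AGE_GROUP = "0-11",
               SEX = "Female", RACE = "White", stringsAsFactors = FALSE),
    make_tf("M1", "A_P1"))
  out <- withr::local_tempfile()
  write_characteristics_table(ct, out)
  js <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(js$total$aggregated_n, 1)
})
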