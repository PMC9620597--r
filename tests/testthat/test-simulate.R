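test_that("generation is deterministic given the seed", {
  cfg <- clean_config(seed = 314)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$pii, p2$pii)
  expect_identical(p1$demo, p2$demo)
  expect_identical(p1$truth, p2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_population(p1, d1); write_population(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("truth partitions all records and respects the planted design", {
  cfg <- sim_config(sites = c("DM1", "DM2", "DM3"),
                    n_records = c(400, 300, 200),
                    overlap = c("DM1-DM2" = 0.05),
                    dup_rate = 0.01, ssn_avail = c(1, 1, 1),
                    typo_rate = 0, dob_error_rate = 0,
                    discordance_rate = 0, seed = 9)
  pop <- generate_population(cfg)
  # every generated record appears exactly once in the truth
  expect_equal(nrow(pop$truth), sum(cfg$n_records))
  for (s in cfg$sites) {
    expect_setequal(pop$truth$PATID[pop$truth$DMID == s],
                    pop$pii[[s]]$PATID)
  }
  # planted overlap: round(0.05 * 300) persons appear at both DM1 and DM2
  sites_of <- tapply(pop$truth$DMID, pop$truth$PERSON_ID,
                     function(d) sort(unique(d)))
  two_site <- sum(vapply(sites_of, function(s)
    identical(s, c("DM1", "DM2")), logical(1)))
  expect_equal(two_site, round(0.05 * 300))
  # within-site duplicates: dup_rate of each site's records
  for (s in cfg$sites) {
    t_s <- pop$truth[pop$truth$DMID == s, ]
    expect_equal(sum(duplicated(t_s$PERSON_ID)),
                 round(0.01 * cfg$n_records[[s]]))
  }
  # shared persons have identical base PII at both sites (no corruption)
  shared <- names(sites_of)[vapply(sites_of, length, integer(1)) == 2]
  for (pid in head(shared, 5)) {
    app <- pop$truth[pop$truth$PERSON_ID == pid, ]
    rec <- lapply(seq_len(nrow(app)), function(i) {
      r <- pop$pii[[app$DMID[i]]]
      r[r$PATID == app$PATID[i], -1]
    })
    expect_equal(rec[[1]], rec[[2]], ignore_attr = TRUE)
  }
})

test_that("corruption at rate zero is the identity and SSN masking propagates", {
  cfg <- clean_config(seed = 5, n_records = c(50, 40, 30, 20),
                      ssn_avail = c(1, 1, 1, 1))
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$corruption_log), 0)
  expect_false(anyNA(pop$pii$DM1$SSN))

  cfg0 <- clean_config(seed = 5, n_records = c(50, 40, 30, 20),
                       ssn_avail = c(0, 0, 0, 0))
  pop0 <- generate_population(cfg0)
  expect_true(all(is.na(pop0$pii$DM1$SSN)))
  kr <- keyring_create("DM1")
  tok <- tokenize_site_file(pop0$pii$DM1, "DM1", kr)
  expect_true(all(is.na(tok$TOKEN_05)) && all(is.na(tok$TOKEN_06)))
})

test_that("name typos are logged and classed by soundex effect", {
  cfg <- sim_config(sites = c("DM1", "DM2"), n_records = c(300, 300),
                    overlap = c("DM1-DM2" = 0.1), dup_rate = 0,
                    ssn_avail = c(1, 1), typo_rate = 0.5,
                    dob_error_rate = 0, discordance_rate = 0, seed = 77)
  pop <- generate_population(cfg)
  log <- pop$corruption_log
  expect_gt(nrow(log), 0)
  expect_true(all(log$type %in% c("typo_soundex_preserving",
                                  "typo_soundex_breaking", "missing",
                                  "dob_error", "discordant")))
  expect_true(any(log$type == "typo_soundex_breaking"))
})

test_that("infeasible overlap configurations are rejected", {
  expect_error(
    sim_config(sites = c("A", "B"), n_records = c(10, 1000),
               overlap = c("A-B" = 1), dup_rate = 0.5,
               ssn_avail = c(1, 1), seed = 1),
    "infeasible overlap")
  expect_error(sim_config(sites = c("A", "B"), n_records = c(10, 10),
                          overlap = c("A-C" = 0.1), seed = 1),
               "distinct known sites")
  expect_error(sim_config(seed = 1, typo_rate = 1.5), "fractions")
  expect_error(sim_config(), "seed is mandatory")
})

test_that("clean pipelines recover truth exactly; precision convention at zero links", {
  cfg <- clean_config(seed = 2024)
  res <- run_pipeline(cfg)
  expect_equal(res$evaluation$precision, 1.0)
  expect_equal(res$evaluation$recall, 1.0)
  # multiplicity equals the truth-derived distribution exactly
  truth_mult <- table(tapply(res$population$truth$DMID,
                             res$population$truth$PERSON_ID,
                             function(d) length(unique(d))))
  expect_equal(res$overlap$multiplicity$n[1:2],
               as.integer(truth_mult[c("1", "2")]))

  # zero-overlap truth with no predicted links: precision reported as 1.0
  cfg0 <- clean_config(seed = 31, sites = c("A", "B"),
                       n_records = c(40, 30), overlap = numeric(0),
                       dup_rate = 0)
  res0 <- run_pipeline(cfg0)
  expect_equal(res0$evaluation$n_pairs_predicted, 0)
  expect_equal(res0$evaluation$precision, 1.0)
  expect_equal(res0$evaluation$recall, 1.0)
})

test_that("more comparable token slots never hurt recall under name typos", {
  base <- list(sites = c("DM1", "DM2"), n_records = c(400, 400),
               overlap = c("DM1-DM2" = 0.15), dup_rate = 0,
               typo_rate = 0.05, dob_error_rate = 0,
               discordance_rate = 0, seed = 512)
  with_ssn <- do.call(sim_config, c(base, list(ssn_avail = c(1, 1))))
  without_ssn <- do.call(sim_config, c(base, list(ssn_avail = c(0, 0))))
  r1 <- run_pipeline(with_ssn)$evaluation$recall
  r0 <- run_pipeline(without_ssn)$evaluation$recall
  expect_gte(r1, r0)
})

test_that("evaluation rejects mismatched record universes", {
  cfg <- clean_config(seed = 8, sites = c("A", "B"), n_records = c(30, 30))
  res <- run_pipeline(cfg)
  truncated <- res$population$truth[-1, ]
  expect_error(evaluate_linkage(res$match_index_tf, truncated),
               "universes")
})
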