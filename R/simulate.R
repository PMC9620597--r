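#' Configuration for a synthetic multi-site population
#'
#' Defines the study conditions the generator emulates: a small distributed
#' network of sites holding overlapping patient populations. Defaults
#' mirror a four-site pilot: three of the six site pairs share patients,
#' the largest pairwise overlap is 0.2% of a site's patient count, roughly
#' one patient in a thousand appears at two sites, within-site duplicate
#' records are rare (0.02% of records), and SSN availability varies widely
#' across sites (0% to 99%, median 66%) while name, gender and date of
#' birth are essentially complete. Site sizes default to a desk-scale
#' population of a few thousand records each.
#'
#' @param sites character vector of DMIDs (no underscores).
#' @param n_records records per site (same length as \code{sites}).
#' @param overlap named numeric vector of pairwise overlap fractions, names
#'   \code{"<site1>-<site2>"}; the planted shared-patient count for a pair
#'   is \code{round(frac * min(site record counts))}. Unnamed pairs share
#'   no patients.
#' @param dup_rate fraction of each site's records that are within-site
#'   duplicate records of another record at that site.
#' @param ssn_avail per-site probability that a record carries an SSN.
#' @param typo_rate per-appearance probability of a single-character name
#'   typo (substitution or adjacent transposition).
#' @param dob_error_rate per-appearance probability of a date-of-birth
#'   error (day/month swap when valid, otherwise a day perturbation).
#' @param discordance_rate per-appearance probability that a site codes the
#'   patient's race differently from the person-level value (exercises the
#'   Discordant adjudication pathway).
#' @param sex_priors,race_priors,age_priors named category priors for the
#'   person-level demographics.
#' @param seed mandatory integer seed; the run is fully reproducible.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(sites = c("DM1", "DM2", "DM3", "DM4"),
                       n_records = c(3000, 2400, 1800, 1200),
                       overlap = c("DM1-DM2" = 0.002, "DM1-DM3" = 0.001,
                                   "DM2-DM4" = 0.0005),
                       dup_rate = 0.0002,
                       ssn_avail = c(0, 0.62, 0.70, 0.99),
                       typo_rate = 0.01,
                       dob_error_rate = 0.005,
                       discordance_rate = 0.002,
                       sex_priors = c(F = 0.5375, M = 0.4615, OT = 0.0004,
                                      UN = 0.0006),
                       race_priors = c("American Indian or Alaska Native" = 0.002,
                                       "Asian" = 0.032,
                                       "Black or African American" = 0.190,
                                       "Native Hawaiian or Other Pacific Islander" = 0.001,
                                       "White" = 0.621,
                                       "Other/Missing" = 0.154),
                       age_priors = c("0-11" = 0.302, "12-19" = 0.178,
                                      "20-34" = 0.140, "35-49" = 0.118,
                                      "50-64" = 0.127, "65-74" = 0.080,
                                      ">=75" = 0.055),
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  stopifnot(length(sites) >= 1, length(n_records) == length(sites),
            all(n_records >= 1), !anyDuplicated(sites))
  if (any(grepl("_", sites, fixed = TRUE))) {
    stop("site ids may not contain '_'", call. = FALSE)
  }
  # defaults adapt to a caller-supplied site list
  if (missing(overlap) && length(overlap)) {
    parts <- strsplit(names(overlap), "-", fixed = TRUE)
    known <- vapply(parts, function(p) all(p %in% sites), logical(1))
    overlap <- overlap[known]
  }
  if (missing(ssn_avail) || length(ssn_avail) == 1) {
    ssn_avail <- rep_len(ssn_avail, length(sites))
  }
  stopifnot(length(ssn_avail) == length(sites))
  rates <- c(overlap, dup_rate, ssn_avail, typo_rate, dob_error_rate,
             discordance_rate)
  if (any(rates < 0 | rates > 1)) stop("fractions must be in [0, 1]",
                                       call. = FALSE)
  names(n_records) <- sites
  names(ssn_avail) <- sites
  cfg <- list(sites = sites, n_records = n_records, overlap = overlap,
              dup_rate = dup_rate, ssn_avail = ssn_avail,
              typo_rate = typo_rate, dob_error_rate = dob_error_rate,
              discordance_rate = discordance_rate,
              sex_priors = sex_priors,
              race_priors = race_priors, age_priors = age_priors,
              seed = as.integer(seed))
  # feasibility: every site must hold its shared patients plus >=0 singletons
  counts <- overlap_counts(cfg)
  n_dup <- round(cfg$dup_rate * n_records)
  persons_per_site <- n_records - n_dup
  for (s in sites) {
    shared_s <- sum(counts$count[counts$site1 == s | counts$site2 == s])
    if (shared_s > persons_per_site[s]) {
      stop("infeasible overlap: site '", s, "' must host ", shared_s,
           " shared patients but has only ", persons_per_site[s],
           " patient slots", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

overlap_counts <- function(cfg) {
  if (length(cfg$overlap) == 0) {
    return(data.frame(site1 = character(0), site2 = character(0),
                      count = integer(0)))
  }
  parts <- strsplit(names(cfg$overlap), "-", fixed = TRUE)
  s1 <- vapply(parts, `[`, character(1), 1)
  s2 <- vapply(parts, `[`, character(1), 2)
  if (!all(c(s1, s2) %in% cfg$sites) || any(s1 == s2)) {
    stop("overlap names must be '<site1>-<site2>' over distinct known sites",
         call. = FALSE)
  }
  cnt <- as.integer(round(cfg$overlap *
                            pmin(cfg$n_records[s1], cfg$n_records[s2])))
  data.frame(site1 = s1, site2 = s2, count = cnt, stringsAsFactors = FALSE)
}

substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

load_name_tables <- function() {
  fn <- read.csv(system.file("extdata", "first_names.csv",
                             package = "pprlink"), stringsAsFactors = FALSE)
  sn <- read.csv(system.file("extdata", "surnames.csv", package = "pprlink"),
                 stringsAsFactors = FALSE)
  list(first = fn, last = sn)
}

AGE_RANGES <- list("0-11" = c(0, 11), "12-19" = c(12, 19),
                   "20-34" = c(20, 34), "35-49" = c(35, 49),
                   "50-64" = c(50, 64), "65-74" = c(65, 74),
                   ">=75" = c(75, 90))
SIM_REF_DATE <- as.Date("2019-06-30")

sample_persons <- function(n, cfg, names_tab, id_offset, ssn_pool) {
  sex <- sample(names(cfg$sex_priors), n, replace = TRUE,
                prob = cfg$sex_priors)
  first <- character(n)
  for (s in c("F", "M")) {
    idx <- which(sex == s)
    pool <- names_tab$first[names_tab$first$SEX == s, ]
    if (length(idx)) {
      first[idx] <- sample(pool$NAME, length(idx), replace = TRUE,
                           prob = pool$WEIGHT)
    }
  }
  other <- which(!(sex %in% c("F", "M")))
  if (length(other)) {
    first[other] <- sample(names_tab$first$NAME, length(other), replace = TRUE,
                           prob = names_tab$first$WEIGHT)
  }
  last <- sample(names_tab$last$NAME, n, replace = TRUE,
                 prob = names_tab$last$WEIGHT)
  age_group <- sample(names(cfg$age_priors), n, replace = TRUE,
                      prob = cfg$age_priors)
  age_days <- vapply(age_group, function(g) {
    r <- AGE_RANGES[[g]]
    round(runif(1, r[1] * 365.25, (r[2] + 1) * 365.25 - 1))
  }, numeric(1))
  dob <- format(SIM_REF_DATE - age_days, "%Y-%m-%d")
  zip <- sprintf("%05d", sample(c(10001:10080, 27501:27560, 60601:60640,
                                  94102:94130), n, replace = TRUE))
  race <- sample(names(cfg$race_priors), n, replace = TRUE,
                 prob = cfg$race_priors)
  data.frame(
    PERSON_ID = sprintf("PER%06d", id_offset + seq_len(n)),
    FIRST_NAME = first, LAST_NAME = last, GENDER = sex,
    DOB = dob, ZIP5 = zip,
    SSN = ssn_pool[id_offset + seq_len(n)],
    AGE_GROUP = unname(age_group),
    SEX = unname(SEX_CDM_MAP[sex]),
    RACE = race,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic multi-site population with ground truth
#'
#' Draws a pool of synthetic persons (names from a bundled frequency list,
#' unique SSNs, demographics from the configured priors), plants the
#' configured pairwise overlaps and within-site duplicates, then corrupts
#' each site appearance independently (name typos, date errors, per-site
#' SSN missingness, demographic discordance). A person shared between two
#' sites has identical base PII at both before corruption. The run is
#' deterministic given the seed; each site and site pair draws from its
#' own substream.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{pii} (named list of PII extracts per site),
#'   \code{demo} (named list of demographic extracts), \code{truth} (a
#'   \code{link_truth} data.frame: PERSON_ID, DMID, PATID), and
#'   \code{corruption_log}.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  names_tab <- load_name_tables()
  counts <- overlap_counts(cfg)
  n_dup <- round(cfg$dup_rate * cfg$n_records)
  persons_per_site <- cfg$n_records - n_dup
  n_shared_at <- setNames(numeric(length(cfg$sites)), cfg$sites)
  for (i in seq_len(nrow(counts))) {
    n_shared_at[counts$site1[i]] <- n_shared_at[counts$site1[i]] + counts$count[i]
    n_shared_at[counts$site2[i]] <- n_shared_at[counts$site2[i]] + counts$count[i]
  }
  n_singleton <- persons_per_site - n_shared_at
  total_persons <- sum(counts$count) + sum(n_singleton)

  set.seed(substream(cfg$seed, "ssn-pool"))
  ssn_pool <- sprintf("%09d", 99999999 + sample(8e8, total_persons))

  # person blocks: one per overlapping pair, one per site's singletons
  blocks <- list()
  offset <- 0L
  for (i in seq_len(nrow(counts))) {
    if (counts$count[i] == 0) next
    lab <- paste0("pair:", counts$site1[i], "-", counts$site2[i])
    set.seed(substream(cfg$seed, lab))
    p <- sample_persons(counts$count[i], cfg, names_tab, offset, ssn_pool)
    blocks[[lab]] <- list(persons = p,
                          sites = c(counts$site1[i], counts$site2[i]))
    offset <- offset + counts$count[i]
  }
  for (s in cfg$sites) {
    if (n_singleton[s] == 0) next
    lab <- paste0("site:", s)
    set.seed(substream(cfg$seed, lab))
    p <- sample_persons(n_singleton[s], cfg, names_tab, offset, ssn_pool)
    blocks[[lab]] <- list(persons = p, sites = s)
    offset <- offset + n_singleton[s]
  }

  blocks <- enforce_distinct_persons(blocks, cfg)

  site_members <- setNames(vector("list", length(cfg$sites)), cfg$sites)
  for (b in blocks) {
    for (s in b$sites) site_members[[s]] <- rbind(site_members[[s]], b$persons)
  }

  pii <- list(); demo <- list(); truth <- list(); logs <- list()
  for (si in seq_along(cfg$sites)) {
    s <- cfg$sites[si]
    set.seed(substream(cfg$seed, paste0("appear:", s)))
    members <- site_members[[s]]
    if (is.null(members)) {
      members <- sample_persons(0, cfg, names_tab, 0L, ssn_pool)
    }
    # within-site duplicates: extra appearances of randomly chosen persons
    if (n_dup[s] > 0) {
      dup_idx <- sample(nrow(members), n_dup[s])
      members <- rbind(members, members[dup_idx, ])
    }
    members <- members[sample(nrow(members)), , drop = FALSE]
    members$PATID <- sprintf("P%05d", seq_len(nrow(members)))
    corrupted <- corrupt_pii(members, cfg, s)
    rec <- corrupted$records
    pii[[s]] <- data.frame(PATID = rec$PATID, FIRST_NAME = rec$FIRST_NAME,
                           LAST_NAME = rec$LAST_NAME, GENDER = rec$GENDER,
                           DOB = rec$DOB, ZIP5 = rec$ZIP5, SSN = rec$SSN,
                           stringsAsFactors = FALSE)
    demo[[s]] <- data.frame(DMID = s, PATID = rec$PATID,
                            AGE_GROUP = rec$AGE_GROUP, SEX = rec$SEX,
                            RACE = rec$RACE, stringsAsFactors = FALSE)
    truth[[s]] <- data.frame(PERSON_ID = rec$PERSON_ID, DMID = s,
                             PATID = rec$PATID, stringsAsFactors = FALSE)
    logs[[s]] <- corrupted$log
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  class(truth) <- c("link_truth", "data.frame")
  list(pii = pii, demo = demo, truth = truth,
       corruption_log = do.call(rbind, c(logs, list(make.row.names = FALSE))),
       config = cfg)
}

# Distinct synthetic persons must be distinguishable by their identity
# fields: two persons identical in name, gender and date of birth are
# indistinguishable to any identifier-based linkage, so planting them would
# make the ground truth unattainable by construction. Coinciding draws have
# their date of birth redrawn within the same age group.
enforce_distinct_persons <- function(blocks, cfg) {
  if (length(blocks) == 0) return(blocks)
  all_p <- do.call(rbind, c(lapply(blocks, `[[`, "persons"),
                            list(make.row.names = FALSE)))
  key <- function(p) paste(p$FIRST_NAME, p$LAST_NAME, p$GENDER, p$DOB,
                           sep = "|")
  set.seed(substream(cfg$seed, "distinct-persons"))
  for (pass in 1:20) {
    dup <- which(duplicated(key(all_p)))
    if (length(dup) == 0) break
    for (i in dup) {
      r <- AGE_RANGES[[all_p$AGE_GROUP[i]]]
      days <- round(runif(1, r[1] * 365.25, (r[2] + 1) * 365.25 - 1))
      all_p$DOB[i] <- format(SIM_REF_DATE - days, "%Y-%m-%d")
    }
  }
  at <- 0L
  for (b in names(blocks)) {
    n <- nrow(blocks[[b]]$persons)
    blocks[[b]]$persons <- all_p[at + seq_len(n), , drop = FALSE]
    rownames(blocks[[b]]$persons) <- NULL
    at <- at + n
  }
  blocks
}

name_typo <- function(name) {
  if (is.na(name) || nchar(name) < 2) return(name)
  chars <- strsplit(name, "")[[1]]
  if (runif(1) < 0.5) {
    i <- sample(length(chars), 1)
    chars[i] <- sample(setdiff(LETTERS, chars[i]), 1)
  } else {
    i <- sample(length(chars) - 1, 1)
    chars[c(i, i + 1)] <- chars[c(i + 1, i)]
  }
  paste(chars, collapse = "")
}

dob_error <- function(dob) {
  d <- as.Date(dob)
  day <- as.integer(format(d, "%d")); mon <- as.integer(format(d, "%m"))
  swapped <- sprintf("%s-%02d-%02d", format(d, "%Y"), day, mon)
  if (day <= 12 && day != mon && !is.na(as.Date(swapped, "%Y-%m-%d"))) {
    return(swapped)
  }
  new_day <- max(1, min(28, day + sample(c(-1, 1), 1)))
  sprintf("%s-%02d-%02d", format(d, "%Y"), mon, new_day)
}

#' Corrupt one site's PII appearances
#'
#' Applies, independently per record: a single-character name typo at the
#' configured rate (logged as soundex-preserving or soundex-breaking), a
#' date-of-birth error, per-site SSN missingness, and race discordance in
#' the demographic fields. A rate of zero leaves the records byte-identical.
#'
#' @param records data.frame of uncorrupted site appearances (internal
#'   layout of [generate_population()]).
#' @param cfg a [sim_config()].
#' @param site site id (selects the SSN availability).
#' @return list of \code{records} (corrupted) and \code{log} (one row per
#'   corruption event).
#' @export
corrupt_pii <- function(records, cfg, site) {
  log <- list()
  n <- nrow(records)
  if (n == 0) {
    return(list(records = records,
                log = data.frame(DMID = character(0), PATID = character(0),
                                 field = character(0), type = character(0))))
  }
  note <- function(patid, field, type) {
    log[[length(log) + 1]] <<- data.frame(DMID = site, PATID = patid,
                                          field = field, type = type,
                                          stringsAsFactors = FALSE)
  }
  # SSN availability
  keep_ssn <- runif(n) < cfg$ssn_avail[site]
  dropped <- which(!keep_ssn & !is.na(records$SSN))
  records$SSN[!keep_ssn] <- NA_character_
  for (i in dropped) note(records$PATID[i], "SSN", "missing")
  # name typos
  hit <- which(runif(n) < cfg$typo_rate)
  for (i in hit) {
    field <- sample(c("FIRST_NAME", "LAST_NAME"), 1)
    old <- records[[field]][i]
    new <- name_typo(old)
    records[[field]][i] <- new
    kind <- if (identical(soundex(new), soundex(old)))
      "typo_soundex_preserving" else "typo_soundex_breaking"
    note(records$PATID[i], field, kind)
  }
  # dob errors
  hit <- which(runif(n) < cfg$dob_error_rate & !is.na(records$DOB))
  for (i in hit) {
    records$DOB[i] <- dob_error(records$DOB[i])
    note(records$PATID[i], "DOB", "dob_error")
  }
  # demographic discordance (race recoded at this site)
  hit <- which(runif(n) < cfg$discordance_rate)
  for (i in hit) {
    informative <- setdiff(RACE_LEVELS, c("Other/Missing", records$RACE[i]))
    records$RACE[i] <- sample(informative, 1)
    note(records$PATID[i], "RACE", "discordant")
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(DMID = character(0), PATID = character(0),
               field = character(0), type = character(0))
  list(records = records, log = log)
}

#' Write the generated population to extract files
#'
#' @param pop result of [generate_population()].
#' @param dir output directory; writes \code{pii_<DMID>.csv},
#'   \code{demo_<DMID>.csv} and \code{link_truth.csv}.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(pop$pii)) {
    write_pii_extract(pop$pii[[s]], file.path(dir, paste0("pii_", s, ".csv")))
    d <- pop$demo[[s]]
    d[is.na(d)] <- ""
    write.csv(d, file.path(dir, paste0("demo_", s, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(pop$truth, file.path(dir, "link_truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Evaluate an inferred Match Index against ground truth
#'
#' Pairwise precision and recall of the inferred patient partition against
#' the true person partition, plus the absolute error of every reported
#' pairwise site-overlap percentage against the overlap implied by the
#' truth. With zero predicted (or true) links, precision (recall) is
#' reported as 1.0 by convention.
#'
#' @param mi \code{match_index} (token-bearing or token-free; only
#'   MATCH_ID and DMID_PATID are used).
#' @param truth \code{link_truth} data.frame from [generate_population()]
#'   or \code{link_truth.csv}.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{n_pairs_predicted}, \code{n_pairs_true} and \code{overlap_error}
#'   (per site pair: reported vs true percentage and absolute error).
#' @export
evaluate_linkage <- function(mi, truth) {
  truth_ref <- paste0(truth$DMID, "_", truth$PATID)
  mi_ref <- mi$DMID_PATID
  if (!setequal(truth_ref, mi_ref) || length(truth_ref) != length(mi_ref)) {
    stop("record universes of Match Index and truth differ", call. = FALSE)
  }
  person <- truth$PERSON_ID[match(mi_ref, truth_ref)]
  cluster <- mi$MATCH_ID
  pairs2 <- function(x) sum(choose(table(x), 2))
  n_pred <- pairs2(cluster)
  n_true <- pairs2(person)
  tp <- pairs2(paste(cluster, person, sep = "\r"))
  precision <- if (n_pred == 0) 1 else tp / n_pred
  recall <- if (n_true == 0) 1 else tp / n_true
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)

  mi_tf <- strip_tokens(mi)
  rep_pairs <- pairwise_overlap(mi_tf)$pairs
  true_mi <- structure(
    data.frame(MATCH_ID = person, DMID_PATID = mi_ref,
               stringsAsFactors = FALSE),
    token_free = TRUE, class = c("match_index", "data.frame"))
  true_pairs <- pairwise_overlap(true_mi)$pairs
  err <- NULL
  if (!is.null(rep_pairs) && !is.null(true_pairs)) {
    key <- paste(rep_pairs$site1, rep_pairs$site2)
    tkey <- paste(true_pairs$site1, true_pairs$site2)
    m <- match(key, tkey)
    err <- data.frame(
      site1 = rep_pairs$site1, site2 = rep_pairs$site2,
      reported_pct = rep_pairs$pct_of_site1,
      true_pct = true_pairs$pct_of_site1[m],
      abs_error = abs(rep_pairs$pct_of_site1 - true_pairs$pct_of_site1[m]),
      stringsAsFactors = FALSE)
  }
  list(precision = precision, recall = recall, f1 = f1,
       n_pairs_predicted = n_pred, n_pairs_true = n_true,
       overlap_error = err)
}
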