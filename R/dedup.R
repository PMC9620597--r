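AGE_GROUPS <- c("0-11", "12-19", "20-34", "35-49", "50-64", "65-74", ">=75")
SEX_LEVELS <- c("Female", "Male", "Other/Missing")
RACE_LEVELS <- c("American Indian or Alaska Native", "Asian",
                 "Black or African American",
                 "Native Hawaiian or Other Pacific Islander", "White",
                 "Other/Missing")
DISCORDANT <- "Discordant"

# CDM-coded values accepted in demographic extracts, mapped to table labels
RACE_CDM_MAP <- c(
  "01" = "American Indian or Alaska Native",
  "02" = "Asian",
  "03" = "Black or African American",
  "04" = "Native Hawaiian or Other Pacific Islander",
  "05" = "White",
  "OT" = "Other/Missing", "NI" = "Other/Missing", "UN" = "Other/Missing",
  "06" = "Other/Missing", "07" = "Other/Missing"
)
SEX_CDM_MAP <- c("F" = "Female", "M" = "Male",
                 "OT" = "Other/Missing", "NI" = "Other/Missing",
                 "UN" = "Other/Missing", "A" = "Other/Missing")

#' Read a demographic extract
#'
#' Headered comma-separated text with columns DMID, PATID, AGE_GROUP, SEX,
#' RACE. SEX and RACE accept either the table labels or common data model codes
#' (F/M/OT/NI/UN; race 01-07/OT/NI/UN), which are mapped onto the closed
#' vocabularies used in the characteristics table. Missing values become
#' "Other/Missing" for sex and race and \code{NA} for age group. A value
#' outside both vocabularies is a validation error.
#'
#' @param path file path.
#' @return data.frame with DMID, PATID, DMID_PATID, AGE_GROUP, SEX, RACE.
#' @export
read_demographic_extract <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("DMID", "PATID", "AGE_GROUP", "SEX", "RACE")
  if (!all(need %in% names(df))) {
    stop("not a demographic extract: '", path, "'", call. = FALSE)
  }
  df <- df[need]
  df[df == ""] <- NA_character_
  if (anyDuplicated(paste0(df$DMID, "_", df$PATID))) {
    stop("duplicate DMID/PATID in demographic extract '", path, "'",
         call. = FALSE)
  }
  df$SEX <- map_vocab(df$SEX, SEX_CDM_MAP, SEX_LEVELS, "Other/Missing", "SEX")
  df$RACE <- map_vocab(df$RACE, RACE_CDM_MAP, RACE_LEVELS, "Other/Missing",
                       "RACE")
  bad_age <- !is.na(df$AGE_GROUP) & !(df$AGE_GROUP %in% AGE_GROUPS)
  if (any(bad_age)) {
    stop("AGE_GROUP value(s) outside vocabulary: ",
         paste(unique(df$AGE_GROUP[bad_age]), collapse = ", "), call. = FALSE)
  }
  df$DMID_PATID <- paste0(df$DMID, "_", df$PATID)
  df
}

map_vocab <- function(x, cdm_map, levels, missing_label, what) {
  out <- ifelse(is.na(x), missing_label,
                ifelse(x %in% levels, x, unname(cdm_map[x])))
  bad <- is.na(out)
  if (any(bad)) {
    stop(what, " value(s) outside vocabulary: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Adjudicate one demographic dimension across a matched cluster
#'
#' Consolidates the values reported by a matched patient's records into a
#' single value while retaining genuinely distinct information. The policy
#' is missing-aware: uninformative values ("Other/Missing", \code{NA}) are
#' dropped first, so a cluster reporting \{Female, Other/Missing\} resolves
#' to Female rather than Discordant. If nothing informative remains the
#' result is "Other/Missing"; a single informative value wins outright;
#' two or more distinct informative values yield "Discordant" for sex and
#' race, or — since age has no discordant category — the oldest reported
#' age group under the age policy.
#'
#' @param values character vector of category values from one cluster.
#' @param policy \code{"sex_race"} (conflicts become Discordant) or
#'   \code{"age"} (conflicts resolve to the oldest group).
#' @return single adjudicated value. Order-invariant in \code{values}.
#' @export
adjudicate_category <- function(values, policy = c("sex_race", "age")) {
  policy <- match.arg(policy)
  stopifnot(length(values) >= 1)
  vocab <- if (policy == "age") AGE_GROUPS else
    unique(c(SEX_LEVELS, RACE_LEVELS))
  bad <- !is.na(values) & !(values %in% vocab)
  if (any(bad)) {
    stop("value(s) outside vocabulary: ",
         paste(unique(values[bad]), collapse = ", "), call. = FALSE)
  }
  informative <- values[!is.na(values) & values != "Other/Missing"]
  distinct <- unique(informative)
  if (length(distinct) == 0) return("Other/Missing")
  if (length(distinct) == 1) return(distinct)
  if (policy == "age") {
    distinct[which.max(match(distinct, AGE_GROUPS))]
  } else {
    DISCORDANT
  }
}

#' Percentage reduction between two counts
#'
#' \code{100 * (before - after) / before}, formatted either by rounding or
#' by truncation toward zero at the requested number of decimals.
#'
#' @param before,after non-negative counts, \code{before >= after},
#'   \code{before > 0}.
#' @param mode \code{"round"} or \code{"truncate"}.
#' @param decimals decimal places retained.
#' @return numeric percentage.
#' @examples
#' percent_reduction(3111792, 3108515, "round", 2)     # 0.11
#' percent_reduction(198, 163, "truncate", 1)          # 17.6
#' @export
percent_reduction <- function(before, after, mode = c("round", "truncate"),
                              decimals = 1) {
  mode <- match.arg(mode)
  if (before <= 0) stop("percent_reduction undefined for before <= 0",
                        call. = FALSE)
  if (after > before || after < 0) {
    stop("require before >= after >= 0", call. = FALSE)
  }
  pct <- 100 * (before - after) / before
  f <- 10^decimals
  if (mode == "round") round(pct * f) / f else floor(pct * f) / f
}

#' Aggregated vs de-duplicated patient characteristics table
#'
#' Joins per-site demographic extracts to the token-free Match Index and
#' tabulates age group, sex and race twice: over the full record set (the
#' aggregated column, with potential duplicates) and over one adjudicated
#' record per master patient id (the de-duplicated column). Sex and race
#' gain a "Discordant" row in the de-duplicated column for clusters whose
#' records genuinely disagree. Records present in the demographics but
#' absent from the index (or vice versa) are listed in a reconciliation
#' report; unmatched demographic records are treated as their own
#' singleton patients unless \code{strict} drops them.
#'
#' @param demo demographic data.frame ([read_demographic_extract()]) or a
#'   list of them (one per site).
#' @param mi token-free \code{match_index}.
#' @param strict drop demographic records missing from the index from the
#'   de-duplicated column (default FALSE: keep as singletons).
#' @return object of class \code{characteristics_table}: per dimension a
#'   data.frame of category, aggregated N and %, de-duplicated N and %,
#'   plus totals and the reconciliation report.
#' @export
build_characteristics_table <- function(demo, mi, strict = FALSE) {
  assert_token_free(mi, "build_characteristics_table")
  if (is.list(demo) && !is.data.frame(demo)) {
    demo <- do.call(rbind, c(demo, list(make.row.names = FALSE)))
  }
  if (is.null(demo$DMID_PATID)) {
    demo$DMID_PATID <- paste0(demo$DMID, "_", demo$PATID)
  }
  if (anyDuplicated(demo$DMID_PATID)) {
    stop("duplicate DMID_PATID across demographic extracts", call. = FALSE)
  }
  in_index <- demo$DMID_PATID %in% mi$DMID_PATID
  recon <- list(
    demo_not_in_index = demo$DMID_PATID[!in_index],
    index_not_in_demo = setdiff(mi$DMID_PATID, demo$DMID_PATID)
  )
  demo$MATCH_ID <- mi$MATCH_ID[match(demo$DMID_PATID, mi$DMID_PATID)]
  orphan <- is.na(demo$MATCH_ID)
  if (strict) {
    dedup_src <- demo[!orphan, ]
  } else {
    demo$MATCH_ID[orphan] <- paste0("S_", demo$DMID_PATID[orphan])
    dedup_src <- demo
  }
  cl <- split(seq_len(nrow(dedup_src)), dedup_src$MATCH_ID)
  dedup <- data.frame(
    MATCH_ID = names(cl),
    AGE_GROUP = vapply(cl, function(i)
      adjudicate_category(dedup_src$AGE_GROUP[i], "age"), character(1)),
    SEX = vapply(cl, function(i)
      adjudicate_category(dedup_src$SEX[i], "sex_race"), character(1)),
    RACE = vapply(cl, function(i)
      adjudicate_category(dedup_src$RACE[i], "sex_race"), character(1)),
    stringsAsFactors = FALSE
  )
  tab_dim <- function(agg_values, dd_values, levels, discordant) {
    lev <- c(levels, if (discordant) DISCORDANT)
    agg_values[is.na(agg_values)] <- "Other/Missing"
    dd_values[is.na(dd_values)] <- "Other/Missing"
    a <- table(factor(agg_values, levels = lev))
    d <- table(factor(dd_values, levels = lev))
    data.frame(category = lev,
               aggregated_n = as.integer(a),
               aggregated_pct = round(100 * as.integer(a) / length(agg_values), 1),
               deduplicated_n = as.integer(d),
               deduplicated_pct = round(100 * as.integer(d) / length(dd_values), 1),
               stringsAsFactors = FALSE)
  }
  structure(list(
    total = data.frame(aggregated_n = nrow(demo),
                       deduplicated_n = nrow(dedup)),
    age = tab_dim(demo$AGE_GROUP, dedup$AGE_GROUP, AGE_GROUPS,
                  discordant = FALSE),
    sex = tab_dim(demo$SEX, dedup$SEX, SEX_LEVELS, discordant = TRUE),
    race = tab_dim(demo$RACE, dedup$RACE, RACE_LEVELS, discordant = TRUE),
    reduction_pct = percent_reduction(nrow(demo), nrow(dedup), "round", 2),
    reconciliation = recon
  ), class = "characteristics_table")
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat(sprintf("Patients: aggregated %s, de-duplicated %s (%.2f%% reduction)\n",
              format(x$total$aggregated_n, big.mark = ","),
              format(x$total$deduplicated_n, big.mark = ","),
              x$reduction_pct))
  for (dim in c("age", "sex", "race")) {
    cat("\nBy", switch(dim, age = "Age", sex = "Sex", race = "Race"),
        "(N, %):\n")
    print(x[[dim]], row.names = FALSE)
  }
  nr <- length(x$reconciliation$demo_not_in_index) +
    length(x$reconciliation$index_not_in_demo)
  if (nr > 0) cat("\nReconciliation:", nr, "unmatched reference id(s)\n")
  invisible(x)
}

#' Write a characteristics table
#'
#' Tab-separated text plus a JSON variant with raw counts.
#'
#' @param ct a \code{characteristics_table}.
#' @param path output path stem; \code{<path>.tsv} and \code{<path>.json}
#'   are written.
#' @export
write_characteristics_table <- function(ct, path) {
  con <- file(paste0(path, ".tsv"), "w")
  on.exit(close(con))
  writeLines(sprintf("# total\taggregated=%d\tdeduplicated=%d\treduction_pct=%.2f",
                     ct$total$aggregated_n, ct$total$deduplicated_n,
                     ct$reduction_pct), con)
  for (dim in c("age", "sex", "race")) {
    writeLines(paste0("# by ", dim), con)
    write.table(ct[[dim]], con, sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines("", con)
  }
  jsonlite::write_json(unclass(ct), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
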