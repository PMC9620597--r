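#' Distribution of patients over the number of sites they appear in
#'
#' For each unique master patient id, counts the distinct sites (DMIDs)
#' holding at least one of its records, and tabulates patients appearing in
#' exactly 1, 2, 3, or 4-or-more sites. A patient whose only extra records
#' are within-site duplicates still counts as a one-site patient.
#'
#' @param mi token-free \code{match_index}.
#' @return data.frame with columns \code{sites} (\code{"1","2","3",">=4"}),
#'   \code{n}, \code{pct} (of unique patients, 1 decimal).
#' @export
site_multiplicity <- function(mi) {
  assert_token_free(mi, "site_multiplicity")
  parts <- split_ref_id(mi$DMID_PATID)
  k <- tapply(parts$DMID, mi$MATCH_ID, function(d) length(unique(d)))
  bin <- cut(k, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
             labels = c("1", "2", "3", ">=4"))
  n <- as.integer(table(bin))
  data.frame(sites = c("1", "2", "3", ">=4"), n = n,
             pct = round(100 * n / sum(n), 1),
             stringsAsFactors = FALSE)
}

#' Within-site duplicate rate per site
#'
#' For each site, the percentage of that site's records belonging to a
#' cluster that contains two or more records from that same site —
#' potential duplicate patients or mismatches. The denominator is the
#' site's record count.
#'
#' @param mi token-free \code{match_index}.
#' @return data.frame with columns DMID, n_records, n_duplicate, pct.
#' @export
within_site_duplicates <- function(mi) {
  assert_token_free(mi, "within_site_duplicates")
  parts <- split_ref_id(mi$DMID_PATID)
  key <- paste(mi$MATCH_ID, parts$DMID, sep = "\r")
  sz <- ave(seq_along(key), key, FUN = length)
  dup <- sz >= 2
  dmids <- sort(unique(parts$DMID))
  n_dup <- as.integer(tapply(dup, parts$DMID, sum)[dmids])
  n_rec <- as.integer(table(factor(parts$DMID, levels = dmids)))
  data.frame(DMID = dmids, n_records = n_rec, n_duplicate = n_dup,
             pct = round(100 * n_dup / n_rec, 1),
             stringsAsFactors = FALSE)
}

#' Pairwise patient overlap between sites
#'
#' For every unordered site pair, counts unique patients with at least one
#' record at both sites. The percentage is computed twice per pair, with
#' the shared-patient count as numerator both times and each site's unique
#' patient count in turn as denominator, and summarized (min, max, mean,
#' median) over all ordered percentages (two per pair; set
#' \code{ordered = FALSE} to summarize one value per unordered pair, the
#' larger of the two).
#'
#' @param mi token-free \code{match_index}.
#' @param ordered summarize over ordered pair percentages (default TRUE).
#' @return list with \code{site_counts} (unique patients per site),
#'   \code{pairs} (per-pair counts and both percentages, 1 decimal) and
#'   \code{summary}.
#' @export
pairwise_overlap <- function(mi, ordered = TRUE) {
  assert_token_free(mi, "pairwise_overlap")
  parts <- split_ref_id(mi$DMID_PATID)
  dmids <- sort(unique(parts$DMID))
  if (length(dmids) < 2) {
    warning("fewer than two sites: pairwise overlap section is empty",
            call. = FALSE)
    return(list(site_counts = NULL, pairs = NULL, summary = NULL))
  }
  # unique patients per site
  pm <- unique(data.frame(MATCH_ID = mi$MATCH_ID, DMID = parts$DMID,
                          stringsAsFactors = FALSE))
  counts <- table(factor(pm$DMID, levels = dmids))
  site_counts <- data.frame(DMID = dmids, n_patients = as.integer(counts),
                            stringsAsFactors = FALSE)
  sites_of <- split(pm$DMID, pm$MATCH_ID)
  pairs <- t(combn(dmids, 2))
  res <- data.frame(site1 = pairs[, 1], site2 = pairs[, 2],
                    stringsAsFactors = FALSE)
  res$overlap <- vapply(seq_len(nrow(res)), function(i) {
    sum(vapply(sites_of, function(s) {
      res$site1[i] %in% s && res$site2[i] %in% s
    }, logical(1)))
  }, integer(1))
  n1 <- site_counts$n_patients[match(res$site1, site_counts$DMID)]
  n2 <- site_counts$n_patients[match(res$site2, site_counts$DMID)]
  res$n_site1 <- n1
  res$n_site2 <- n2
  res$pct_of_site1 <- round(100 * res$overlap / n1, 1)
  res$pct_of_site2 <- round(100 * res$overlap / n2, 1)
  raw <- if (ordered) c(100 * res$overlap / n1, 100 * res$overlap / n2)
         else pmax(100 * res$overlap / n1, 100 * res$overlap / n2)
  summ <- data.frame(min = round(min(raw), 1), max = round(max(raw), 1),
                     mean = round(mean(raw), 1), median = round(median(raw), 1))
  list(site_counts = site_counts, pairs = res, summary = summ)
}

#' Full overlap report
#'
#' Bundles site multiplicity, within-site duplicate rates and pairwise
#' overlap from a token-free Match Index. All numbers are recomputable
#' from MATCH_ID and DMID_PATID alone; no token bytes are read.
#'
#' @param mi token-free \code{match_index}.
#' @param ordered passed to [pairwise_overlap()].
#' @return object of class \code{overlap_report}.
#' @export
overlap_report <- function(mi, ordered = TRUE) {
  assert_token_free(mi, "overlap_report")
  structure(list(
    n_records = nrow(mi),
    n_patients = length(unique(mi$MATCH_ID)),
    multiplicity = site_multiplicity(mi),
    within_site = within_site_duplicates(mi),
    pairwise = pairwise_overlap(mi, ordered = ordered)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap report:", x$n_records, "records,",
      x$n_patients, "unique patients\n\n")
  cat("Patients by number of sites:\n")
  print(x$multiplicity, row.names = FALSE)
  cat("\nWithin-site duplicate records:\n")
  print(x$within_site, row.names = FALSE)
  if (!is.null(x$pairwise$pairs)) {
    cat("\nPairwise overlap:\n")
    print(x$pairwise$pairs, row.names = FALSE)
    cat("\nSummary of pairwise percentages:\n")
    print(x$pairwise$summary, row.names = FALSE)
  }
  invisible(x)
}

#' Write an overlap report
#'
#' Emits tab-separated tables (human-readable) and a JSON variant carrying
#' the raw counts for exact downstream use.
#'
#' @param report an \code{overlap_report}.
#' @param path output path stem; \code{<path>.tsv} and \code{<path>.json}
#'   are written.
#' @export
write_overlap_report <- function(report, path) {
  tsv <- paste0(path, ".tsv")
  con <- file(tsv, "w")
  on.exit(close(con))
  w <- function(df, title) {
    writeLines(paste0("# ", title), con)
    write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines("", con)
  }
  w(report$multiplicity, "patients by number of sites")
  w(report$within_site, "within-site duplicate records")
  if (!is.null(report$pairwise$pairs)) {
    w(report$pairwise$site_counts, "unique patients per site")
    w(report$pairwise$pairs, "pairwise overlap")
    w(report$pairwise$summary, "summary of pairwise percentages")
  }
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
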