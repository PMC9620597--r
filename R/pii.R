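#' @importFrom utils read.csv write.csv write.table combn
#' @importFrom stats setNames runif median ave
NULL

PII_COLUMNS <- c("PATID", "FIRST_NAME", "LAST_NAME", "GENDER", "DOB",
                 "ZIP5", "SSN")
GENDER_CODES <- c("F", "M", "OT", "UN")

#' Read a PII extract
#'
#' PII extracts are headered comma-separated files with columns PATID,
#' FIRST_NAME, LAST_NAME, GENDER, DOB, ZIP5, SSN; an empty string means
#' missing. PATID must be non-empty and unique within a file (it is the
#' site-local pseudo-identifier).
#'
#' @param path file path.
#' @return data.frame with the seven PII columns, character-typed, missing
#'   values as \code{NA}.
#' @export
read_pii_extract <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(PII_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("PII extract '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[PII_COLUMNS]
  df[df == ""] <- NA_character_
  if (anyNA(df$PATID)) stop("PII extract has empty PATID values", call. = FALSE)
  if (anyDuplicated(df$PATID)) {
    stop("duplicate PATID within PII extract '", path,
         "': PATID must be unique per site", call. = FALSE)
  }
  df
}

#' Write a PII extract
#' @param pii data.frame of PII columns.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pii_extract <- function(pii, path) {
  out <- pii[PII_COLUMNS]
  out[is.na(out)] <- ""
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

norm_name <- function(x) {
  x <- toupper(gsub("[^A-Za-z]", "", x))
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

norm_digits <- function(x, width) {
  x <- gsub("[^0-9]", "", x)
  x[!is.na(x) & nchar(x) != width] <- NA_character_
  x
}

parse_dob <- function(x) {
  out <- rep(NA_character_, length(x))
  idx <- which(!is.na(x))
  for (i in idx) {
    d <- tryCatch(
      as.Date(x[i], tryFormats = c("%Y-%m-%d", "%m/%d/%Y", "%Y%m%d")),
      error = function(e) NA
    )
    if (is.na(d)) {
      warning("unparseable DOB '", x[i], "' treated as missing", call. = FALSE)
    } else {
      out[i] <- format(d, "%Y-%m-%d")
    }
  }
  out
}

#' Normalize raw PII for tokenization
#'
#' Deterministic canonicalization so that records differing only in letter
#' case, whitespace or punctuation produce identical token preimages:
#' names are uppercased and stripped to letters; SSN and zip are stripped to
#' digits and rejected as missing if not exactly 9 resp. 5 digits; gender is
#' uppercased and restricted to the CDM codes F, M, OT, UN (anything else is
#' missing); dates of birth are parsed (ISO, US slash, or compact form) and
#' serialized as ISO \code{YYYY-MM-DD} — an unparseable date becomes missing
#' with a warning, never an error. Derived fields used by token recipes are
#' added: first initial, soundex codes of both names, and the 3-digit zip
#' prefix. Missing inputs stay missing; the function is idempotent.
#'
#' @param pii data.frame as returned by [read_pii_extract()].
#' @return data.frame with the normalized PII columns plus FIRST_INITIAL,
#'   FIRST_SOUNDEX, LAST_SOUNDEX, ZIP3, DOB_ISO.
#' @export
normalize_pii <- function(pii) {
  stopifnot(is.data.frame(pii))
  if (!all(PII_COLUMNS %in% names(pii))) {
    stop("input lacks required PII columns", call. = FALSE)
  }
  patid <- as.character(pii$PATID)
  if (any(is.na(patid) | patid == "")) {
    stop("PATID must be non-empty", call. = FALSE)
  }
  n <- data.frame(
    PATID = patid,
    FIRST_NAME = norm_name(as.character(pii$FIRST_NAME)),
    LAST_NAME = norm_name(as.character(pii$LAST_NAME)),
    GENDER = toupper(trimws(as.character(pii$GENDER))),
    DOB = as.character(pii$DOB),
    ZIP5 = norm_digits(as.character(pii$ZIP5), 5L),
    SSN = norm_digits(as.character(pii$SSN), 9L),
    stringsAsFactors = FALSE
  )
  n$GENDER[!is.na(n$GENDER) & !(n$GENDER %in% GENDER_CODES)] <- NA_character_
  n$DOB_ISO <- parse_dob(n$DOB)
  n$DOB <- n$DOB_ISO
  n$FIRST_INITIAL <- substr(n$FIRST_NAME, 1, 1)
  n$FIRST_INITIAL[!is.na(n$FIRST_INITIAL) & n$FIRST_INITIAL == ""] <- NA_character_
  n$FIRST_SOUNDEX <- soundex(n$FIRST_NAME)
  n$LAST_SOUNDEX <- soundex(n$LAST_NAME)
  n$ZIP3 <- substr(n$ZIP5, 1, 3)
  n$ZIP3[!is.na(n$ZIP3) & n$ZIP3 == ""] <- NA_character_
  n
}
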