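TOKEN_COLUMNS <- paste0("TOKEN_0", 1:6)
TOKEN_STAGES <- c("master_hash", "site", "transit", "cc")

#' Create a key ring for the token lifecycle
#'
#' Holds the secret material for every stage of the token lifecycle: the
#' master salt keying the one-way hash (shared by all tokenizing sites, so
#' underlying hashes are comparable), one site-specific encryption key per
#' site, one transit key per (site, recipient) channel, and the coordinating
#' center's common key. All keys are independent 32-byte random values.
#'
#' @param site_ids character vector of site (DataMart) identifiers. The
#'   underscore is reserved as the DMID_PATID delimiter and may not appear
#'   in a site id.
#' @param recipient identifier of the token recipient (default "CC").
#' @return an object of class \code{pprl_keyring}.
#' @export
keyring_create <- function(site_ids, recipient = "CC") {
  stopifnot(length(site_ids) >= 1, !anyDuplicated(site_ids))
  if (any(grepl("_", site_ids, fixed = TRUE))) {
    stop("site ids may not contain '_' (reserved as the DMID_PATID delimiter)",
         call. = FALSE)
  }
  rnd <- function() paste(as.character(openssl::rand_bytes(32)), collapse = "")
  kr <- list(
    master_salt = rnd(),
    site_keys = setNames(lapply(site_ids, function(s) rnd()), site_ids),
    transit_keys = setNames(lapply(site_ids, function(s) rnd()), site_ids),
    cc_key = rnd(),
    recipient = recipient
  )
  all_keys <- c(kr$master_salt, unlist(kr$site_keys), unlist(kr$transit_keys),
                kr$cc_key)
  stopifnot(!anyDuplicated(all_keys))
  structure(kr, class = "pprl_keyring")
}

#' Write / read a key ring
#'
#' Keys are stored in a local JSON key file. Key files must never travel
#' with token files; token writers refuse to serialize keys.
#'
#' @param keyring a \code{pprl_keyring}.
#' @param path file path.
#' @return \code{read_keyring} returns a \code{pprl_keyring};
#'   \code{write_keyring} returns \code{path} invisibly.
#' @export
write_keyring <- function(keyring, path) {
  stopifnot(inherits(keyring, "pprl_keyring"))
  jsonlite::write_json(unclass(keyring), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_keyring
#' @export
read_keyring <- function(path) {
  kr <- jsonlite::read_json(path, simplifyVector = FALSE)
  kr$master_salt <- as.character(kr$master_salt)
  kr$cc_key <- as.character(kr$cc_key)
  kr$site_keys <- lapply(kr$site_keys, as.character)
  kr$transit_keys <- lapply(kr$transit_keys, as.character)
  structure(kr, class = "pprl_keyring")
}

# Token recipes: which normalized fields feed each of the six token slots,
# in fixed order. A missing constituent makes the whole preimage missing.
TOKEN_RECIPES <- list(
  c("LAST_NAME", "FIRST_INITIAL", "GENDER", "DOB_ISO"),
  c("LAST_SOUNDEX", "FIRST_SOUNDEX", "GENDER", "DOB_ISO"),
  c("LAST_NAME", "FIRST_NAME", "DOB_ISO", "ZIP3"),
  c("LAST_NAME", "FIRST_NAME", "GENDER", "DOB_ISO"),
  c("SSN", "GENDER", "DOB_ISO"),
  c("SSN", "FIRST_NAME")
)

#' Build the six token preimages from normalized PII
#'
#' Each token slot concatenates a fixed combination of identifier fields
#' with a \code{"|"} delimiter: (1) last name + first initial + gender +
#' date of birth; (2) soundex of last name + soundex of first name + gender
#' + date of birth; (3) last name + first name + date of birth + 3-digit
#' zip; (4) last name + first name + gender + date of birth; (5) SSN +
#' gender + date of birth; (6) SSN + first name. If any constituent is
#' missing the whole preimage is missing — the delimiter therefore never
#' has to encode a missing field, which prevents concatenation ambiguity.
#'
#' @param norm data.frame from [normalize_pii()].
#' @return character matrix, one row per record, columns TOKEN_01..TOKEN_06;
#'   \code{NA} where a constituent was missing.
#' @export
token_preimages <- function(norm) {
  need <- unique(unlist(TOKEN_RECIPES))
  if (!all(need %in% names(norm))) {
    stop("input is not normalized PII (run normalize_pii first)", call. = FALSE)
  }
  out <- matrix(NA_character_, nrow = nrow(norm), ncol = 6,
                dimnames = list(NULL, TOKEN_COLUMNS))
  for (i in seq_along(TOKEN_RECIPES)) {
    fields <- norm[TOKEN_RECIPES[[i]]]
    complete <- !Reduce(`|`, lapply(fields, is.na))
    if (any(complete)) {
      out[complete, i] <- do.call(paste,
                                  c(lapply(fields, function(x) x[complete]),
                                    sep = "|"))
    }
  }
  out
}

#' Hash token preimages under the master salt
#'
#' Passes each preimage through a one-way keyed secure hash
#' (HMAC-SHA-256) with the master salt as key, irreversibly destroying the
#' underlying identifiers. Identical PII under the same salt always yields
#' identical digests; different salts yield unrelated digests.
#'
#' @param preimages character matrix from [token_preimages()].
#' @param master_salt non-empty secret string.
#' @return character matrix of lowercase-hex 32-byte digests (64 hex
#'   characters), \code{NA} propagated from missing preimages, with
#'   attribute \code{stage = "master_hash"}.
#' @export
hash_tokens <- function(preimages, master_salt) {
  if (!is.character(master_salt) || length(master_salt) != 1 ||
      is.na(master_salt) || !nzchar(master_salt)) {
    stop("master_salt must be a non-empty string", call. = FALSE)
  }
  out <- preimages
  present <- !is.na(preimages)
  if (any(present)) {
    out[present] <- as.character(openssl::sha256(preimages[present],
                                                 key = master_salt))
  }
  structure(out, stage = "master_hash")
}

key_bytes <- function(key_hex) {
  openssl::sha256(charToRaw(key_hex))  # normalize any key string to 32 bytes
}

ZERO_IV <- as.raw(rep(0L, 16))

encrypt_hex <- function(tokens_hex, key_hex) {
  key <- key_bytes(key_hex)
  vapply(tokens_hex, function(h) {
    if (is.na(h)) return(NA_character_)
    raw_in <- hex_to_raw(h)
    paste(as.character(openssl::aes_cbc_encrypt(raw_in, key = key,
                                                iv = ZERO_IV)),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

decrypt_hex <- function(tokens_hex, key_hex) {
  key <- key_bytes(key_hex)
  vapply(tokens_hex, function(h) {
    if (is.na(h)) return(NA_character_)
    raw_in <- hex_to_raw(h)
    paste(as.character(openssl::aes_cbc_decrypt(raw_in, key = key,
                                                iv = ZERO_IV)),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

hex_to_raw <- function(h) {
  if (nchar(h) %% 2 != 0) stop("malformed hex token", call. = FALSE)
  as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)),
                base = 16L))
}

stage_key <- function(keyring, stage, site_id = NULL) {
  switch(stage,
    site = {
      k <- keyring$site_keys[[site_id]]
      if (is.null(k)) stop("no site key for '", site_id, "'", call. = FALSE)
      k
    },
    transit = {
      k <- keyring$transit_keys[[site_id]]
      if (is.null(k)) stop("no transit key for '", site_id, "'", call. = FALSE)
      k
    },
    cc = keyring$cc_key,
    stop("stage '", stage, "' carries no encryption layer", call. = FALSE)
  )
}

#' Encrypt or decrypt one stage layer of a token matrix
#'
#' Tokens move through three encryption schemes after the master hash:
#' site-specific (each site's tokens are unique, so a breach at one site
#' does not propagate), transit (unique per site-to-recipient channel), and
#' the coordinating center's common scheme, under which — and only under
#' which — tokens from different sites become comparable. Each layer is a
#' deterministic, invertible, equality-preserving block encryption
#' (AES-256-CBC with a fixed zero IV over the fixed-length digest):
#' \code{E(a) == E(b)} iff \code{a == b} under one key, and encryptions of
#' the same digest under different keys differ. The missingness mask is
#' never changed by a stage transition.
#'
#' @param tokens character matrix of hex tokens with a \code{stage}
#'   attribute (\code{"master_hash"} for \code{encrypt_stage} input at the
#'   first transition).
#' @param keyring a \code{pprl_keyring}.
#' @param to,from target / current stage: \code{"site"}, \code{"transit"}
#'   or \code{"cc"}.
#' @param site_id required for the site and transit schemes.
#' @return token matrix with updated \code{stage} attribute.
#' @export
encrypt_stage <- function(tokens, keyring, to, site_id = NULL) {
  to <- match.arg(to, c("site", "transit", "cc"))
  cur <- attr(tokens, "stage")
  if (!identical(cur, "master_hash")) {
    stop("encrypt_stage expects master-hash tokens; got stage '", cur, "'",
         call. = FALSE)
  }
  key <- stage_key(keyring, to, site_id)
  out <- apply_hex(tokens, encrypt_hex, key)
  attr(out, "stage") <- to
  out
}

#' @rdname encrypt_stage
#' @export
decrypt_stage <- function(tokens, keyring, from, site_id = NULL) {
  from <- match.arg(from, c("site", "transit", "cc"))
  cur <- attr(tokens, "stage")
  if (!identical(cur, from)) {
    stop("decrypt_stage: tokens are at stage '", cur, "', not '", from, "'",
         call. = FALSE)
  }
  key <- stage_key(keyring, from, site_id)
  out <- apply_hex(tokens, decrypt_hex, key)
  attr(out, "stage") <- "master_hash"
  out
}

apply_hex <- function(tokens, fn, key) {
  out <- tokens
  present <- !is.na(tokens)
  if (any(present)) out[present] <- fn(tokens[present], key)
  out
}

#' Re-encrypt tokens from one scheme into another
#'
#' The transform-tokens step: peels the current encryption layer and applies
#' the next one, without ever exposing the underlying identifiers (only the
#' master hash is transiently in memory). Sites run
#' \code{site -> transit} before upload; the coordinating center runs
#' \code{transit -> cc} so that tokens can only be linked there.
#'
#' @inheritParams encrypt_stage
#' @export
transform_tokens <- function(tokens, keyring, from, to, site_id = NULL) {
  hashes <- decrypt_stage(tokens, keyring, from = from, site_id = site_id)
  encrypt_stage(hashes, keyring, to = to, site_id = site_id)
}

#' Tokenize a site's PII extract into a HASH_TOKEN file
#'
#' Runs the full on-premises tokenize step for one site: normalize PII,
#' build the six preimages, hash under the master salt, and encrypt under
#' the site-specific key. One output row per input row; no PII leaves this
#' function. The output mirrors the CDM HASH_TOKEN table: one row per
#' patient, columns PATID, TOKEN_01..TOKEN_06, lowercase hex, empty string
#' for a missing token.
#'
#' @param pii_file path to a PII extract.
#' @param site_id the site's DataMart identifier (key-ring lookup).
#' @param keyring a \code{pprl_keyring}.
#' @param out_file output path for the HASH_TOKEN extract.
#' @return the token data.frame (stage \code{"site"}), invisibly if
#'   \code{out_file} is given.
#' @export
tokenize_site_file <- function(pii_file, site_id, keyring, out_file = NULL) {
  pii <- if (is.data.frame(pii_file)) pii_file else read_pii_extract(pii_file)
  if (anyDuplicated(pii$PATID)) {
    stop("duplicate PATID within site '", site_id, "'", call. = FALSE)
  }
  norm <- suppressWarnings(normalize_pii(pii))
  tok <- encrypt_stage(hash_tokens(token_preimages(norm), keyring$master_salt),
                       keyring, to = "site", site_id = site_id)
  df <- token_df(pii$PATID, tok, stage = "site")
  if (!is.null(out_file)) {
    write_token_file(df, out_file)
    return(invisible(df))
  }
  df
}

token_df <- function(patid, tokens, stage) {
  df <- data.frame(PATID = patid, stringsAsFactors = FALSE)
  for (j in seq_len(6)) df[[TOKEN_COLUMNS[j]]] <- unname(tokens[, j])
  structure(df, stage = stage, class = c("hash_token_df", "data.frame"))
}

token_matrix <- function(df) {
  m <- as.matrix(df[TOKEN_COLUMNS])
  dimnames(m) <- list(NULL, TOKEN_COLUMNS)
  structure(m, stage = attr(df, "stage"))
}

#' Read / write HASH_TOKEN extracts
#'
#' Headered comma-separated text, columns PATID, TOKEN_01..TOKEN_06
#' (lowercase hex, empty string = missing). The file format does not carry
#' the encryption stage, so the reader takes it as an argument and checks
#' the hex length convention (64 characters for master hashes, 96 for any
#' encrypted scheme).
#'
#' @param df a token data.frame from [tokenize_site_file()] or
#'   [transform_token_file()].
#' @param path file path.
#' @param stage declared stage of the file's tokens.
#' @export
write_token_file <- function(df, path) {
  out <- as.data.frame(df)[c("PATID", TOKEN_COLUMNS)]
  out[is.na(out)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_token_file
#' @export
read_token_file <- function(path, stage) {
  stage <- match.arg(stage, TOKEN_STAGES)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("PATID", TOKEN_COLUMNS)
  if (!all(need %in% names(df))) {
    stop("not a HASH_TOKEN file: '", path, "'", call. = FALSE)
  }
  df <- df[need]
  df[df == ""] <- NA_character_
  expected_len <- if (stage == "master_hash") 64L else 96L
  lens <- nchar(unlist(df[TOKEN_COLUMNS]))
  lens <- lens[!is.na(lens)]
  if (length(lens) && any(lens != expected_len)) {
    stop("token hex length inconsistent with declared stage '", stage, "'",
         call. = FALSE)
  }
  structure(df, stage = stage, class = c("hash_token_df", "data.frame"))
}

#' Transform a HASH_TOKEN file between encryption schemes
#'
#' @param in_file input HASH_TOKEN path (or token data.frame).
#' @param keyring a \code{pprl_keyring}.
#' @param from,to current and target stage.
#' @param site_id site whose site/transit keys apply.
#' @param out_file optional output path.
#' @return transformed token data.frame.
#' @export
transform_token_file <- function(in_file, keyring, from, to, site_id,
                                 out_file = NULL) {
  df <- if (is.data.frame(in_file)) in_file else read_token_file(in_file, from)
  tok <- transform_tokens(token_matrix(df), keyring, from = from, to = to,
                          site_id = site_id)
  out <- token_df(df$PATID, tok, stage = to)
  if (!is.null(out_file)) {
    write_token_file(out, out_file)
    return(invisible(out))
  }
  out
}
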