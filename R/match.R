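#' Majority-vote token match between two records
#'
#' Two records are declared a match when, over the token slots available
#' (non-missing) in \emph{both} records, strictly more than half carry
#' equal values. A slot missing on either side cannot be compared and does
#' not vote. The rule is conservative: a 2-of-4 tie is a non-match, and a
#' pair with no mutually available slot never matches.
#'
#' @param a,b character vectors of 6 tokens (NA = missing), same encryption
#'   scheme. Matrices with a \code{stage} attribute are accepted; mixed
#'   stages are an error because tokens under different schemes are never
#'   comparable.
#' @param min_available minimum number of mutually available slots required
#'   before a match may be declared (default 1, the plain majority rule).
#' @return logical scalar; symmetric in \code{a} and \code{b}.
#' @export
pair_is_match <- function(a, b, min_available = 1L) {
  sa <- attr(a, "stage"); sb <- attr(b, "stage")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("token stage mismatch: '", sa, "' vs '", sb, "'", call. = FALSE)
  }
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  avail <- !is.na(a) & !is.na(b)
  n_avail <- sum(avail)
  if (n_avail < max(1L, min_available)) return(FALSE)
  sum(a[avail] == b[avail]) > n_avail / 2
}

# Disjoint-set forest; roots are found by chasing parents. Clusters in this
# problem are tiny (a patient appears at a handful of sites), so no path
# compression is needed.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build the Match Index from per-site token extracts
#'
#' Compares all candidate record pairs — across sites and within a site,
#' since within-site duplicates are part of the analysis — under the
#' majority rule and clusters matching records into master patient ids by
#' transitive closure (union-find over the match graph). Candidate pairs
#' are generated by exact-token blocking: a majority match requires at
#' least one shared token value, so only records sharing some token value
#' in some slot are ever compared; the result equals the all-pairs
#' computation. Each record is identified by its network-wide reference id
#' \code{DMID_PATID}; MATCH_ID labels are assigned sequentially after
#' sorting clusters by their lexicographically smallest member, so output
#' is independent of input file order.
#'
#' @param token_sets named list (names = DMID) of token data.frames at the
#'   coordinating-center stage, as from [transform_token_file()] or
#'   [read_token_file()].
#' @param min_available passed to [pair_is_match()].
#' @return a \code{match_index} data.frame with columns MATCH_ID,
#'   DMID_PATID, TOKEN_01..TOKEN_06 and attribute \code{token_free = FALSE}.
#'   The token-bearing variant stays on the token side of the privacy
#'   boundary; see [strip_tokens()].
#' @export
build_match_index <- function(token_sets, min_available = 1L) {
  stopifnot(is.list(token_sets), length(token_sets) >= 1)
  dmids <- names(token_sets)
  if (is.null(dmids) || any(!nzchar(dmids))) {
    stop("token_sets must be a named list keyed by DMID", call. = FALSE)
  }
  if (any(grepl("_", dmids, fixed = TRUE))) {
    stop("DMID may not contain '_'", call. = FALSE)
  }
  for (df in token_sets) {
    st <- attr(df, "stage")
    if (!is.null(st) && !identical(st, "cc")) {
      stop("matching requires coordinating-center stage tokens; got '",
           st, "'", call. = FALSE)
    }
  }
  ref_id <- unlist(lapply(dmids, function(d) {
    p <- token_sets[[d]]$PATID
    if (length(p) == 0) character(0) else paste0(d, "_", p)
  }), use.names = FALSE)
  if (length(ref_id) == 0) {
    mi <- data.frame(MATCH_ID = character(0), DMID_PATID = character(0),
                     stringsAsFactors = FALSE)
    for (j in seq_len(6)) mi[[TOKEN_COLUMNS[j]]] <- character(0)
    return(structure(mi, token_free = FALSE,
                     class = c("match_index", "data.frame")))
  }
  if (anyDuplicated(ref_id)) {
    stop("duplicate DMID_PATID across token files", call. = FALSE)
  }
  tok <- do.call(rbind, lapply(token_sets, function(df) {
    as.matrix(as.data.frame(df)[TOKEN_COLUMNS])
  }))
  rownames(tok) <- NULL
  n <- length(ref_id)

  parent <- seq_len(n)
  # blocking: records sharing a token value in any slot are candidates
  for (j in seq_len(6)) {
    col <- tok[, j]
    groups <- split(which(!is.na(col)), col[!is.na(col)])
    for (g in groups) {
      if (length(g) < 2) next
      anchor <- g[1]
      for (i in g[-1]) {
        ra <- uf_find(parent, anchor); ri <- uf_find(parent, i)
        if (ra == ri) next
        if (pair_is_match(tok[anchor, ], tok[i, ], min_available)) {
          parent[max(ra, ri)] <- min(ra, ri)
        } else {
          # anchor transitivity does not hold for majority matching:
          # compare i against every other block member explicitly
          for (k in g[g != i]) {
            rk <- uf_find(parent, k); ri <- uf_find(parent, i)
            if (rk != ri && pair_is_match(tok[k, ], tok[i, ], min_available)) {
              parent[max(rk, ri)] <- min(rk, ri)
            }
          }
        }
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))

  # deterministic labels: order clusters by smallest member ref_id
  cluster_min <- tapply(ref_id, root, min)
  ord <- order(cluster_min)
  label <- setNames(sprintf("M%06d", seq_along(ord)),
                    names(cluster_min)[ord])
  mi <- data.frame(MATCH_ID = unname(label[as.character(root)]),
                   DMID_PATID = ref_id,
                   stringsAsFactors = FALSE)
  for (j in seq_len(6)) mi[[TOKEN_COLUMNS[j]]] <- tok[, j]
  mi <- mi[order(mi$MATCH_ID, mi$DMID_PATID), ]
  rownames(mi) <- NULL
  structure(mi, token_free = FALSE, class = c("match_index", "data.frame"))
}

#' Drop token columns from a Match Index
#'
#' Produces the token-free Match Index — MATCH_ID and DMID_PATID only —
#' the only artifact that crosses the privacy boundary to the analysis
#' team. Every overlap and demographics computation downstream consumes
#' this variant and refuses token-bearing input.
#'
#' @param mi a \code{match_index}.
#' @return token-free \code{match_index} (idempotent).
#' @export
strip_tokens <- function(mi) {
  out <- as.data.frame(mi)[intersect(c("MATCH_ID", "DMID_PATID"), names(mi))]
  structure(out, token_free = TRUE, class = c("match_index", "data.frame"))
}

#' Read / write Match Index files
#'
#' Headered comma-separated text. Full variant: MATCH_ID, DMID_PATID,
#' TOKEN_01..TOKEN_06; token-free variant: MATCH_ID, DMID_PATID.
#'
#' @param mi a \code{match_index}.
#' @param path file path.
#' @param expect_token_free if TRUE, reading a file that carries token
#'   columns is a privacy-boundary error rather than a format choice.
#' @export
write_match_index <- function(mi, path) {
  out <- as.data.frame(mi)
  out[is.na(out)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_match_index
#' @export
read_match_index <- function(path, expect_token_free = FALSE) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("MATCH_ID", "DMID_PATID") %in% names(df))) {
    stop("not a Match Index file: '", path, "'", call. = FALSE)
  }
  has_tokens <- any(TOKEN_COLUMNS %in% names(df))
  if (expect_token_free && has_tokens) {
    stop_privacy("Match Index file '", path, "' carries token columns; ",
                 "the analysis side accepts only the token-free variant")
  }
  keep <- c("MATCH_ID", "DMID_PATID",
            if (has_tokens) intersect(TOKEN_COLUMNS, names(df)))
  df <- df[keep]
  df[df == ""] <- NA_character_
  structure(df, token_free = !has_tokens,
            class = c("match_index", "data.frame"))
}

stop_privacy <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pprl_privacy_error", "error")))
}

# split DMID_PATID at the first underscore (DMID contains none)
split_ref_id <- function(ref_id) {
  pos <- regexpr("_", ref_id, fixed = TRUE)
  if (any(pos < 0)) stop("malformed DMID_PATID reference id", call. = FALSE)
  data.frame(DMID = substr(ref_id, 1, pos - 1),
             PATID = substr(ref_id, pos + 1, nchar(ref_id)),
             stringsAsFactors = FALSE)
}

assert_token_free <- function(mi, what) {
  if (any(TOKEN_COLUMNS %in% names(mi)) ||
      identical(attr(mi, "token_free"), FALSE)) {
    stop_privacy(what, " operates on the analysis side and accepts only a ",
                 "token-free Match Index (use strip_tokens)")
  }
  invisible(mi)
}
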