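# Shared fixtures built in code.

# a small fully-populated PII frame
make_pii <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    PATID = sprintf("P%03d", seq_len(n)),
    FIRST_NAME = sample(c("JANE", "JOHN", "MARY", "ROBERT", "ALICE"), n, TRUE),
    LAST_NAME = sample(c("SMITH", "OBRIEN", "GARCIA", "LEE"), n, TRUE),
    GENDER = sample(c("F", "M"), n, TRUE),
    DOB = format(as.Date("1960-01-01") + sample(15000, n), "%Y-%m-%d"),
    ZIP5 = sprintf("%05d", sample(10000:99999, n)),
    SSN = sprintf("%09d", sample(1e8, n) + 1e8),
    stringsAsFactors = FALSE
  )
}

test_keyring <- function(sites = c("A", "B")) keyring_create(sites)

# tokenize a PII frame straight to the coordinating-center stage
cc_tokens_for <- function(pii, site, keyring) {
  st <- tokenize_site_file(pii, site, keyring)
  tr <- transform_token_file(st, keyring, from = "site", to = "transit",
                             site_id = site)
  transform_token_file(tr, keyring, from = "transit", to = "cc",
                       site_id = site)
}

# hand-built token matrix (hex-ish strings are fine: matching is equality)
tok_row <- function(...) {
  v <- c(...)
  stopifnot(length(v) == 6)
  v
}

# token data.frame at a declared stage from a plain matrix
tok_df <- function(patids, m, stage = "cc") {
  df <- data.frame(PATID = patids, stringsAsFactors = FALSE)
  for (j in 1:6) df[[paste0("TOKEN_0", j)]] <- m[, j]
  structure(df, stage = stage, class = c("hash_token_df", "data.frame"))
}

# random token sets with shared persons for oracle comparisons:
# returns a named list of token data.frames ("cc" stage) where some persons
# appear at several sites and slots are masked at random
random_token_instance <- function(n_persons, n_sites = 2, p_share = 0.3,
                                  p_missing = 0.3, p_corrupt = 0.1) {
  persons <- matrix(sprintf("h%05d", sample(1e5, n_persons * 6)),
                    ncol = 6)
  sites <- paste0("S", seq_len(n_sites))
  out <- list()
  for (s in seq_along(sites)) {
    keep <- if (s == 1) seq_len(n_persons) else
      which(runif(n_persons) < p_share)
    if (length(keep) == 0) keep <- 1L
    m <- persons[keep, , drop = FALSE]
    mask <- matrix(runif(length(m)) < p_missing, nrow = nrow(m))
    m[mask] <- NA_character_
    corrupt <- matrix(runif(length(m)) < p_corrupt, nrow = nrow(m))
    m[corrupt & !mask] <- sprintf("x%07d", sample(1e7, sum(corrupt & !mask)))
    out[[sites[s]]] <- tok_df(sprintf("P%04d", keep), m)
  }
  out
}

# independent oracle: all-pairs majority matching + igraph components
brute_force_partition <- function(token_sets, min_available = 1L) {
  ref <- unlist(lapply(names(token_sets), function(s) {
    paste0(s, "_", token_sets[[s]]$PATID)
  }))
  m <- do.call(rbind, lapply(token_sets, function(df) {
    as.matrix(as.data.frame(df)[paste0("TOKEN_0", 1:6)])
  }))
  n <- length(ref)
  edges <- c()
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- m[i, ]; b <- m[j, ]
      avail <- !is.na(a) & !is.na(b)
      if (sum(avail) >= min_available && sum(avail) > 0 &&
          sum(a[avail] == b[avail]) > sum(avail) / 2) {
        edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # canonical form: sets of ref ids
  unname(lapply(split(ref, comp), function(x) sort(x)))
}

canonical_partition <- function(mi) {
  unname(lapply(split(mi$DMID_PATID, mi$MATCH_ID), sort))
}

partition_equal <- function(p1, p2) {
  setequal(vapply(p1, paste, character(1), collapse = "|"),
           vapply(p2, paste, character(1), collapse = "|"))
}

clean_config <- function(seed, sites = c("DM1", "DM2", "DM3", "DM4"),
                         n_records = c(500, 400, 300, 200),
                         overlap = NULL, ...) {
  if (is.null(overlap)) {
    overlap <- if (identical(sites, c("DM1", "DM2", "DM3", "DM4"))) {
      c("DM1-DM2" = 0.01, "DM1-DM3" = 0.005, "DM2-DM4" = 0.005)
    } else numeric(0)
  }
  sim_config(sites = sites, n_records = n_records, overlap = overlap,
             typo_rate = 0, dob_error_rate = 0, discordance_rate = 0,
             seed = seed, ...)
}
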