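#' Run the full linkage pipeline on a synthetic population in memory
#'
#' Convenience wrapper chaining every stage the distributed deployment runs
#' across organizations: generate a population, tokenize each site's PII
#' under its site scheme, transform site tokens to transit and then to the
#' coordinating-center scheme, match and cluster into a Match Index, strip
#' tokens at the privacy boundary, and compute the overlap report,
#' characteristics table and ground-truth evaluation from the token-free
#' index. PII and token bytes never reach the analysis-side computations.
#'
#' @param cfg a [sim_config()]; its seed drives the whole run.
#' @param min_available passed to [build_match_index()].
#' @return list with \code{population}, \code{match_index} (token-bearing),
#'   \code{match_index_tf} (token-free), \code{overlap},
#'   \code{characteristics}, \code{evaluation}.
#' @export
run_pipeline <- function(cfg, min_available = 1L) {
  pop <- generate_population(cfg)
  keyring <- keyring_create(cfg$sites)
  cc_tokens <- lapply(cfg$sites, function(s) {
    site_tok <- tokenize_site_file(pop$pii[[s]], s, keyring)
    transit <- transform_token_file(site_tok, keyring, from = "site",
                                    to = "transit", site_id = s)
    transform_token_file(transit, keyring, from = "transit", to = "cc",
                         site_id = s)
  })
  names(cc_tokens) <- cfg$sites
  mi <- build_match_index(cc_tokens, min_available = min_available)
  mi_tf <- strip_tokens(mi)
  list(
    population = pop,
    match_index = mi,
    match_index_tf = mi_tf,
    overlap = overlap_report(mi_tf),
    characteristics = build_characteristics_table(pop$demo, mi_tf),
    evaluation = evaluate_linkage(mi_tf, pop$truth)
  )
}
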