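---
title: "Privacy-preserving record linkage with hashed tokens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving record linkage with hashed tokens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprlink)
```

## The problem

Patients accumulate records at many health-care institutions. A distributed
research network that wants de-duplicated patient counts — or a complete view
of one patient's encounters across sites — must decide which records at
different sites belong to the same person, without any site ever disclosing
names, birth dates or social security numbers. `pprlink` implements a
complete privacy-preserving record linkage (PPRL) workflow for this setting:
sites convert identifiers into irreversible hashed tokens on premises, a
coordinating center compares tokens it cannot invert, and an analysis team
works only with an anonymous cluster index.

## Token model

Each patient record is reduced to six tokens. A token is the HMAC-SHA-256
digest, keyed by a shared secret *master salt*, of a fixed combination of
normalized identifier fields:

| token | constituents |
|-------|--------------|
| 1 | last name, first initial, gender, date of birth |
| 2 | soundex(last name), soundex(first name), gender, date of birth |
| 3 | last name, first name, date of birth, 3-digit zip |
| 4 | last name, first name, gender, date of birth |
| 5 | SSN, gender, date of birth |
| 6 | SSN, first name |

The constituents are joined with `|` in a fixed order. If any constituent is
missing, the whole token is missing — so a token either encodes the complete
combination or nothing, and the delimiter never has to represent an absent
field (which would invite concatenation ambiguities such as
`("AB","C")` vs `("A","BC")`).

Two design points matter here:

* **Normalization is the only tolerance mechanism besides soundex.** Hashes
  match only on exact preimage equality, so `normalize_pii()` canonicalizes
  aggressively: names are uppercased and stripped to letters, SSN/zip are
  stripped to digits and discarded if not exactly 9/5 digits, dates are
  serialized as ISO `YYYY-MM-DD`, and gender is restricted to the common
  data model codes `F`, `M`, `OT`, `UN`. Anything unparseable becomes
  missing (with a warning), never an error: a site extract should tokenize
  end to end even when dirty.
* **Soundex provides phonetic tolerance.** Token 2 replaces both names by
  their American Soundex codes (first letter plus three digits from the
  consonant classes, `h`/`w` transparent, vowels separating repeated codes),
  so *Jon* and *John* — or a one-letter typo that preserves the sound class —
  still agree in that slot. We implement classic American Soundex; no variant
  is claimed to be byte-compatible with any commercial tokenizer, and such
  compatibility is explicitly out of scope.

## Encryption lifecycle

The master-salt hash is never stored. Tokens pass through three deterministic
encryption schemes:

1. **site** — each site encrypts its hashes under a site-specific key, so a
   breach at one site reveals nothing about another's tokens;
2. **transit** — re-encrypted under a per-site transit key for upload to the
   coordinating center;
3. **cc** — the center transforms every site's tokens into one common
   scheme; only under this scheme are tokens from different sites
   comparable.

Each layer must be deterministic (the center compares tokens for equality),
invertible (the next layer replaces, not wraps, the previous one) and
equality-preserving (`E(a) = E(b)` iff `a = b` under one key). We realize it
as AES-256-CBC with a fixed all-zero IV over the fixed-length 32-byte
digest. A fixed IV would be a defect for general-purpose encryption; here
the plaintexts are uniformly distributed HMAC digests of high-entropy keyed
input, the determinism is the point, and the construction is exactly a
keyed pseudorandom permutation applied blockwise. Any other deterministic
keyed permutation could be substituted without touching the rest of the
pipeline. Master hashes are 64 hex characters; encrypted tokens are 96 (the
CBC padding block), and file readers check this length convention against
the declared stage.

## Matching rule

Two records match when, among the token slots available in *both* records,
strictly more than half are equal (`pair_is_match()`). The interpretation
of "available" as the intersection is deliberate: a slot missing on either
side carries no evidence. The strict majority makes a 2-of-4 tie a
non-match — a conservative choice that favors precision over recall.
`min_available` (default 1) can require more mutually available slots
before any match is declared; single-token matches are the least supported
and the parameter exists to let a study tighten that.

Majority matching is not transitive, so `build_match_index()` takes the
transitive closure: connected components of the pairwise match graph,
computed with a union-find structure, become master patient ids
(`MATCH_ID`). Candidate pairs come from exact-token blocking — only records
sharing at least one token value in some slot are compared — which is
output-equivalent to all-pairs comparison because a majority match needs at
least one shared token. The all-pairs equivalence is verified in the test
suite against an independent brute-force implementation on hundreds of
random instances. Cluster labels are assigned after sorting components by
their smallest member id, so the output is invariant to input file order.

## Privacy boundary

The matcher's full output (MATCH_ID, DMID_PATID, tokens) stays with the
token team. `strip_tokens()` produces the token-free Match Index —
MATCH_ID and DMID_PATID only — which is the sole artifact that crosses to
the analysis team. Every analysis-side function (`site_multiplicity()`,
`within_site_duplicates()`, `pairwise_overlap()`,
`build_characteristics_table()`, and the corresponding CLI subcommands)
refuses token-bearing input with a classed `pprl_privacy_error`; the CLI
maps it to its own exit code. The boundary models an organizational
separation, not process isolation: the point is that the analysis outputs
are demonstrably recomputable from the token-free index alone, which the
test suite checks by recomputing every report from a stripped file.

## Overlap statistics

From the token-free index the package reports, mirroring the shape of a
multi-site overlap study:

* the percentage of unique patients appearing in exactly 1, 2, 3 or ≥4
  sites (a patient whose only extra records are within-site duplicates
  still counts once);
* per site, the percentage of records in clusters with ≥2 records from
  that same site (potential duplicates), with the site's record count as
  denominator;
* per site pair, the shared-patient count and two percentages — the count
  divided by each site's unique patient count in turn — summarized by
  min/max/mean/median. The summary spans the ordered percentages (two per
  pair) by default; `ordered = FALSE` summarizes one value per unordered
  pair instead.

Report percentages are rounded to one decimal, matching the granularity
such studies print; raw counts are always emitted alongside for exact
downstream use.

## Demographic deduplication and adjudication

Demographics (age group, sex, race, in closed vocabularies with the CDM
code mappings accepted on input) are tabulated twice: over all records, and
over one consolidated record per cluster. Consolidation is missing-aware:
uninformative values (`Other/Missing`, `NA`) are dropped first, then a
single remaining distinct value wins; genuinely conflicting informative
values become **Discordant** for sex and race. This drop-first policy is
the only one under which merging a `{Female, Other/Missing}` cluster yields
`Female` — which is what lets the Other/Missing category shrink under
deduplication while the Discordant row stays near zero, the behavior a
consolidated characteristics table should show. Age has no discordant
category; conflicting age groups resolve to the oldest, a deterministic,
configurable interpretation (records from different encounter years can
legitimately differ in age group, and the oldest observation is the most
recent). The headline reduction is reported to two decimals with plain
rounding; category-level reductions in prose conventionally truncate, and
`percent_reduction()` exposes both modes explicitly rather than hiding the
convention.

Age group arrives as a category, never as a date of birth: the analysis
side must not be able to reconstruct identifier fields, so sites compute
the category upstream.

## The synthetic population generator

No real linkage data can ship with the package, so `sim_config()` +
`generate_population()` create multi-site populations with known
ground-truth equivalence classes (`LinkTruth`), exercising every pipeline
stage. The defaults emulate a four-site pilot network at desk scale:

* four sites of 3000/2400/1800/1200 records (a real pilot's sites are a
  few hundred thousand to a million patients each; the package's test and
  example runs use 10^3–10^4 records so a full pipeline completes in tens
  of seconds, and every reported statistic is scale-free);
* three of the six site pairs share patients, the largest overlap being
  0.2% of a site's patient count and about 0.1% of all patients appearing
  at two sites;
* within-site duplicate records at 0.02% of records;
* SSN availability per site of 0%, 62%, 70% and 99% (range hitting 0 and
  99, median 66%) while names, gender and birth dates are complete —
  reflecting how much more variable SSN capture is in practice;
* a 1% per-appearance name-typo rate and 0.5% date-error rate as a
  realistic dirtiness level for EHR identifier fields, and a 0.2% race
  discordance rate so the Discordant pathway is exercised at toy scale.

Corruption is applied per appearance, after shared persons receive
identical base PII at all their sites; every corruption event is logged
with its type (soundex-preserving vs soundex-breaking typos are
distinguished) so evaluations can condition on it. One global seed drives
labeled substreams per site and per site pair, keeping runs byte-identical.

Two generator properties are deliberate idealizations:

* **Distinct persons are distinguishable.** After sampling, any two
  persons coinciding in first name, last name, gender and date of birth
  have the date redrawn within the same age group. Records identical in
  all token constituents are information-theoretically unlinkable-apart,
  so leaving such coincidences in the truth would make perfect precision
  unattainable by any method; the generator instead guarantees the truth
  is identifiable, and token-level collisions remain possible only through
  the corruption model.
* **SSNs are unique per person**, so SSN-based tokens never collide across
  distinct persons.

What the generator does *not* model: realistic name/ethnicity correlation
(names come from a small bundled frequency list), geographic or temporal
encounter structure, address fields (address-derived tokens are out of
scope), nicknames and transliteration, or sites with systematically
different data-entry conventions. Passing tests therefore demonstrate the
pipeline's mechanics — exact linkage under clean identifiers, graceful
degradation under the modeled corruptions, conservation of every reported
margin — not field performance on real EHR data, where error structure is
richer.

`evaluate_linkage()` scores an inferred index against the truth by
pairwise precision and recall (with the 0-predicted-pairs and 0-true-pairs
cases defined as 1.0), and reports the absolute error of each pairwise
overlap percentage against the truth-implied value.

## Numerical and degenerate-input choices

* Percentages: one decimal in tables; reduction headline two decimals;
  both raw counts and percentages always available.
* Empty inputs flow through: an empty PII extract tokenizes to a headered
  empty token file; an empty token set yields an empty match index; a
  single-site index produces an empty pairwise section with a warning.
* Malformed dates and wrong-length SSN/zip degrade to missing with a
  warning; duplicate PATIDs within a site, duplicate reference ids across
  sites, stage mismatches and out-of-vocabulary demographic codes are hard
  errors.
* Tie-break in clustering: none needed — the partition is a closure, and
  labels come from sorting components by smallest member.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- sim_config(typo_rate = 0, dob_error_rate = 0,
                  discordance_rate = 0, seed = 1)
res <- run_pipeline(cfg)
res$overlap$multiplicity
res$evaluation[c("precision", "recall")]
res$characteristics$total
```

With clean identifiers this recovers the planted design exactly: 99.9% of
unique patients in one site, 0.1% in two, three overlapping site pairs
with a 0.2% maximum, and precision = recall = 1. The same run with the
default 1% typo rate loses a fraction of the true cross-site pairs
(majority voting needs most slots to survive the typo) while keeping
precision at 1 — the conservative trade the matching rule is designed to
make.

## Known limitations

* Equal token weighting only; probabilistic (Fellegi–Sunter-style) scoring
  and per-token weights are out of scope.
* Blocking assumes token equality is the only match evidence; there is no
  similarity search over hashes (by construction — that is the privacy
  model).
* The union-find is plain R; populations far beyond 10^5 records per run
  would warrant a compiled implementation.
* Token byte-compatibility with any proprietary tokenizer is a non-goal;
  the keys, cipher and formats are this package's own documented
  conventions.
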