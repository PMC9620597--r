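# pprlink

Privacy-preserving record linkage (PPRL) with hashed tokens, for
distributed health data networks.

## The problem

Research networks that pool electronic health records across many
institutions need to know when records at different sites belong to the
same patient — to de-duplicate counts, to measure cross-site overlap, and
eventually to assemble complete patient histories — but no site may share
names, dates of birth or social security numbers. `pprlink` implements the
token-based solution to this problem end to end, for informaticians and
coordinating-center analysts who want a transparent, fully inspectable
implementation they can run on synthetic or real extracts.

## The method

Each record's identifiers are normalized (case, punctuation, date format,
digit-only SSN/zip) and reduced to six **tokens**, each the keyed hash

&nbsp;&nbsp;&nbsp;&nbsp;*t*<sub>*i*</sub> = HMAC-SHA-256(salt, *f*<sub>*i*,1</sub> | *f*<sub>*i*,2</sub> | …)

of a fixed combination of fields (e.g. token 1 = last name | first initial
| gender | date of birth; token 2 uses soundex-coded names so *Jon* and
*John* agree; tokens 5–6 use the SSN). A missing constituent makes the
whole token missing. The salted hash is irreversible; the shared master
salt makes it comparable across sites. Tokens then move through three
deterministic encryption schemes — site-specific, transit, and the
coordinating center's common scheme — so that linkage is possible only at
the center.

Two records **match** when, among token slots present in both, strictly
more than half are equal; matched pairs are clustered into master patient
ids by transitive closure (union-find over exact-token blocking, proven
equivalent to all-pairs comparison in the test suite). The resulting
**Match Index** is stripped of tokens before it crosses to the analysis
side, which computes site-overlap statistics and an aggregated vs
de-duplicated demographics table with discordance adjudication. A
synthetic multi-site population generator with known ground truth makes
the whole pipeline testable without any real data.

## Worked example

```r
library(pprlink)

cfg <- sim_config(typo_rate = 0, dob_error_rate = 0,
                  discordance_rate = 0, seed = 1)   # clean identifiers
res <- run_pipeline(cfg)   # simulate -> tokenize -> transform -> match
                           # -> strip -> overlap -> table -> evaluate

res$overlap$multiplicity
#>   sites    n  pct
#> 1     1 8383 99.9
#> 2     2    8  0.1
#> 3     3    0  0.0
#> 4   >=4    0  0.0

res$overlap$pairwise$pairs[, c("site1","site2","overlap",
                               "pct_of_site1","pct_of_site2")]
#>   site1 site2 overlap pct_of_site1 pct_of_site2
#> 1   DM1   DM2       5          0.2          0.2
#> 2   DM1   DM3       2          0.1          0.1
#> 3   DM1   DM4       0          0.0          0.0
#> 4   DM2   DM3       0          0.0          0.0
#> 5   DM2   DM4       1          0.0          0.1
#> 6   DM3   DM4       0          0.0          0.0

res$evaluation[c("precision", "recall")]   # against planted ground truth
#> $precision
#> [1] 1
#> $recall
#> [1] 1

res$characteristics$total
#>   aggregated_n deduplicated_n
#> 1         8400           8391
res$characteristics$reduction_pct
#> [1] 0.11
```

Reading: of 8,400 records at four sites, 8,391 unique patients remain
after linkage (a 0.11% reduction); 99.9% of patients appear at one site
and 0.1% at two; three of six site pairs share patients, the largest
overlap being 0.2% of a site's patient count — and with clean identifiers
the de-identified tokens recover the planted truth perfectly. The
percent-reduction formatter reproduces published worked arithmetic
exactly: `percent_reduction(3111792, 3108515, "round", 2)` is `0.11` and
`percent_reduction(198, 163, "truncate", 1)` is `17.6`.

A command-line pipeline with the same functionality (subcommands `keygen`,
`simulate`, `tokenize`, `transform`, `match`, `strip`, `overlap`, `table`,
`evaluate`, with the analysis-side subcommands refusing token-bearing
files) is installed at `system.file("exec", "pprl", package = "pprlink")`.

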