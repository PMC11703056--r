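# hdlomop

German statutory health-insurance claims data is delivered by the Health Data
Lab (HDL) in table layouts that changed across the years: **Format 1**
(2009–2016; Format 2 of 2017–2018 is structurally identical) consists of 9
tables keyed by a long-term person pseudonym `psid` and a year/insurer
pseudonym `vsid`; **Format 3** (2019 onwards) spans four schemas — insured
person, drugs, ambulatory incl. dental, inpatient — with schema-specific case
IDs. `hdlomop` transforms both into the **OMOP Common Data Model v5.4** so
that one analysis, and the OHDSI tool ecosystem, can be used regardless of
the delivery format. It is aimed at claims-data engineers and
health-services researchers who need a tested, reproducible ETL plus the
evidence that it worked.

The package ships four things:

1. **Source models** — typed schemas, CSV readers/writers and validators for
   both formats (`read_source()`, `validate_source()`).
2. **A deterministic synthetic generator** (`generate_format1()`,
   `generate_format3()`) emulating the structure of the HDL example data
   (which is itself random and unrealistic), so everything is testable
   without data access.
3. **The ETL** (`run_format1()`, `run_format3()`, `run_pipeline()`): surrogate
   keys with `psid`/`vsid` lookup registries, vague-date imputation (first
   day of the known period; `+1` day per inpatient case enumerator to keep
   case order; December 31st for year-only deaths; 29-day drug-exposure
   intervals), observation-period derivation with union-merging, and domain
   routing — each coded event lands in the table its standard concept's
   domain dictates, with one event per "Maps to" target and a concept-0
   fallback so nothing is dropped. PZN drug codes have no public RxNorm
   mapping and always keep concept 0 with the PZN as source value.
4. **Quality assessment** (`field_coverage()`, `mapping_coverage()`,
   `run_checks()`): the ledger-based field-coverage ratio
   `transformed / (transformed + untransformable)`, an Achilles-style
   per-domain mapping-coverage table, and a DQD-style catalog of
   conformance/completeness checks (plausibility is a toggle, off by
   default).

A bundled micro-fixture vocabulary (ATHENA export dialect, OHDSI custom
concepts in the 2&nbsp;000&nbsp;000&nbsp;000+ range) stands in for the full
ATHENA download, which is supported as input but never required.

## Worked example

```r
library(hdlomop)
res <- run_pipeline(list(
  seed = 7, out_dir = "readme_run",
  formats = list(list(format_id = 1, years = c(2009, 2010), n_persons = 50))))

res$dbs$format1
#> <cdm_database>
#>   person                       50 rows
#>   observation_period           50 rows
#>   visit_occurrence            396 rows
#>   condition_occurrence        382 rows
#>   ...
res$reports$format1
#> <quality_report>
#>   field coverage format 1: 92.68% (38/41)
#>   checks: 89 (3 failed)
```

50 persons over two reported years stay 50 person rows (the `psid` lookup
updates them in place) with one merged two-year observation period each.
The coverage table shows the structure the source forces on the result:

```r
res$reports$format1$mapping_coverage
#>               domain codes_source codes_mapped pct_codes records_mapped pct_records
#> 1          Condition           58            9      15.5             78        20.4
#> 3               Drug          211            0       0.0              0         0.0
#> 8              Visit            3            2      66.7            299        75.5
```

Condition coverage is low because the generator, like the HDL example data,
draws mostly fictional ICD-10-GM codes; Drug is 0% because no public
PZN→RxNorm mapping exists; Visit has three source codes (two inpatient
visit types plus the obligatory `"0"` filler on outpatient rows), two of
them mapped. The check totals separate verification from validation context:

```r
res$reports$format1$totals
#>       category      context pass fail total pct_pass
#> 1  Conformance Verification   68    0    68    100.0
#> 2 Completeness Verification   10    3    13     76.9
#> 4  Conformance   Validation    4    0     4    100.0
```

The three completeness failures are exactly the expected ones (unmapped
PZN drugs, the visit `"0"` concepts, condition concept-0 saturation from the
fictional codes); conformance is clean.

A thin CLI wrapping the same functions is installed at
`system.file("cli", "hdlomop", package = "hdlomop")` with subcommands
`synth`, `etl`, `qa`, `all` (YAML config) and `union`.

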