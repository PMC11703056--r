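---
title: "Transforming German claims-data formats into the OMOP CDM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transforming German claims-data formats into the OMOP CDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdlomop)
```

## The problem

German statutory health-insurance claims data is delivered by the Health Data
Lab (HDL) in format generations that changed over time: Format 1 (2009–2016,
structurally identical to Format 2 of 2017–2018) is a set of 9 flat tables
keyed by a long-term person pseudonym (`psid`) and a year- and
insurer-dependent pseudonym (`vsid`); Format 3 (2019 onwards) is much wider
and organised into four schemas (insured person, drugs, ambulatory including
dental, inpatient) with additional schema-specific case IDs. Longitudinal
research across format generations, and any network research at all, needs a
common representation. This package transforms both formats into the OMOP
Common Data Model v5.4, the person-centred, domain-oriented model maintained
by the OHDSI community, and ships the quality-assessment layer used to judge
the result: field coverage, concept-mapping coverage, and a
conformance/completeness/plausibility check catalog.

Because real HDL data is not publicly accessible, everything here is
developed and tested against synthetic data whose structure mirrors the HDL
example deliveries (see *The synthetic generator* below).

## The transformation model

**Persons and keys.** Source pseudonyms do not conform to OMOP's integer-key
convention, so every table gets monotone integer surrogate keys. The `psid`
is stored as `person_source_value` and used as a lookup key: a person
reappearing in a later reported year is updated in place, never duplicated.
The `vsid` keys the payer plan period — the one table whose identity comes
straight from the source. The OMOP person table supports only binary
genders; any other gender code maps to concept 0 with the original retained
as source value.

**Dates.** Format 1 dates are vague: outpatient diagnoses carry a quarter,
inpatient diagnoses a discharge month plus a case enumerator, prescriptions a
day, everything else just the year. The package represents this explicitly
(`vague_date()`) and imputes with the first day of the most precise known
period (`impute_date()`). Two exceptions follow OHDSI guidance: inpatient
cases add one day per following case enumerator so the order of cases
survives imputation (`impute_case_date()`), and a year-only death is dated
December 31st (`death_date()`). The case offset is deliberately unbounded —
case 95 of a quarter lands outside the quarter — and surfaces in the
plausibility checks rather than being clipped, since clipping would destroy
the ordering the offset exists to preserve. Format 3 dates follow a
precision cascade (exact day, else first day of the quarter, else January
1st); whenever a day-precise date exists it is used exactly. For a death in
Format 3 the delivered day is used; if only a quarter is known the *last*
day of that quarter steps in, consistent with the year-end rule.

**Observation and payer periods.** Coverage start/end dates are not
delivered in Format 1, so each person is assumed insured for the whole
reported year, and each insurance relationship (vsid) gets a one-year payer
plan period. In Format 3 the insured-quarter rows narrow the observation
period to the first-seen through last-seen quarter, with interior quarters
assumed covered. Periods that overlap or touch (gap of at most one day) are
merged into their union, so observation periods per person never overlap —
including the corner of multi-insurance persons, where one period per
insurance would otherwise overlap; the merge resolves that conflict in
favour of the non-overlap constraint.

**Domain routing.** Clinical facts are represented by standard concepts; the
domain of the standard concept, not the source table, decides the target
table. An ICD-10-GM code may map to a condition, procedure, observation or
measurement; an OPS code additionally to a drug. `route_event()` emits one
event per "Maps to" target and — crucially — exactly one concept-0 event in
the context's default table when no mapping exists, so no source event is
ever dropped. The default table preserves the source's own categorisation
(diagnoses → condition, OPS → procedure, drugs → drug exposure), which is
why unmapped codes still appear inside their source domain in the coverage
tables.

**Codes without public mappings.** PZN (German drug identifiers) have no
public mapping to RxNorm; drug exposures therefore carry concept 0 with the
PZN as source value and the OHDSI 29-day convention for the exposure end.
UAS tariff numbers are handled through a pluggable mapping CSV (empty by
default) so an external tariff-to-procedure mapping can be dropped in
without code changes. ICD-10-GM special characters (dagger, asterisk,
exclamation mark) and localisation letters are stripped before lookup and
kept as source value (`normalize_icd_gm()`); dental teeth positions have no
standard-concept representation at all and are accepted as lost —
they are two of the "untransformable" fields in the ledger.

**Local concepts.** Source categories without any medical coding system —
specialist categories, disease management programs, the five dental service
groups, visit and diagnosis-status categories, day-count claims — are mapped
through a Usagi-style CSV of hand-curated mappings (only `APPROVED` rows are
registered). Custom concepts live in the 2,000,000,000+ range per OHDSI
convention. The bundled vocabulary is a pinned micro-fixture: a few dozen
concepts covering every routing situation the ETL can encounter (all four
ICD event domains, OPS→Drug, a dual mapping, visit and status concepts). A
full ATHENA download in its export dialect is accepted as a drop-in
replacement but never required.

**Costs.** The OMOP cost table is tailored to the US system, so only a
minimal, well-defined subset is populated: an amount, a cost-type concept
(e.g. dental claim, hospital case payment, the three-way pharmacy split into
paid-by-patient / total costs / total charge), the payer-plan-period link,
and an event link where one exists. Format 1 expenditures are account-level
and link only to the insurance period. US-specific columns stay empty.

## The field ledger

Every non-key source field is classified as *transformed*, *intentionally
omitted* (administrative noise, checksums, empty placeholders, or detail
dropped in favour of other detail), or *untransformable* (intended for
retention but without a viable CDM target). Field coverage is
`transformed / (transformed + untransformable)`:

```{r}
field_coverage(make_ledger_fixture(1), 1)   # 38 / (38 + 3)
field_coverage(make_ledger_fixture(3), 3)   # 100 / (100 + 16)
```

The ledger is generated from the same schema tables the ETL reads its input
through (`etl_consumed_fields()`), so the ledger cannot silently drift from
the implementation; a test asserts the two sets are identical. The HDL's
full data dictionaries are not public, so field names beyond the published
ones (psid, vsid, icd_zusatz, lokalisation, versichertentage, khdiag, fa,
aufnfa, the tsvg\* block, zahn, refart, wirkstoffvo, abrvondat/abrbisdat,
versstatus, inansprartamb, zweitmein, qualifizierung) are documented
German-claims-style placeholders; the classification counts are fixed by the
package data dictionary at 38/4/3 and 100/40/16, with intentional omissions
split 19 administrative, 12 dropped-in-favour, 5 no-added-value, 4 empty,
and `zahn` is carried by two dental tables, which is why 16
untransformable entries cover 15 distinct field names.

## The synthetic generator

The generator emulates the HDL *example* data — which is itself randomly
generated and free of realistic distributions — not German epidemiology.
What passing tests show is therefore structural correctness (keys, case
linkage, date precision, routing, conservation, determinism), not clinical
plausibility; real-data properties such as realistic code frequencies,
seasonal patterns, or consistent death/activity sequences are out of reach
by construction.

Defaults are fixed once to mirror the example data's structure:

* Format 1: mean 3 inpatient diagnosis rows and 1 outpatient diagnosis row
  per person-year (the 3:1 ratio behind the 75% visit-record coverage), 2
  prescriptions, invalid-ICD fraction 0.8 (the example data consists mostly
  of artificially created codes; with the 11-code mapped pool and 49-code
  invalid pool this yields the characteristically low condition coverage),
  outpatient rows carry no visit-type code so their obligatory visit-concept
  field gets "0".
* Format 3: invalid-ICD fraction 0.002 (condition coverage near 100%),
  mapped-OPS row fraction 0.3 over a 5-mapped/220-invalid pool (procedure
  records ≈ 30% mapped, codes ≈ 2%), missing-optional-date fraction 0.2
  ("mostly day-precise"), mapped-specialty row fraction 0.52 over a
  13-mapped/4-unmapped pool.
* Both: 10% multi-insurance persons, 2% deaths per year, Poisson row counts.

Determinism: every table draws from its own stream seeded by `(seed, table,
year)`, so adding a table never perturbs another, and a fixed seed gives
byte-identical CSVs. Person demographics are drawn from a year-independent
stream so a psid keeps its birth year and gender across reported years.

## Quality assessment

`run_checks()` is a compact reimplementation of the Data Quality Dashboard's
check *semantics*, not its 4000+ check instances: ~70 named checks across
primary-key uniqueness, foreign-key resolution, concept existence,
standard-concept flags, domain/table agreement, date ordering,
observation-period non-overlap (Conformance); concept-0 saturation per
concept field (default threshold 5%, a DQD convention) and expected-table
population (Completeness); source-coverage checks that need the original
dataset (Validation context); and a plausibility section (event inside an
observation period, event within a week of its visit, birth before death)
that is off by default — on randomly generated data plausibility carries no
signal, which is exactly why it is a toggle. On anomaly-free synthetic
input every conformance check passes; completeness checks fail exactly where
the source makes them fail (PZN drugs at 0% mapped, the visit-type "0"
filler, unmapped OPS/UAS procedures) — those failures are information, not
defects.

`mapping_coverage()` reproduces the Achilles-style coverage table: per
domain, distinct source codes and total records, each split into mapped
(assigned concept ≠ 0) and unmapped. Percentages are rounded half-up to one
decimal. Domains are defined by CDM location (condition, condition status,
drug, measurement, observation, procedure, provider specialty, visit), with
provider specialty counted over provider rows.

## Numerical and interface choices

* CSV dialect fixed everywhere: UTF-8, comma, quoted fields, header row,
  ISO-8601 dates, empty string = absent. Round trips are lossless and
  byte-deterministic (rows ordered by primary key on write).
* The reported year always comes from configuration, never from the rows.
* Re-loading the same reported year twice is out of contract: persons would
  deduplicate but events would duplicate. The pipeline refuses duplicate
  years at configuration time, before any work is done.
* Temporary visit keys — needed because the diagnosis tables have no primary
  keys of their own — exist only in memory and are dropped before writing.
* The union step for combining the two per-format CDMs offsets the second
  run's surrogate keys by the first run's counters and merges persons that
  share a psid (a long-term pseudonym, stable across formats). Tests verify
  key uniqueness and zero dangling references after the union.
* Problem sizes: worked examples run on hand-built one-person datasets; the
  property suites and the acceptance script use 1,000 persons per format
  (two reported years for Format 1) — large enough that every code-pool
  element and routing branch is exercised, small enough for a desk run.

## Worked example

```{r, eval = FALSE}
res <- run_pipeline(list(
  seed = 7, out_dir = "run",
  formats = list(list(format_id = 1, years = c(2009, 2010), n_persons = 200),
                 list(format_id = 3, years = 2019, n_persons = 200))))
res$reports$format1$mapping_coverage
res$reports$format1$totals
```

## Known limitations

* The schemas are a reconstruction of the ETL-relevant subset of the HDL
  dictionaries, not the full 83/217-column inventories.
* The bundled vocabulary is a desk-scale fixture; coverage percentages on
  synthetic data characterise the pipeline, not German claims reality.
* Format 3 condition-code coverage counts distinct *source values*, which
  include special-character and localisation variants; a handful of invalid
  codes therefore depresses the distinct-code percentage more than the
  record percentage.
* Dental teeth positions, TSVG details, admitted-department codes and the
  other untransformable fields are read, counted, and dropped — the ledger
  documents each with its reason.
* Dates are never extracted from related events; only period-start
  imputation is used.
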