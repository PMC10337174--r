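---
title: "Methods: validating IPF case-finding across linked EHR sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating IPF case-finding across linked EHR sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfvalid)
```

## The validation design

Idiopathic pulmonary fibrosis is mostly diagnosed in secondary care, so a
primary-care code list alone may mislabel other fibrotic lung disease as
IPF, or miss cases never coded by the GP. The package implements a
three-source validation design: patients are identified in a primary-care
event stream, in hospital admitted-patient-care spells, and in death
registrations, and the death certificate serves as the reference standard.
The design rests on one central assumption — that a person with an IPF code
on their death certificate very likely carried a true IPF diagnosis in
life. Because the reference is a death record, every validation quantity
conditions on death: cohorts are restricted to study-eligible decedents.

### Eligibility and follow-up

A patient contributes usable follow-up from the latest of: the study start
(default 2008-01-01), the IPF diagnosis date (the earliest qualifying
primary-care code, when one exists), the start of the current practice
registration, and the 18th birthday; until the earliest of: the study end
(default 2018-12-31), death, the practice's last collection date, and
transfer out. A window exists when it contains at least one calendar day,
start-day inclusive (`start <= end`) — the minimal reading of a "1 day"
usable-follow-up requirement. 29 February birthdays roll to 1 March in
non-leap years. Patients found only in hospital or death data have no
diagnosis term in the window; their cohort-specific index date is the first
qualifying admission.

One boundary behaviour worth noting: eligibility requires adulthood *at
the study start*, so moving the study start later simultaneously shrinks
every follow-up window and relaxes the age clause. Window shrinkage alone
can never make a patient newly eligible, but the age clause can; the
property tests state monotonicity accordingly.

### The eight algorithms

All algorithms are Boolean conjunctions (no scoring) over four predicates:

| id  | code set | hospitalisation | thoracic CT | no other ILD cause |
|-----|----------|-----------------|-------------|--------------------|
| DA1 | broad    |                 |             |                    |
| DA2 | broad    |                 | yes         | yes                |
| DA3 | narrow   |                 |             |                    |
| DA4 | narrow   |                 | yes         | yes                |
| DA5 | —        | yes             |             |                    |
| DA6 | —        | yes             | yes         |                    |
| DA7 | broad    | yes             |             |                    |
| DA8 | narrow   | yes             |             |                    |

*Code sets.* Rated codelists drive the primary-care predicates: the narrow
subset is the codes rated "yes" (strongly indicative of IPF), the broad
subset adds the "maybe" codes (pulmonary fibrosis of unspecified
aetiology); "no"-rated codes are never matchable, so narrow ⊆ broad by
construction. Primary-care codes are opaque identifiers — no terminology
hierarchy is traversed, because the case definitions match flat lists.

*Hospitalisation.* An admission qualifies when any episode of the spell
carries one of the ICD-10 codes J84.1, J84.8, J84.9 at an admissible
diagnostic position. The base rule admits positions 1–2, where coding
accuracy is highest; the sensitivity-analysis rule admits positions 1–3.
ICD-10 matching is prefix-based after dot-stripping and upper-casing, so
4th/5th-character subdivisions of a listed code qualify (national hospital
data carry such subdivisions; exact-only matching is available via a flag).
Admissions must fall inside the follow-up window; this applies equally to
the standalone hospital algorithms (DA5/DA6) and to the conjunctions
(DA7/DA8), by symmetry.

*Thoracic CT.* The imaging source records modality and body region but not
resolution, so any CT of the thorax, at any time (even after death),
satisfies the high-resolution-CT criterion. No date restriction is applied
— the imaging dataset's coverage starts later than the study (2012), which
is a documented limitation rather than a modelled one.

*Exclusions.* The "no other known cause of ILD" conjunct fails when any
primary-care event, at any date, matches the exclusion codelist
(connective tissue disease, sarcoidosis, environmental exposures, drug
toxicity, other non-IPF ILD).

### Validation quantities

With the cohort restricted to eligible decedents, an algorithm's PPV is
`n_true / n_found` and its sensitivity `n_true / n_gold`, where `n_gold`
counts all decedents with IPF on the certificate — one shared denominator
across algorithms, so sensitivities are comparable. Two gold-standard modes
exist: IPF *anywhere* on the certificate (default) and IPF as the
*underlying* cause only; switching to the stricter mode can only shrink
`n_true` and `n_gold`. An algorithm that finds nobody yields an `NA` PPV
rather than an error.

Confidence intervals are Wilson score intervals. The choice is the
package's own: the score interval has good coverage at proportions near the
boundaries and needs no continuity fudge; its bounds are clipped to
[0, 1]. (On the shipped fixture the Wilson bounds agree with the published
intervals to about one unit in the last printed decimal, but interval
bounds are not treated as reproduction targets since the original method
is unstated.)

Concordance partitions the union of the three deceased cohorts into seven
exclusive regions. Membership follows the analysis conventions: the
primary-care cohort admits a code recorded up to 60 days *after* death
(certificate-triggered coding), the hospital cohort requires the admission
inside the follow-up window, and deaths must fall inside the study period.
The 60-day grace applies only here, never to follow-up windows or to the
per-algorithm validation. `derive_pairwise_from_marginals()` recovers the
one pairwise overlap a three-set summary usually leaves unprinted
(primary-care ∩ hospital) by inclusion–exclusion, rejecting any input set
of marginals that would force a negative region.

## The synthetic data sources

### Stochastic generator

`generate_cohort()` draws a decedent cohort of "possible IPF" patients:
a latent true-IPF label (`p_true_ipf`), imperfect primary-care coding
(`p_gp_broad_given_ipf`, `p_gp_broad_given_not`, with a narrow code layered
on broad with probability `p_narrow_given_broad`), imperfect hospital
recording (`p_hosp_given_*`, with the IPF code relegated to diagnostic
position 3 with probability `p_position3_only`), thoracic CT and
other-ILD-code flags, and a certificate process in which true cases carry
IPF with probability `p_death_cert_given_ipf`, placed as underlying cause
with probability `p_underlying_given_cert`. Non-cases never receive
certificate IPF codes; that convention keeps the expected PPV closed form,

$$\mathrm{PPV} \;=\; \frac{p_{\mathrm{true}}\; p_{\mathrm{code|IPF}}\;
p_{\mathrm{cert}}}{p_{\mathrm{true}}\; p_{\mathrm{code|IPF}} +
(1-p_{\mathrm{true}})\; p_{\mathrm{code|\neg IPF}}},$$

which `expected_ppv()` returns and the recovery tests compare against the
pipeline's empirical PPV (within three Monte-Carlo standard errors at
50,000 patients; the tests run twenty random configurations and require at
least nineteen recoveries). Certificate false positives can still be
studied by labelling such patients "true" at generation.

The default parameters describe a plausible decedent IPF-suspect
population: prevalence of true IPF 0.65 among the generated suspects,
broad-coding sensitivity 0.60 and false-coding rate 0.35, certificate
sensitivity 0.85 with 0.62 of certificate codes underlying, hospital
admission probabilities 0.65/0.30, narrow-coding share 0.19. These were
chosen once, to land the implied PPV in the mid-60s per cent and the
underlying-cause share near three-fifths — the regime the validation
literature reports for IPF — and are not tuned thereafter.

Code *identity* (not presence) follows per-year multinomial weights,
`default_code_drift()`: the weights interpolate linearly between a 2008
profile dominated by older terms (fibrosing alveolitis, diffuse pulmonary
fibrosis) and a 2018 profile dominated by IPF-specific terms, emulating the
documented drift in GP coding behaviour. The trend report
`code_usage_by_year()` recovers this drift from generated data.

What the generator does **not** emulate: correlated comorbidity structure
(comorbidity codes are independent per patient), multiple registration
periods, regional or practice-level clustering, survivors (every generated
patient dies in-window), and certificate miscoding of non-cases. Tests that
pass on generated data therefore demonstrate the pipeline's arithmetic and
its statistical calibration under the stated model — not robustness to
real-world linkage error or informative censoring.

### Deterministic fixture

`build_fixture()` constructs a patient-level dataset whose *marginal*
counts equal a published worked example exactly: the seven-region
concordance partition (derived from the printed totals by
inclusion–exclusion), each algorithm's found/confirmed counts, the
underlying-cause restriction, and the top-3-position augmentation of the
hospital cohort. The allocation of narrow/CT/underlying flags within
regions is solved in closed form from the printed marginals; where slack
remains, it is resolved greedily and deterministically (the
most-constrained region is saturated first). Any recipe that forces a
negative region or exceeds a region's capacity raises an infeasibility
error naming the violated quantity. Determinism is for test stability —
any allocation satisfying the marginals would reproduce the targets, since
every target depends only on marginal counts.

Two fixture choices deserve note. First, the published tables pin no count
involving the other-ILD exclusion codes, so the fixture assigns none and
the DA2/DA4 counts are carried entirely by the CT flag; the exclusion
predicate is exercised by the generator and unit tests instead. Second,
the hospital cohort's top-3-position variant is reported with its
death-record overlap share; the fixture realises that share by giving part
of the certificate-only region an additional position-3 admission and
creating the remainder as new patients with no primary-care or certificate
IPF record. Fixture dates are schematic (registration 2000, codes 2010,
admissions 2012–2013, all deaths mid-2015): no published target depends on
date arithmetic, and date logic is the generator's job.

## Numerical and reporting conventions

* Dates are ISO-8601 calendar dates; all comparisons are closed
  calendar-date comparisons, no times.
* Input tables are header-first delimited text; the delimiter (tab or
  comma) is sniffed from the header line. Canonical comma-delimited files
  round-trip byte-identically.
* Percentages are reported to one decimal, rounding half away from zero
  (`round_half_away()`), matching the convention of the source tables.
  Note that a table published with ordinary rounding can disagree with its
  own printed counts by one unit in the last decimal; the package always
  reports the count-derived value.
* Ties in "closest smoking record at or before index" resolve to the later
  record (last in table order on equal dates); comorbidity look-back is
  strict (`< index`); age is completed years at index.
* Cause-of-death rankings break ties lexicographically on the canonical
  ICD-10 code.
* `stats::IQR()` (type-7 quantiles) supplies interquartile ranges.

## Problem sizes used in the tests

The bundled suite runs the fixture (19,665 patients) once for the
worked-example checks, and the generator at 1,500–5,000 patients for
structural properties, 30,000 for the coding-drift trend, and twenty
configurations of 50,000 for PPV recovery. These sizes make the
Monte-Carlo bands tight enough for three-standard-error assertions while
keeping the whole suite in the low minutes on a single core.

## Known limitations

* The death certificate is an imperfect gold standard: IPF deaths without
  certificate mention depress measured PPV, and the package (like the
  design it implements) cannot estimate specificity or NPV without
  IPF-free controls.
* Thoracic CT evidence cannot distinguish high-resolution protocols, and
  no coverage-era restriction is applied to imaging data.
* Only one registration period per patient is modelled.
* The fixture reproduces marginal counts, not joint patient-level
  structure; analyses of interactions the published tables do not pin
  (e.g. CT-by-underlying-cause cross-tabulations) are meaningful only on
  generator output.
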