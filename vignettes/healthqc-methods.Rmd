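---
title: "Methods: quality control and semantic enrichment of tabular health data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and semantic enrichment of tabular health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthqc)
```

## Scope and rationale

Multimodal health datasets — clinical pathology, epidemiology, mutation
panels, treatment records — arrive as rectangular patient-by-variable
tables with heterogeneous missing-value encodings, free-text fields,
logically dependent variable pairs, and categorical values that block
numeric analysis. healthqc implements a quality-control workflow
(standardise missingness, profile completeness, flag zero-entropy
variables, check internal consistency, evaluate variable merging,
encode everything numerically, and review what changed) followed by an
optional semantic-enrichment step that uses an ontology to aggregate
semantically related variables into meta-variables.

The container is a `health_table`: a data frame of raw cells plus a
record-identifier column and per-variable metadata. The canonical
missing marker is R's `NA` — an out-of-band sentinel, so the literal
string `"NA"` remains representable as a category label; serialisation
writes the marker as `"NA"`.

## Information-theoretic measures

All measures use log base 2 (bits) and are computed on complete cases;
missing values never contribute probability mass.

* **Entropy** $H(X) = -\sum_c p_c \log_2 p_c$ over the distinct
  non-missing values, with empirical probabilities. Zero iff the
  variable takes at most one distinct value — the criterion behind
  zero-entropy flagging.
* **Information content** $IC(X) = -\sum_i \log_2 p(x_i)$, summed over
  elements rather than distinct values, so $IC(X) = n\,H(X)$ exactly.
* **Mutual information content** $MIC(X,Y) = MI(X;Y) \times n$ with
  $n$ the number of complete cases. MIC has units of bits summed over
  observations, the same scale as IC, which is what makes the
  merge-loss comparison below well defined. We retain this printed
  definition rather than a per-observation variant.
* **Symmetric uncertainty**
  $SU(X,Y) = 2\,(H(X)+H(Y)-H(X,Y))/(H(X)+H(Y))$, in $[0,1]$, with the
  convention $SU = 0$ when $H(X)+H(Y)=0$ (two constants share no
  information worth calling redundant).
* **Min–max normalisation**
  $X_{norm} = (X-\min X)/(\max X - \min X)$; constant vectors are an
  error, because the rescaling is undefined, and callers may skip
  normalisation for them.

For continuous variables, information content is estimated with a
Gaussian kernel density estimator with adaptive per-point bandwidths:
a Silverman pilot bandwidth
$h_0 = 0.9 \min(s, IQR/1.34)\, n^{-1/5}$, Abramson local factors
$\lambda_j = (\hat f_0(x_j)/g)^{-1/2}$ (geometric mean $g$, sensitivity
$\alpha = 0.5$), and densities floored at $10^{-12}$ before logs. With
1,000 standard-normal draws this estimator reproduces the plug-in value
from the true density within a few parts per thousand, and it shifts by
exactly $n \log_2 s$ under rescaling by $s$, as the change-of-variables
identity requires. At least 5 observations are required; constant
vectors are rejected as degenerate.

Mutual information between vectors with a continuous component is a
plug-in estimate after equal-frequency discretisation into
$\min(10, \lfloor\sqrt{n}\rfloor)$ bins. This is a declared estimator
choice: the plug-in MI of discretised data carries a positive bias of
roughly $(r-1)(c-1)/(2n\ln 2)$ bits under independence, which is why
the package's tests treat continuous MI comparatively rather than
against exact values. No bias-corrected or k-NN estimators are
provided.

## Merge-loss evaluation

A merge specification maps every observed combination of input values
to a merged value (unmapped observed combinations are an error, not a
silent `NA`). On the records complete across all inputs, an input is
retained losslessly iff its MIC with the merged variable equals its IC,
tested at an absolute tolerance of `1e-9` bits — MIC equals
$n\,H(X) = IC(X)$ exactly when the input is a deterministic function of
the merged variable, and falls strictly below otherwise. The package's
tests verify this equivalence against a brute-force recoverability
oracle over randomised merge specifications.

## Quality-control conventions

* **Missing-value standardisation** matches string encodings exactly
  but case-insensitively ("Unknown"/"unknown" variants are pervasive),
  and numeric encodings after numeric parse (`"-1"` matches `"-1.0"`).
  It is idempotent.
* **Consistency rules** either compare two numeric variables with an
  operator, or constrain variable B's values (category set or inclusive
  `lo:hi` range) given a boundary condition on variable A. Records with
  a missing operand are skipped — a missing value is unproven, not
  inconsistent — and findings are deduplicated per (record, rule).
* **Completeness matrices** encode non-numeric cells by the count of
  distinct values in their variable, replace missing cells with a
  distant value (default twice the largest absolute encoded value plus
  two), and order rows and columns by single-linkage hierarchical
  clustering of Euclidean distances, which makes blocks of co-missing
  variables adjacent.
* **Zero-entropy flagging** includes all-missing variables: they
  stratify nothing either way.
* **Type inference** is deliberately conservative: numeric parse, then
  a two-level test, then a free-text test (mean whitespace-token count
  above 3), then multi-level nominal. Ordinal types are never inferred
  because level order is domain knowledge; user review is a mandatory
  step, and overrides are validated for level coverage. The
  `max_levels_nominal = 10` default only drives a review warning.
* **Encoding**: ordinals become 1-based level positions; binaries 0/1;
  multi-level nominals one-hot with a `<variable>_NA` indicator
  whenever missingness exists (and only then); frequency encoding ranks
  labels by descending cohort count with lexicographic tie-breaks
  (determinism over elegance). Labels and codes are preserved in a
  mapping reference table so encodings stay reversible.
* **Free text**: lowercase, strip punctuation, drop stopwords (a
  vendored English snapshot; no network), optionally apply a
  user-supplied fixed-string substitution table (abbreviations,
  misspellings — automatic spelling correction is out of scope). Terms
  are unigrams plus, for `ngram_length = 2` and `skip_window = 1`
  (defaults), skipgrams joining tokens at most one position apart.
  Terms must occur in at least 2 records to become indicator
  variables; records without text get missing indicators.
* **Review** classifies each compared cell as unchanged, substitution,
  removal or addition — a partition, so per-record percentages sum
  to 100. Numbers are compared after formatting to 12 significant
  digits so float noise never counts as a substitution. Variables
  present in only one table are reported by the variable diff, not as
  cell modifications.

## Semantic enrichment

The ontology is consumed as a child→parent edge table (a DAG; multiple
roots allowed, cycles and self-loops rejected), plus a long-form
variable→entity mapping table. Mapped variables are attached as leaf
nodes. Negative-finding and missingness indicators should simply be
left unmapped: aggregating "no diabetes" alongside positive findings
would cancel information rather than add it.

Node specificity is scored by depth and relative descendant count:

$$IC(c) = k\left(1-\frac{\ln(hypo(c)+1)}{\ln N}\right) +
 (1-k)\,\frac{\ln(depth(c))}{\ln(depth_{max})}$$

with $hypo(c)$ the number of ontology descendants (variable nodes
excluded from both $hypo$ and $N$ — they are data, not knowledge),
$depth$ the longest root-to-node path in nodes (roots have depth 1;
under multiple parents the longest path is taken, as the more specific
reading), and $k = 0.5$ by default, exposed to the user. Roots score 0,
a childless node at maximal depth scores 1, and a single-node ontology
scores 0 by convention. On the five-node documentation tree
(R → A, B; A → C, D) the internal node A scores 0.4742.

Every ontology node's variable-descendant set is computed; sets with
at least two variables are grouped when identical, and each group is
labelled by its most informative common ancestor (MICA) — maximal IC,
ties broken by greater depth and then lexicographic id, again for
determinism. Each set yields five candidate meta-variables: row-wise
sum, minimum, maximum, average and product over the non-missing
constituent values (a record with all constituents missing stays
missing — which is why meta-variable completeness is never below the
best constituent's). Min–max normalisation of constituents first is
recommended whenever magnitudes differ; constant constituents are left
unnormalised with a warning rather than failing the whole set.
Candidates whose values are constant — equality judged after rounding
to 12 decimals, to keep float noise from simulating information — are
dropped before appending, so `candidates − dropped = appended` holds by
construction. The enrichment report includes a redundancy audit: the
symmetric uncertainty of each appended meta-variable with each of its
constituents, flagging fully redundant aggregations (typical for
two-variable 0/1 sets, where e.g. MIN and MULT collapse onto a
near-constant constituent).

## Synthetic data

`generate_cohort()` emulates the structure of a multimodal colorectal
cancer cohort: 661 records and 155 variables by default, spread over
clinical pathology (including a lymph-node staging trio generated
internally consistent), epidemiology with one free-text family-history
field present for 21% of records, a 19-variable three-level mutation
panel, and treatment/outcome variables; 8 distinct missing-value
encodings; modality-aligned rectangular blocks of true missingness plus
4% uniform missingness planted as encoding tokens; 40 inconsistencies
planted against the bundled lymph-node rules (constructed so exactly
one rule fires per planted record, and never planted into cells that
carry other defects); and 4 constant variables. Every planted defect is
recorded in a ledger, so recovery is asserted exactly, not
approximately. The generators are pure functions of their spec —
a fixed seed yields byte-identical output, and the caller's RNG stream
is left untouched.

What the generator does *not* emulate: realistic clinical marginal
distributions, correlated comorbidities, informative missingness beyond
block structure, misspelled free text, or the content of any real
ontology. Passing tests on this cohort therefore demonstrate that the
mechanics (counting, matching, recovery, encoding) are exact, not that
the defaults are tuned to any particular hospital's data.

Unit tests run the generator at 40–120 records and the exhaustive
information-theory checks over all vectors of length ≤ 6 on a 3-letter
alphabet (and all joint contingency tables of such pairs, which is the
exhaustive pair check up to position permutation); the acceptance
script additionally runs one full 661-record QC pass. These sizes keep
the whole suite near a minute while leaving every assertion exact.

## Known limitations

* No imputation, outlier detection, or record linkage; consistency
  checking is limited to the pairwise rule schema.
* Continuous MI/SU treat each distinct value as a category after
  binning; heavily continuous redundancy audits are approximate.
* Ontology reasoning is limited to is_a edge tables; OWL/RF2
  preprocessing happens upstream, and variable→ontology mapping is
  manual by design (automatic fuzzy mapping invites silent semantic
  errors).
* The free-text extractor is a deliberately small tokeniser: no
  stemming, lemmatisation, embeddings or clinical NER.
* Exact numeric agreement of node IC with other implementations is not
  claimed beyond the declared formula; all anchors in the tests are
  computed under it.
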