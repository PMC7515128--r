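---
title: "Predicting molecular recognition features with ensemble MLPs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting molecular recognition features with ensemble MLPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Molecular recognition features (MoRFs) are short segments — typically
10–70 consecutive residues — inside intrinsically disordered protein
regions that fold into a defined structure upon binding a partner.
Because they mediate signalling and recognition, locating them from
sequence alone is a long-standing per-residue classification problem.
`morfmlp` scores every residue of a protein for MoRF propensity from two
complementary information sources: the local physicochemical character
of the sequence, and the evolutionary conservation profile of the
position.

## Feature extraction

### Multi-window pooling

Both feature branches share one two-stage pooling scheme.  For a
sequence of length $L$ and a window size $N$, let $N_0 = \lfloor N/2
\rfloor$ and $L_0 = L + 2N_0$.  The per-position track (scale values, or
one PSSM row) is padded with $N_0$ zeros on each side; window $i$
($1 \le i \le L_0 - N + 1$) covers padded positions $i..i{+}N{-}1$ and
receives the mean track value over those positions, pads contributing
zero.  Residue $j$ (padded position $j + N_0$) is then assigned the mean
of all window values whose window covers it:

$$x_j = \operatorname{mean}\{\,v_i : \max(1,\, j+N_0-N+1) \le i \le
\min(j+N_0,\, L_0-N+1)\,\}.$$

Interior residues average exactly $N$ windows; residues within $N_0$ of
either end average the (fewer) windows that exist.  We implement this
single clamped-range formula rather than three separate edge/interior
branches: the printed piecewise forms are reproduced exactly by the
clamped range for the first two branches, and the clamped form is the
natural consistent reading of the third (its printed index bounds
simplify to the same window count).  For odd $N$ the number of windows
is exactly $L$; for even $N$ it is $L+1$, and the clamped pooling
handles both parities without special cases.

Three window sizes are used by default, $N \in \{10, 45, 90\}$: the
short window resolves the MoRF itself (MoRFs are short relative to their
disordered context), the longer two summarize the surrounding region.

### The 16 sequence properties

Fifteen properties are amino-acid scales — one real value per residue
type, averaged within windows — and the sixteenth is a windowed
**topological entropy**, a subword-complexity functional.  For a window
of length $N$ over alphabet size $A = 20$: take the largest $n \ge 1$
with $A^n + n - 1 \le N$ (when no such $n$ exists, i.e. $N < 20$, we
clamp to $n = 1$, the natural limit of the definition), set
$m = \min(A^n + n - 1, N)$, and score
$\log_A(\#\text{distinct } n\text{-mers in the first } m \text{
letters})/n$.  At the default window sizes this always resolves to
$n = 1$: a normalized count of distinct letters, low in low-complexity
(disorder-like) regions.  Pad characters at the sequence ends — and the
ambiguity placeholder X — count as symbols distinct from the 20 residue
letters, so terminal windows are not spuriously scored low-complexity by
letter collision; whether the original method padded entropy windows at
all is unstated, and this is our documented choice.

With 16 properties and 3 window sizes the property branch emits a 48-
dimensional feature vector per residue; the profile branch pools each of
the 20 PSSM rows the same way, giving 60 dimensions.

### Scale provenance

The original method names 13 physicochemical scales (in an appendix
table unavailable to us) plus the GlobPlot "Remark 465" and
Deleage/Roux disorder propensities.  The shipped scale file
(`inst/extdata/scales_default.txt`) therefore substitutes 13 documented
scales in the AAindex tradition (Kyte–Doolittle hydropathy, Hopp–Woods
hydrophilicity, Eisenberg consensus hydrophobicity, Grantham polarity,
Zimmerman pI/polarity/bulkiness, Klein net charge, Chou–Fasman
helix/sheet propensities, Bhaskaran–Ponnuswamy flexibility, Zamyatnin
volume, residue molecular weight) and two documented propensity
substitutes (TOP-IDP disorder propensity for Remark 465; Chou–Fasman
turn propensity for Deleage/Roux).  Every scale can be replaced at run
time with `--scales`, so restoring the original table requires no code
change.  Feature semantics (48 columns, entropy first, scales in file
order, grouped by window size) are unaffected by which 15 scales are
loaded.

### Degenerate inputs

Non-standard residues are canonicalized (B→D, Z→E, U→C, O→K; anything
else → X with a warning).  X keeps the sequence length — and hence label
alignment — intact; it contributes the scale's mean value to scale
windows, counts as its own symbol in entropy windows, and PSSM rows are
taken as the profile file provides them.  Sequences shorter than a
window are processed with a warning: the clamped pooling stays
well-defined, windows are simply pad-dominated.  All features are finite
for every canonical input, including $L = 1$.

## The classifier

Each branch trains a multi-layer perceptron with two ReLU hidden layers
and a sigmoid output (properties branch: 12+12 units, dropout keep
probability $p_d = 0.5$, learning rate $10^{-3}$; profile branch: 25+25
units, $p_d = 0.7$, learning rate $10^{-4}$).  During training each
hidden activation is multiplied by a Bernoulli($p_d$) mask.  We use
*inverted* dropout (kept activations scaled by $1/p_d$) so that
eval-mode needs no rescaling; the literal unscaled mask is available via
`inverted_dropout = FALSE`.  Dropout applies to hidden layers only,
never to the output unit.

Because MoRF residues are rare (a few percent of residues), training
uses a class-balanced subsample: all positive residues plus an equal
number of uniformly sampled negatives, mirroring the original protocol
of downsampling the negatives to the positive count.  Per-feature
z-score standardization statistics are fitted on this subsample and
stored in the model: the two branches' raw inputs (scale averages vs
integer log-odds) differ by orders of magnitude, and the source is
silent on normalization.

Training minimizes binary cross-entropy with Adam ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$), 200 epochs, batch size 128 —
the source states none of loss, epochs, batch size or initialization, so
these are package choices, fixed as defaults and exposed in
configuration.  Weights start from a He-style scaled-uniform draw
(appropriate for ReLU).  Five members are trained per branch with
derived seeds (master seed $+0..4$ controlling initialization, dropout
masks and batch order); the ensemble score is the arithmetic member
mean.  Everything downstream of a master seed is reproducible
bit-for-bit.

## Score fusion

The two branch scores are combined by a naive-Bayes posterior product.
Both branches are trained on balanced data, so each output is read as a
class posterior at prior $\tfrac12$; under conditional independence the
fused posterior odds are

$$\frac{\pi}{1-\pi}\cdot\frac{o_1}{1-o_1}\cdot\frac{o_2}{1-o_2},
\qquad \text{fused} = \frac{\text{odds}}{1+\text{odds}},$$

which at $\pi = \tfrac12$ is $o_1 o_2 / (o_1 o_2 + (1-o_1)(1-o_2))$.
The source invokes "the Bayes rule" without printing a formula; this
independence reading is the one consistent with balanced training, and
its testable consequences — symmetry, strict monotonicity in each
argument, 0.5 as neutral element, conflicting branches cancelling to the
prior, and the prior acting as a monotone transform that leaves ROC and
AUC unchanged — are asserted in the test suite rather than any claim
that fusion dominates both branches on particular data.  Scores are
clipped to $[10^{-7}, 1-10^{-7}]$ before the odds are formed.

## Evaluation

ROC curves sweep every distinct score as a threshold (plus a $+\infty$
sentinel for the $(0,0)$ endpoint); tied residues enter the confusion
matrix together.  TPR $=$ TP$/N_\text{MoRF}$ and FPR $=$
FP$/N_\text{non}$ — the source misprints FPR as TN$/N_\text{non}$, which
is the specificity and contradicts its own ROC figures, so the standard
definition is implemented.  AUC is trapezoidal, which under this tie
handling equals the tie-aware Mann–Whitney pair statistic exactly; the
test suite checks that identity against a brute-force pair count.
Operating-point summaries report the smallest FPR among points reaching
TPR $\ge$ 0.2, 0.3, 0.4.  Residues are pooled across sequences (no
macro-averaging), matching single-number-per-dataset reporting.
Stratified evaluation splits positives by containing-region length
(short $\le 30$, long $> 30$) and scores each stratum's positives
against **all** pooled negatives — whether the original stratified
evaluation matched negatives per stratum is unstated; pooling all
negatives is our documented choice.

## Synthetic fixtures: what they do and do not establish

`make_dataset()` generates a stated world: 50 sequences of 250–350
residues (≈300, the scale at which the full pipeline runs in about a
minute on one CPU), each with 0–2 non-overlapping planted MoRF intervals
of 10–70 residues (the length range that defines MoRFs), uniform
background composition, and a single effect-size dial $\delta$.
Interval starts are sampled with terminus overhang and truncated to the
chain (always keeping at least 10 residues inside, so annotated region
lengths stay in 10–70).  This detail matters for the null: with
interior-only placement, residues near the chain termini are covered by
fewer candidate placements, and the window features expose terminus
proximity through their pads — a trained model could then beat chance
at $\delta = 0$ from position alone.  Overhang placement makes MoRF
coverage position-uniform, so the zero-effect world is genuinely
exchangeable.  The signal itself enters through $\delta$ acting
through both branches: MoRF residues are drawn with composition weights
$\propto e^{\delta}$ on a designated hydrophobic/aromatic letter set
(ILVFWYM — a set that separates on most physicochemical scales and
lowers windowed letter diversity), and PSSM columns inside MoRFs get a
$+\delta$ shift on the matching rows before integer rounding of
Gaussian noise (sd 2, clipped to $[-10, 12]$, the magnitude of real
log-odds).  The default $\delta = 2$ is a deliberately strong signal
(about 7-fold letter enrichment); $\delta = 0$ is an exact null in which
MoRF and background residues are exchangeable.

A green planted-signal test therefore establishes that features carry a
composition/profile signal end to end, that both MLPs learn it, that
fusion does not destroy it, and that the null calibrates to AUC ≈ 0.5.
It does **not** establish biological accuracy: real MoRFs differ from
their flanks far more subtly, disorder context is not simulated, real
PSSMs have structured column correlations, and the published benchmark
AUCs (≈0.8 on curated test sets) depend on external corpora and
database-version-dependent PSI-BLAST profiles that a self-contained
package cannot ship.

## Numerical and interface choices

* Coordinates are 1-based inclusive in every file format; conversions
  happen only at I/O boundaries.
* Only the 20 log-odds columns of a PSI-BLAST ASCII PSSM are read; the
  percentage columns are ignored.  Raw log-odds are averaged; a
  `logistic_pssm` flag squashes them through $1/(1+e^{-x})$ for
  experimentation.
* Model archives are plain JSON with full-precision numbers and an
  embedded format version; save→load→save is byte-identical and a
  version mismatch is an explicit error.
* The CLI accepts a flat `key = value` config file (no YAML dependency
  in the environment); precedence is flag > config file > default.
* The determinism acceptance check runs the end-to-end pipeline twice at
  a reduced scale (6 sequences, 20 epochs): bit-level reproducibility is
  scale-free, and the reduced run keeps the suite inside its time
  budget.

## Known limitations

* The shipped scale set is a documented substitute, not the original
  appendix table (see above).
* Stratified AUCs use all pooled negatives, one of two defensible
  protocols.
* Training is plain R matrix algebra: ample for the intended scale
  (tens of thousands of residues, 48–60 features), not for
  proteome-scale retraining.
* No disorder-context modelling: the predictor scores MoRF-likeness
  directly and does not first call disordered regions.
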