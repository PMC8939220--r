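---
title: "Compressing k-mer count tables: methods and design notes"
author: "kcsf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing k-mer count tables: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcsf)
```

## The problem

A k-mer count table is a static map $f : K \to \mathbb{N}$ from the
distinct k-mers of a dataset to their occurrence (or document-frequency)
counts. Tables for whole genomes easily hold millions of keys, yet their
value distribution is extremely skewed: in a bacterial genome most
distinct 15-mers occur exactly once. The information-theoretic floor for
storing the *values* is the zero-order empirical entropy

$$H_0(f) = \sum_{\ell \in L} \frac{|f^{-1}(\ell)|}{|K|}
  \log_2 \frac{|K|}{|f^{-1}(\ell)|},$$

which for such skewed spectra is far below 1 bit per key. kcsf provides
data structures that answer $f(q)$ in O(1) without storing the keys at
all, at a space cost tracking (and, with minimizer bucketing, sometimes
beating) $H_0$. All of them share the *static function* contract:
querying a key not in $K$ returns an arbitrary value rather than an
error, which is the price of keyless storage.

## The CSF core

`buildCSF()` codes each value with a canonical length-limited prefix code
(package-merge over the value histogram, cap 32 bits so one query reads
fixed-width windows). Each key contributes, per codeword bit $j$, the
GF(2) equation

$$W[p_1+j] \oplus W[p_2+j] \oplus W[p_3+j] = c_j,$$

with $p_1,p_2,p_3$ hash-derived positions in a bit array $W$ sized
$\gamma$ times the total codeword length. Keys are partitioned into
chunks by a top-level hash; each chunk's system is solved by hypergraph
peeling, with dense Gaussian elimination on the residual 2-core, and a
failed chunk is retried with a bumped seed. Querying XORs three windows
and decodes the prefix.

Numerical design choices:

* **gamma = 1.10.** Random 3-XOR systems are solvable with high
  probability for equations/variables below ~0.917, so $\gamma = 1.10$
  (ratio 0.909) works; pure peeling would need $\gamma \approx 1.23$.
  The payload is then $\approx 1.1 \times$ the compressed value array,
  matching the slope of the fitted cost model below.
* **Chunks of ~1024 equations.** At $\gamma = 1.10$ the 2-core is a
  *constant fraction* of the system (the ratio sits above the peeling
  threshold ~0.818), so the dense elimination step is kept cheap by
  bounding chunks at roughly a thousand equations — the dense solve then
  touches at most a couple of thousand variables and runs in
  milliseconds. `chunkTarget` additionally caps keys per chunk.
* **Seed retries.** Because $\gamma$ sits close to the solvability
  threshold, small chunks occasionally draw singular systems. Up to 16
  seeds are tried; from the fifth attempt the chunk's array is widened
  by 4% per attempt (the realized width is stored per chunk, so queries
  are unaffected). Exhausting the budget raises an error advising a
  larger gamma.
* **Determinism.** Keys are sorted within each chunk, and all hashing is
  seeded, so identical inputs and seed give a bit-identical structure
  regardless of input order.
* A single-valued table needs a 0-bit codeword and no equations: the
  payload is empty and $H_0 = 0$ is achieved exactly.

## The Bloom-enhanced CSF

A practical CSF cannot go below about 1 bit per key, which is wasteful
when a dominant value $v_0$ covers a fraction $\alpha$ of the keys and
$H_0 \ll 1$. `buildBCSF()` stores the *non-dominant* keys in a Bloom
filter $B$ and builds a CSF only on the filter's positives — true
positives at their real values, false positives at $v_0$. A
Bloom-negative query answers $v_0$ immediately; since Bloom filters have
no false negatives, and false positives are stored with the correct
value, **every built key is answered exactly** despite the probabilistic
filter.

With filter cost $C_{BF}\log_2(1/\varepsilon)$ bits/key
($C_{BF} = \log_2 e \approx 1.44$) and CSF cost $C_{CSF}$ bits/key, the
total space objective is minimized at

$$\varepsilon_0 = \frac{C_{BF}}{C_{CSF}}\cdot\frac{1-\alpha}{\alpha}
  \cdot \log_2 e,$$

and the filter pays off exactly when $\varepsilon_0 < 1$, i.e. when
$\alpha > C_{BF}\log_2 e \,/\, (C_{CSF} + C_{BF}\log_2 e)$ — 0.59 at
equal coefficients:

```{r}
bloomAlphaThreshold(1.44, 1.44)
optimalEpsilon(0.97, cBf = 1.44, cCsf = estimateCsfCost(0.25))
```

$C_{CSF}$ comes by default from the fitted envelope
`estimateCsfCost()`: $0.22H_0^2 + 0.18H_0 + 1.16$ for $H_0 < 2$, else
$1.1H_0 + 0.2$ (continuous at the kink). That envelope was fitted to a
reference implementation, not to this one; `costModel = "measured"`
substitutes this package's own expected payload ($\gamma$ times the mean
codeword length). We keep the fitted constants as the default because
the dimensioning *decisions* they produce are the documented behavior,
and the same $C_{CSF}$ is used on both sides of the comparison, where
its absolute error largely cancels. Degenerate case: $\alpha = 1$
stores only the constant $v_0$ with no filter and no CSF.

## Minimizer bucketing: AMB and FIL

The minimizer $\mu_m(q)$ of a k-mer is its length-$m$ window that is
smallest in a seeded 64-bit hash order (a lexicographic order has poor
statistical properties; ties between equal-hash windows break to the
leftmost, a deterministic choice the hash makes essentially irrelevant).
Neighboring k-mers of a genome share minimizers, and k-mers sharing a
minimizer tend to share counts — so the map $g$ from *minimizers* to a
representative count is far smaller than $f$, and often constant per
bucket.

**AMB** stores, per bucket, the bucket minimum if all member counts
agree to within $\delta$ and the reserved marker 0 otherwise (counts are
$\ge 1$, so 0 is safe); k-mers of marked buckets cascade to the next
layer with a longer minimizer, and whatever survives the last layer goes
exactly into a terminal k-mer-keyed BCSF. The first non-zero answer
along the cascade is final, so for $\delta = 0$ answers are exact and
for $\delta > 0$ they are the resolving bucket's minimum, within
$\pm\delta$ of the truth. The minimum (rather than mode) is the natural
representative here because k-mer spectra decrease: small counts are the
common ones.

**FIL** stores, per layer, the per-bucket *exact majority* $g_i$ of the
current residual values (full two-pass histogram; ties toward the
smallest value; the streaming approximate-majority alternative is
deliberately not implemented), and telescopes
$f_i(q) = f_{i-1}(q) - g_i(\mu_{m_i}(q))$. The final residuals $h$ are
mostly 0 by the majority rule; they are zigzag-coded
(0, -1, 1, -2, ... to 0, 1, 2, 3, ...) and stored in a k-mer-keyed BCSF
whose Bloom filter therefore holds exactly the k-mers needing a
correction. Queries sum all layer representatives plus the correction
and are always exact. Multi-layer FIL is implemented as this
telescoping sum with every layer defined on all of $K$; the one-layer
scheme is the special case $\ell = 1$, and every query visits every
layer — consistent with the observation that FIL query time grows with
its layer count while AMB's does not.

Design notes: minimizers are computed on the key exactly as stored
(i.e. on the canonical k-mer when the table is canonical), keeping the
bucketing consistent with the key space; per-layer order seeds derive
deterministically from the build seed; changing seeds changes bucket
composition but never correctness, which the tests exercise across
seeds.

### Choosing minimizer lengths

Bucketing helps only when minimizers are long enough to partition the
key set: useful first-layer lengths satisfy
$m > m_s = \log_4|G| + 2$ for a genome of $|G|$ bp.
`suggestMinimizerLengths()` returns the integers strictly between $m_s$
and $k$; when there are none (small $k$), it recommends the
$\delta$-approximate mode with layers at $k-2, k-1$. The empirical
optimum is found by building candidates in increasing order and stopping
when the measured size starts to increase again; this is a build-and-
measure search (the `suggest` CLI verb plus repeated `build`), not an
analytic prediction, because no closed form for the optimum exists.

## Counting and formats

`countKmers()` counts canonical k-mers (lexicographic minimum of the
k-mer and its reverse complement — the convention of standard counters;
`canonical = FALSE` for strand-specific data). Windows containing N are
skipped entirely rather than treating N as a fifth letter. k is capped
at 31 so a k-mer packs into one 64-bit word; KMC-style dumps at k = 32
are rejected with a clear error. Tables are exchanged as the two-column
`<KMER>\t<COUNT>` TSV dump format; FASTA/FASTQ (optionally gzipped) are
read through Biostrings. Indexes are persisted in a checksummed
container (magic bytes, version, scheme tag, fixed-width section table,
CRC-32 per section) with distinct error classes for bad magic, version
mismatch, truncation and checksum failure.

## What the synthetic generators emulate

* `randomGenome()` — the whole-genome regime: an i.i.d. uniform backbone
  (at $|G| \ll 4^k$ essentially all k-mers unique) plus re-inserted
  copies of earlier segments, giving a controllable repeat fraction
  whose k-mers carry counts $\ge 2$. Defaults used in the tests: 2 Mbp,
  5% repeats of 1 kb units — a bacterial-scale stand-in.
* `powerlawTable()` — spectrum-shaped counts,
  $P(c) \propto c^{-a}$ truncated at `maxCount`, sampled by inverse CDF
  so results are exactly reproducible.
* `dominantTable()` — direct control of $\alpha$ for the Bloom
  dimensioning experiments; non-dominant counts default to values
  $v_0+1..v_0+9$ with decreasing, spectrum-like weights
  $\propto \mathrm{rank}^{-2.5}$.

What they do *not* emulate: sequencing errors, coverage fluctuations of
read data, GC bias, or the locality structure of real repeat families.
A green exactness test establishes the correctness contracts on any
input (exactness is distribution-free); the *space* results on synthetic
tables are scaled-down analogues — figure-level bits-per-k-mer numbers
from real genomes are not reproduced here, only the qualitative
orderings (Bloom stage beating a plain CSF above the alpha threshold;
layer-1 bucketing resolving the vast majority of genome k-mers).

## Worked example

```{r}
tab <- countKmers(randomGenome(2e5, repeatFraction = 0.05, seed = 42),
                  k = 18)
length(tab); entropyH0(tab); dominantFraction(tab)$alpha

bcsf <- buildBCSF(tab, seed = 1)
amb  <- buildAMB(tab, minimizerLengths = 13, seed = 1)
all(bcsfQuery(bcsf, kmers(tab)) == counts(tab))
all(ambQuery(amb, kmers(tab)) == counts(tab))
round(rbind(BCSF = bitsPerKmer(bcsf), AMB = bitsPerKmer(amb)), 3)
```

The AMB data payload (Bloom + CSF arrays + code tables) lands below the
table's own $H_0$: the minimizer layer stores one value for whole
buckets of equal-count k-mers, which is structural information the
zero-order bound does not see. The `metadata` column is R serialization
overhead of the container, constant per structure and negligible at
genome scale.

## Known limitations

* Keys are limited to the DNA alphabet and $k \le 31$.
* Counting is in-memory and single-threaded; this is a compression
  library, not a disk-based counter.
* The serialized structures embed R serialization for the payload
  sections (wrapped in the checksummed container); they are not
  interoperable with other implementations' formats.
* Negative or zero counts are rejected at the table level by design
  (0 is the AMB ambiguity marker), though internal structures handle
  arbitrary integer values (FIL residuals).
* Querying keys outside the build set returns arbitrary values; pair an
  index with an external membership structure if that matters.
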