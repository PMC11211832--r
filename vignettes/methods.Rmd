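---
title: "Masked graph contrastive pretraining and R-group retrieval: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked graph contrastive pretraining and R-group retrieval: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Lead optimization keeps a molecule's core scaffold fixed and swaps its
peripheral R-groups in search of better drug-likeness, synthesizability or
binding. `molrgr` implements a pretraining framework built around exactly
this operation: molecules are decomposed into putative cores and R-groups
joined at *linker joints*, a shared graph encoder is trained contrastively
on masked versions of these decompositions, and the resulting co-embedding
space is used to retrieve replacement R-groups for a masked attachment
point on a query scaffold.

# Molecular graphs and masking

Molecules are heavy-atom graphs (`parse_smiles()`): atoms carry element,
formal charge, aromatic flag, chirality tag and hydrogen count; bonds carry
order and a stereo tag. Every attribute is integer-coded against a fixed
vocabulary with one appended `MASK` sentinel (`attribute_vocabularies()`),
and every atom and bond has a mask flag. Masking (`mask_joint()`) flips the
flag: consumers (featurization, the SMILES writer) then see only the
sentinel, while the stored attributes survive so round-trip tests can
restore them. Node indices are 1-based, matching R and every installed R
graph library.

Canonical SMILES are produced by OpenBabel (through ChemmineOB) whenever it
can represent the graph — all unmasked molecules and all fragments whose
wildcard attachment atom is terminal, which includes every R-group record
the package deduplicates. One case is outside any toolkit's reach: a query
template whose masked linker atom sits *inside* an aromatic ring cannot be
kekulized once its attributes are hidden. For those graphs the package uses
its own canonical ordering (iterative neighborhood refinement with
deterministic orbit tie-breaking) and writes explicit aromatic-bond symbols
around the wildcard; the resulting strings are parsed back only by the
package itself. Property tests assert that both canonicalization paths are
invariant under random atom relabeling.

Two deliberate simplifications: stereochemistry is parsed and featurized as
a categorical tag but never re-derived or emitted (canonical forms are
constitution-only), and hydrogens are implicit throughout, with implicit
counts re-derived from standard valences (aromatic atoms restricted to
their lowest valence state, with the usual lone-pair-donor allowance for
pyrrole-type nitrogen). The valence check that backs `sanitize_molgraph()`
is intentionally permissive outside common organic chemistry: its job is to
reject impossible products (pentavalent carbon), not to re-implement a full
aromaticity model.

# Decomposition: putative cores, R-groups, masked linker joints

A *putative core* realizes the "single molecule – multiple scaffolds" idea:
any connected, ring-containing induced subgraph whose boundary consists
only of acyclic single bonds. Operationally the molecule is condensed into
a tree whose super-nodes are the pieces left after contracting all ring
bonds and all non-single bridges (so fused and spiro ring systems are never
split and an exocyclic `=O` never separates from its carbon); every
connected subtree containing a ring system is a candidate core
(`enumerate_putative_cores()`). Candidates are deduplicated by canonical
SMILES and prioritized larger-first with SMILES ties, capped at
`max_cores = 10`; corpus construction drops molecules whose *total* unique
core count exceeds the cap, mirroring the upstream preprocessing rule. The
tests pin this enumerator to an independent brute-force oracle that cuts
every subset of cuttable bonds.

Given a core, each connected peripheral component is one R-group
(`identify_rgroups()`), attached through exactly one bond and sharing one
*linker atom* with the core. Decoupling a subset (`decouple_subset()`)
produces the masked decomposition: the query template keeps all atoms
except the subset's peripheries and masks each affected linker atom (only
the atom — its remaining core bonds keep their attributes); each fragment
receives a duplicated copy of its linker atom, masked, with the copy's bond
into the fragment masked too. A core with $n$ R-groups yields exactly
$2^n - 1$ decompositions, one per non-empty subset, ordered by binary
counting over R-groups sorted by linker atom.

Two branches hanging off the same core atom are two R-groups sharing one
linker atom. Such decompositions have fewer masked query atoms than
fragments; `reattach_all()` therefore merges all fragments of a joint
before unmasking it, while the single-pair `reattach()` keeps the strict
one-masked-node-per-side contract. Re-attachment with
`fill = "restore-original"` reproduces the parent molecule exactly (tested
at 100% across the fixture corpus); `fill = "default"`, used for retrieved
foreign fragments, restores the query atom's stored attributes when it has
them (falling back to carbon), sets the joint bond to single, re-derives
the hydrogen count from remaining valence, and sanitizes — chemically
impossible products are returned as `invalid_product` signals and counted,
not raised.

# Corpus construction

`build_corpus()` emits every decomposition of every surviving (molecule,
core) pair, deduplicates fragments into records with occurrence counts, and
applies two filters taken from the source protocol: records whose count
strictly exceeds the 99.99th percentile (linear-interpolation empirical
percentile over deduplicated records) are flagged *common*, and instances
in which strictly more than half of the decoupled fragments are common are
removed (exactly half is kept). Counts are computed before removal, as in
the original pipeline. An independent validator (`validate_corpus()`)
re-derives all three rules from scratch.

Each fragment gets an 87-bit condition vector: bit $f$ is set iff SMARTS
pattern $f$ of the shipped functional-group catalog matches the fragment
(OpenBabel matching on the `*`-bearing SMILES; the wildcard atom can occupy
a connection slot but never matches an element-specific pattern atom, which
is what makes `*O` a hydroxyl rather than water). The published description
fixes only the length 87, not the patterns, so the catalog shipped at
`inst/extdata/functional_groups.tsv` is this package's pinned, checksummed
choice covering the standard functional-group families; corpora, checkpoints
and libraries all record the checksum and refuse to mix versions.

Splits are molecule-level (all instances of a molecule share a split) with
a seeded shuffle at 0.8/0.1/0.1, so no molecule leaks across partitions.
Serialization is deterministic and round-trips byte-identically; core atoms
and decoupled joints are recorded in the canonical parse frame so reloading
is independent of the original atom order.

# Encoder, heads and objectives

The shared encoder $f_\theta$ is a GIN with edge-feature embeddings: node
features are sums of per-attribute embeddings; each layer aggregates
$\mathrm{ReLU}(h_u + e_{uv})$ over incident edges, adds the center node,
and applies a two-layer MLP followed by batch normalization, with ReLU
between layers. Defaults are 5 layers and $d = 300$. Four two-layer
LeakyReLU (slope 0.01) heads project: graphs ($g_\theta$, after mean-pool
readout), linker nodes ($g_\kappa$), conditioned queries ($g_\Phi$, input
width $d + 87 = 387$) and R-group fragments ($g_\phi$, after mean-pool over
the fragment). Head outputs are unnormalized; the training similarity is
cosine. The GIN center-node weight is fixed at zero (the common "GIN-0"
choice) and heads have no output normalization — both details are
unspecified upstream and are recorded here as this package's defaults.

Training aligns three pairs with a dual (symmetric) InfoNCE over in-batch
negatives (`info_nce()`):

* $L_1$ (temperature 0.01): each molecule's graph projection against its
  decomposed view's, the decomposed branch detached (stop-gradient);
* $L_2$ (0.05): each original linker node against the vector-wise sum of
  its masked pair (query-side plus fragment-side row), the summed branch
  detached; all linker sites in the batch are pooled into one negative
  pool;
* $L_3$ (0.01): each conditioned query projection against its decoupled
  R-group projection, both branches live.

The total is $L = L_1 + L_2 + L_3$; per-term weights expose the ablation
that removes the retrieval term. Pooling sites across instances means $B_2$
and $B_3$ can exceed the instance count $B_1$ when instances average more
than one decoupled site; the pooled reading maximizes negatives and follows
the per-batch definitions of the terms. Stop-gradient branches are
implemented as detached constants on the autodiff tape; the tests verify by
finite differences both that their values move with the encoder weights and
that they contribute exactly zero gradient.

The whole stack — tape-based reverse-mode autodiff, Adam, batch
normalization with running statistics, dropout, the masked BCE/MSE losses —
is implemented in the package and validated against finite differences, and
the InfoNCE implementation against a two-loop reference. `pretrain()` is
fully seeded (weights, batch order, dropout) and early-stops on the
validation total loss with patience 10, retaining the best-validation
parameters; the history starts with an epoch-0 row holding the untrained
validation loss so loss curves are anchored at initialization.

# Retrieval, fine-tuning, lead optimization

`build_library()` embeds the deduplicated fragments with the pretrained
encoder and R-group head. `retrieve()` scores a conditioned query by raw
inner product against the library — the inference-time metric — and ranks
exhaustively with stable id tie-breaking; at the library sizes this package
targets an approximate index would add nothing, so exact search is the only
backend. `evaluate_retrieval()` reports MRR on the best ground-truth rank
and R@K; the cutoffs default to {5, 10, 50, 100}, covering both cutoff sets
used in the source experiments, and are configurable. Baselines: seeded
uniform random sampling, and a popularity ranking identical for all queries
(count-descending, SMILES ties).

`finetune_property()` follows the downstream protocol: load the pretrained
encoder, add a linear task head on the mean-pooled representation, dropout
0.3, Adam at 1e-4, batch 32, deterministic scaffold split 8:1:1 (groups by
the pruned ring-and-linker scaffold, filled largest-first), missing labels
masked, AUROC (averaged over tasks) or RMSE over repeated seeds with
mean/sd.

`optimize()` chains the pieces at one site: decompose at the chosen
R-group, retrieve K candidates, re-attach each with the default fill,
sanitize, and score valid products with QED and SAscore through the
installed RDKit toolkit (a batch `python` subprocess; one call per report).
"Improved" is read conjunctively — QED strictly higher and SAscore strictly
lower than the reference — the stricter of the two possible readings of the
upstream criterion. `color_nodes_by_pca()` reproduces the qualitative
analysis: first principal component of the node representations, min-max
normalized, sign anchored at the highest-degree atom.

# The synthetic fixture generator

`generate_fixtures()` assembles molecules from five ring cores (benzene,
pyridine, piperidine, indole, biphenyl) and ten one-attachment substituents
spanning acyclic, ring-like and functional-group-rich R-groups, sampling
1–3 substituents onto free positions under valence control, with the
construction record (core atoms, linker nodes, fragment SMILES) attached.
It emulates the compositional structure of drug-like screening compounds —
one scaffold, few small substituents — which is what the decomposition and
retrieval machinery needs to be exercised end to end. It does not emulate
real corpora's size distribution, stereochemistry, charge states or the
long tail of rare fragments, so passing tests demonstrate correctness of
the machinery and learnability at desk scale, not transfer to real
chemistry.

# Scaled-down study sizes

The reference protocol (batch 512, up to 100 epochs, $d = 300$, 5 layers,
300K molecules) is far beyond a test suite. The suite and the acceptance
script instead run two fixed small studies chosen once: a *learning* study
— 200 fixture molecules, 30 epochs, 3 seeds, GIN with 3 layers and
$d = 32$, batch 8, Adam at the protocol's 1e-3 — and an *overfitting*
study — 50 molecules, 60 epochs, batch 16, $d = 32$ — whose corpus
fragments form the retrieval library. Batch sizes scale with the corpus
(the protocol's 512 would make a 648-instance train split one batch);
learning rate and temperatures keep the protocol values. A small-corpus
caveat recorded here: decompositions of the same molecule appear together
in batches, so the graph-level term $L_1$ has an irreducible floor (its
duplicated positives are inseparable in-batch negatives) and most of the
loss decrease comes from the node and retrieval terms — at corpus scale
duplicates are rare and this floor vanishes.

# Numerical choices

Softmax computations subtract per-row maxima; cosine similarity clamps
norms at 1e-8; batch normalization uses momentum 0.1 running statistics
(training mode requires at least two rows, else the running statistics are
used); Adam uses the standard bias-corrected defaults; ranking ties break
by library id; percentiles use R's type-7 linear interpolation. Degenerate
inputs are defined, not special-cased: a single-pair batch has zero InfoNCE
loss, a single-atom molecule colors to 0.5, an empty R-group subset and an
unmasked retrieval site are argument errors, and an unsanitizable
re-attachment product is a counted rejection.
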