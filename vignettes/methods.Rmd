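---
title: "Learned edge scoring for overlap-graph assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned edge scoring for overlap-graph assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(contigraph)
```

## The problem

Overlap-layout-consensus assembly of accurate long reads represents each
read as a vertex of a directed graph whose edges are suffix--prefix
overlaps. On a repeat-free genome with error-free reads this graph is a
near-chain and the layout is trivial; real graphs carry spurious branches
-- tips, skip edges, dead ends -- and the layout stage must decide, for
every edge, whether it lies on a genome-consistent traversal. `contigraph`
treats that decision as supervised binary edge classification: an
edge-aware graph transformer scores every edge with a probability, and an
iterative greedy search decodes contigs from the scored graph.

Because real training data (reference genomes, read sets, an external
overlap builder) would make the loop irreproducible at desk scale, the
package closes the loop hermetically: it simulates a genome and
coordinate-annotated HiFi-like reads, builds the overlap graph from true
coordinates, derives ground-truth edge labels from positions alone, trains
the scorer, decodes, and evaluates against the known genome.

## The graph and its features

A node is an oriented read; an edge `u -> v` records that a suffix of `u`
overlaps a prefix of `v` by `ol` bases. Raw features are deliberately
sequence-free:

* node: `[out-degree, in-degree]` -- a dead end (out-degree 0) is the
  classic tip signature;
* edge: `[overlap length, overlap similarity]`, where similarity is
  `max(0, (ol - edit distance) / ol)` over the two overlap windows
  (exact Levenshtein distance, computed in C++; the windows are the
  source's length-`ol` suffix and the target's length-`ol` prefix,
  compared globally).

Degrees and overlap lengths enter unscaled; a z-scoring switch exists but
is off by default -- in side-by-side runs scaling the overlap-length
column did not improve validation accuracy, so the simpler convention
stands. Both feature matrices are lifted to the hidden dimension `d`
(default 64) by three fully connected layers with ReLU between them.

## Positional encodings

Before the first layer, each node embedding receives a projection of `k`
Laplacian eigenvectors (default `k = 16`) of the undirected simple graph:
ascending eigenvalue order, trivial first eigenvector dropped. Eigenvector
signs are arbitrary, so inference fixes them deterministically (largest-
magnitude entry positive) while training flips each column's sign at
random every step, forcing the model to learn sign-invariant functions.
The symmetric normalized Laplacian is the default; the unnormalized
variant is available and is what the closed-form path-graph tests use.
When a graph has too few nodes for `k` eigenvectors the encoding is
zero-padded rather than refused.

## The transformer layer

Each of `L` layers (default 4; the label-recovery experiments use 2)
updates node features `h` and edge features `e` jointly. Per head, over
each directed edge `j -> i`:

* gate vector: `s_ij = (Q h_i * K h_j) / sqrt(d_k) * (E e_ij)`
  (elementwise; an additive gate is available behind a flag for
  ablation);
* attention logit: the head-wise sum of `s_ij`, clamped to `[-5, 5]`,
  softmax-normalized over the in-neighbours of `i`;
* node update: attention-weighted sum of `V h_j`, heads concatenated,
  projected by `O_h`;
* edge update: the clamped gate vectors, heads concatenated, projected by
  `O_e`.

The clamp (config constant, default 5) bounds the exponentials; it is
applied to the logits before the softmax, which is the only reading under
which clamping interacts with the softmax at all -- clamping post-softmax
values, which already lie in `[0, 1]`, would be a no-op. Both streams then
pass residual + BatchNorm, a `2d`-wide ReLU feed-forward network, and a
second residual + BatchNorm. Attention projections and FFNs carry no
biases, so a node with no in-neighbours receives a zero message and its
pre-norm representation is exactly the residual input -- isolated nodes
pass through finitely. BatchNorm uses batch statistics (over the graph's
nodes or edges) during training and running statistics at evaluation, so
scoring is deterministic and permutation-equivariant.

Scores come from concatenating `[h_source, h_target, e_edge]` (width
`3d`) and applying a three-layer MLP (widths 64, 32, 1 by default) with a
sigmoid, giving a probability in `(0, 1)` per edge.

The forward pass, analytic backpropagation through every block (grouped
softmax, clamps, BatchNorm in both modes, the scatter/gather between node
and edge streams) and Adam are implemented in base R; the test suite
checks every parameter group against central-difference numerical
gradients on a small configuration.

## Ground-truth labels

Simulated reads carry their true interval and strand. An edge `A -> B` is
*retained* when both reads share a strand and form a proper dovetail
(`start(A) < start(B)`, `end(A) > start(B)`, `end(B) > end(A)`); the
coordinate-built graph satisfies these by construction, but graphs read
from GFA need not. Labels then come from two sweeps, repeated until every
node has been seen: a forward BFS over retained edges from the unswept
node with the lowest start coordinate (ties by read id), then a backward
BFS -- against edge direction -- from the visited node with the highest
end coordinate ("highest" is a config switch between end and start; end
is the default because the backward sweep should begin where the genome
walk terminates). Edges traversed by both sweeps are positive; everything
else, including never-reached edges, is negative. Negatives are therefore
*one-sided* edges: branches that a genome-spanning walk can enter but not
leave (tips) or reach but never receive.

## Training

The loss is mean binary cross-entropy with a positive-class weight `w`:
`auto` mode uses the negative/positive count ratio of the training set,
or a fixed value may be given. Predictions at the boundary are clipped at
`1e-7`. Optimization is Adam at learning rate `1e-4` (default), one
full-batch step per subgraph per epoch, fully seeded (weight
initialization, positional-encoding sign flips and partition growth all
derive from the one seed, so loss trajectories are bit-reproducible).

Large graphs are split by a seeded BFS-growing partitioner into
node-disjoint parts of roughly equal size; cross-partition edges are
dropped from the loss and their count is reported. METIS-quality cuts are
not needed at desk scale, and the BFS partitioner keeps the package free
of external dependencies. For the 50 kb study graphs below (a few hundred
edges) partitioning is disabled (`partition_count = 1`): the Laplacian
encodings of a fragment differ from those of the whole graph, and
whole-graph steps measurably improved validation accuracy. The checkpoint
with the best validation loss is retained; early stopping uses a patience
counter.

## Decoding

Each round takes the `N` (default 16) highest-scoring edges among those
with both endpoints unvisited, breaking score ties with a seeded random
key. Each candidate edge is extended greedily forward from its head and
backward from its tail -- always the highest-scoring admissible edge,
ties to the lowest edge id, never entering a visited or on-path node --
and the two half-paths are joined around the start edge. Only the winner
(the candidate whose implied contig, sum of read lengths minus sum of
overlap lengths, is longest) marks its nodes visited; losers leave no
trace, so one bad candidate cannot poison the next round. Iteration stops
when the best candidate has fewer than `min_path_reads` reads (default
3). Contigs are spelled by trimming each overlap once, so in error-free
mode contig length conserves read and overlap bases exactly.

## Evaluation

Contigs are aligned to the known reference by exact k-mer anchoring
(k = 21, one anchor per 50 bp, only k-mers unique in the reference) and
chained while collinear; a diagonal jump or gap beyond 1 kb (config)
opens a new block and counts one misassembly junction. Exact-substring
contigs short-circuit to a single block. From the blocks the report
derives genome fraction (interval-union coverage), NA50 (denominator:
total assembly length) and NGA50 (denominator: reference length), both by
the definitional descending-cumulative scan. This is a desk-scale
aligner for a known, repeat-annotated reference, not a QUAST replacement:
it does not classify misassembly types and is not meant for real
assemblies.

## Study conditions and problem sizes

The simulator emulates the two properties of HiFi data that matter to
this method -- reads long enough to overlap informatively and accuracy
high enough that overlap similarity is near 1 -- scaled down so the loop
runs in seconds to minutes: genomes of 20--100 kb, reads of 3--3.5 kb
(truncated normal), error rates 0 to 0.1 %. It does not model pbsim3's
chemistry or pass-number effects, diploidy, or biological repeat
structure (repeats are verbatim copies at random placements), and
coordinate-built graphs contain none of the error-induced edge artifacts
an overlap detector would produce; passing tests therefore demonstrate
the machinery, not performance on real data.

Two reference experiments anchor the test suite and the acceptance
script:

* *Oracle decoding*: 100 kb, 20x, error-free, `min_overlap` 500,
  ground-truth labels as scores. Decoding must recover at least one
  contig that is an exact substring of the genome, with zero
  misassemblies and genome fraction at or above 99 %.
* *Label recovery*: seven graphs from 50 kb genomes at 12x with
  3.5 +/- 2 kb reads and `min_overlap` 2500 (the
  `simulate_labeled_graph()` defaults) -- a deliberately sparse, branchy
  regime in which roughly 10--25 % of edges are one-sided (negative).
  Five graphs train a `d = 64`, `L = 2`, `H = 4` scorer for up to 400
  epochs (whole-graph steps, unit positive weight, patience 120); two
  held-out graphs measure edge-classification accuracy against the
  pooled majority-class baseline.

On the label-recovery task the trained scorer consistently clears the
majority baseline, but the achievable margin deserves honesty: the labels
encode *global* reachability (an edge is positive only if its source is
reachable from the component's start and its target co-reachable from its
end), while the architecture propagates information along edge direction
only -- a node never hears about the death of its downstream branch
except through its own out-degree feature. Side-by-side probes with a
gradient-boosted classifier on degree + positional-encoding features hit
the same wall, a few points above the baseline, confirming the ceiling is
informational, not an optimization failure. The margin achieved therefore
varies with how tip-rich the sampled validation graphs happen to be; on
tip-poor draws the majority baseline alone exceeds 90 % and large margins
are arithmetically out of reach.

## Degenerate inputs and numerical conventions

Empty graphs decode to empty contig sets; single-node graphs score
finitely; empty in-neighbourhoods skip attention; subgraphs smaller than
the encoding width get zero-padded encodings; BCE clips at `1e-7`;
BatchNorm uses `eps = 1e-5` and momentum 0.1; eigendecomposition
tolerances in tests are `1e-6`. GFA edges whose overlap is not strictly
inside `(0, min(read lengths))`, and self loops, are dropped at load with
a warning. All coordinates are 0-based half-open; reverse-complement
duality is deliberately not modelled (each `(read, orientation)` pair is
its own node; the simulator emits forward-strand reads unless asked
otherwise).
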