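---
title: "Exporting point clouds, line sets and meshes to U3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exporting point clouds, line sets and meshes to U3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u3dio)
```

## The problem

Interactive 3D figures can be embedded into PDF documents: a PDF 3D
annotation carries a scene file in one of two binary formats, of which
Universal 3D (U3D, standardized as ECMA-363) is the one most widely
supported by authoring tools and by journals accepting 3D supplements.
Generating those scene files is the bottleneck for most scientists:
mainstream mesh tools neglect the two geometry kinds that matter for a lot
of scientific data — bare point clouds and polylines (trajectories such as
vectorcardiograms, fiber tracts, vessel centerlines) — and programming
against a full 3D library is a high hurdle for a figure.

`u3dio` covers exactly that gap for R: it turns tabular point/line data and
OBJ/PLY meshes into U3D files with a hierarchical object tree, shared
geometry resources, per-object colour/transparency and file metadata, and
it ships a structural reader so that every file the encoder emits can be
decoded back and compared — the package's own round-trip oracle, and the
backend of the `inspect` command.

## Scene model

A scene is a single root group, a tree of group and model nodes beneath it,
and a flat table of uniquely named geometry resources. A model node binds
one resource to one placement in the tree together with a material. The
separation matters for file size: the same anatomical surface shown three
times in different colours is stored once and referenced three times.

Three geometry kinds are supported, mirroring what PDF viewers render:

* **point clouds** — an n × 3 position matrix;
* **line sets** — positions plus an edge list; when the edge list is
  omitted, each node is connected to the next
  (`auto_connect(n)` = the `n − 1` chain), the natural layout for sampled
  trajectories;
* **triangle meshes** — positions, faces, optional unit per-vertex
  normals. Missing normals are computed at export as the normalized
  area-weighted average of incident face normals (counter-clockwise
  winding, right-hand rule); a vertex with only zero-area incidence falls
  back to (0, 0, 1) with a warning.

Coordinates are passed through unchanged (a right-handed system is
assumed, matching U3D viewers); transforms default to the identity and are
carried, not composed. Degenerate faces (repeated vertex) and zero-length
edges are dropped with a warning before export; out-of-range indices
abort. Sibling name collisions in the tree are resolved by suffixing
`_2`, `_3`, … with a warning rather than aborting the export over a
cosmetic clash.

## The object-specification language

Which objects to export, their names, colours, opacity and group placement
are declared in a small XML-like text syntax (`<U3DObject>` records with
`ObjectType`, `GeometryID`, `ObjectName`, `GroupPath`, `Color`,
`SpecularColor`, `Opacity`, `MetaData` children; tags case-insensitive).
The concrete tag vocabulary is this package's own and is versioned here;
it was designed to be diff-friendly and round-trip testable:
`parse_object_specs(generate_object_specs(s))` recovers every valid spec
field-for-field, a property the test suite exercises on 200 randomized
specs. Omitted fields take defaults from a configurable table
(`u3d_spec_defaults()`): mid-gray diffuse (0.65, 0.65, 0.65), specular
(0.3, 0.3, 0.3), opacity 1, root placement, automatic `"<type>_<ordinal>"`
names. The defaults are this package's choice of a neutral matte material;
deleting records is plain text editing, so no deletion API exists.

Numbers are serialized in the shortest decimal form that parses back to
the identical double, which is what makes exact round-trips possible.

## Importers

`read_marker_list()` reads character-separated text (one point per row,
first three numeric fields as x, y, z; extra fields such as labels are
ignored). The delimiter, the decimal separator (substituted before
numeric parsing, so decimal-comma files work), the comment prefix and a
row filter are configurable. The filter keeps data row `i` (0-based) when
`i ≥ start_row` and `(i − start_row) mod stride = 0` and an optional
column match holds, truncated at `max_rows` — a deliberate superset of
"import a subset", since real marker files come with header rows, mixed
marker types and oversampled trajectories. Errors name the offending file
row and column. `read_connections()` reads 0-based index pairs (the text
convention) and converts to R's 1-based indexing.

`read_obj()` covers the OBJ subset that matters for this pipeline
(`v`/`vn`/`f`, comments, 1-based and negative relative indices, polygon
fan-triangulation from the first corner, `v/vt/vn` corner forms); other
record types are counted and reported in one warning, never silently
eaten. `read_ply_ascii()` parses the ASCII PLY header, extracts x/y/z among
arbitrary vertex properties and fan-triangulates face lists; binary PLY is
rejected naming the detected format. No R package in this stack reads
these formats, so both parsers are implemented here, deliberately small.

## U3D serialization

A U3D file is a sequence of 32-bit aligned blocks: `type`, `data size`,
`metadata size` (little-endian 32-bit words), then the data and metadata
payloads, each zero-padded to a 32-bit boundary; declared sizes count
unpadded bytes, and the file-header block's type code spells `U3D\0`. The
encoder emits: the file header (carrying the scene metadata as key/value
pairs), one modifier chain per node (parents before children, so the
on-disk parent-name links reproduce the tree; model chains carry the model
node plus a shading modifier), deduplicated shader/material resources, an
optional ambient light and a perspective view framing the scene bounding
box (both **off** by default — PDF viewers supply sensible defaults), one
model-resource chain per referenced geometry holding its declaration
block, and finally the continuation blocks with the bulk geometry, so the
declaration section is contiguous and its size is recorded in the header.

Meshes are written as a single full-resolution base mesh: minimum
resolution = maximum resolution = vertex count, no progressive
level-of-detail updates. That matches the module's purpose — exporting a
final-resolution figure — and what mainstream exporters emit. Base-mesh
positions and normals are raw 32-bit floats and therefore decode
bit-exactly; face corner indices are coded in a uniform static context
sized by the vertex count (falling back to raw 32-bit words above 16383
vertices). Per-vertex colours and texture coordinates are not emitted;
colour lives in per-object materials, and an opacity below 1 switches the
object's shader onto the alpha-blending path.

Point and line positions are quantized: with factor `q` (default 1000,
i.e. about three decimal digits; configurable via
`u3d_config(position_quant =)`), each coordinate is rounded to `1/q` steps
and the per-axis differences between consecutive points are zigzag-mapped
and entropy-coded. The inverse-quantization error is bounded by half a
step, `0.5/q` per axis (5 × 10⁻⁴ at the default), and the decoded
resources carry that bound as a `position_tolerance` attribute. Zero is a
fixed point of the quantizer, and the factor itself is stored (and
applied) in 32-bit float precision on both sides so writer and reader use
the identical value.

### The bit codec

The byte stream interleaves two channels. Raw values (`u8`…`u64`, `f32`,
length-prefixed strings) are little-endian with bits packed LSB-first.
Compressed values go through a 16-bit context-adaptive arithmetic coder:
each dynamic context (1–1023) keeps an adaptive symbol histogram with an
escape symbol — a value unseen in its context is escaped to a raw 32-bit
write and then enters the histogram with count 1; counts are halved when a
context's total reaches 8191. Static contexts (`1024 + n`) code a value
uniformly over `[0, n)` with no state. When the stream switches from the
compressed to the raw channel (including after every escape), the coder
state is terminated with two-plus-underflow disambiguating bits and the
decoder performs the mirror resync; this makes `read(write(x)) = x` hold
for any interleaving under the same call/context sequence, which is the
contract the whole reader rests on and which the tests fuzz with 10⁴
random context/value pairs. The coder interval arithmetic (half/quarter
renormalization with underflow counting) follows the classic
Witten–Neal–Cleary construction. Compatibility with other U3D readers is
claimed at the structural level (block framing, declared sizes,
alignment); decode-equivalence against this package's reader — not byte
equality with any third-party writer — is the tested contract.

Output is fully deterministic: no timestamps or locale-dependent content
are written, so identical input yields the identical byte stream and
byte-level regression tests are possible.

## The reader as oracle

`parse_blocks()` partitions a stream into blocks, enforcing alignment,
declared-size honesty and exact coverage of the byte length, and reports
unknown block types without failing. `decode_scene()` reconstructs the
tree, materials, metadata and all three geometry kinds by running the same
context sequences through the decoder; `summarize_u3d()` aggregates counts
and is what `u3d inspect` prints. The reader deliberately supports only
the encoder's subset — it is an oracle and inspection backend, not a
universal U3D importer; unknown blocks are skipped via their declared
sizes.

## Fixtures and what the tests do (and do not) show

`make_fixture()` generates the synthetic geometry the test suite runs on:
a 3 × 3 × 3 unit lattice (27 points, optionally jittered under a seed), a
100-sample, 3-turn helix (the stand-in for trajectory data; auto-connected
to 99 segments), the unit cube (8 vertices, 12 outward-wound faces,
closed), and a level-2 icosphere (162 vertices, 320 faces). Sizes were
chosen to keep the full suite in tens of seconds while covering every code
path; randomized-scene tests (structural validity over 100 scenes,
round-trip over 25) draw small scenes from this fixture family under fixed
seeds. `inst/extdata/synthetic_vcg_loop.csv` is a *synthetic*
vectorcardiogram-like loop used in examples — generated data, not a
recording.

What passing tests establish: structural validity of every emitted file,
exact inversion of the codec, exact recovery of trees/topology/metadata,
the half-step quantization bound, and the size benefit of resource
sharing. What they cannot establish is visual correctness in a PDF viewer
— that a viewer renders the scene as intended is inherently a manual
check; `u3d_pdf_embedding_notes()` documents the recipe (LaTeX + media9 or
iText, then Adobe Acrobat Reader) for performing it.

## Numerical and degenerate-input choices

* Quantization overflow (|rounded coordinate| ≥ 2³¹) aborts with advice to
  rescale rather than silently wrapping.
* An empty scene (no models) is a valid file; an *empty referenced
  geometry* is an error at model-attachment time.
* A line set with positions but zero edges is valid (zero segments).
* Mesh corner indices and shading ids in single-entry uniform contexts
  cost zero bits — degenerate uniform contexts are legal on both sides.
* String payloads are UTF-8 with a 16-bit length prefix; longer strings
  are rejected, not truncated.
* The group-path separator is `/`; a leading or trailing slash is
  tolerated, interior empty names are not.

## Limitations

Textures (and with them simulated volume rendering), animation,
progressive level-of-detail streams, per-vertex colours, bones and U3D
glyphs are out of scope, as is PDF document authoring itself — standard
tools (LaTeX/media9, iText) handle that step well, and separating model
generation from document authoring is the established workflow. The
reader decodes only what the encoder emits. PDF viewers other than Adobe
Acrobat Reader render 3D annotations inconsistently or not at all; that
is a property of the viewer landscape, not of the exported files.
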