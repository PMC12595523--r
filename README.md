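# wormsight

Map neuron-class-resolved gene expression onto a 3D model of the
*Caenorhabditis elegans* nervous system — headlessly.

Single-cell RNA-seq atlases of the worm nervous system (the CeNGEN
consortium's thresholded L4 matrices) report expression per
*transcriptomic neuron class* (AVK, RIM, VA, ...), while 3D anatomical
models such as the openworm.org Virtual Worm carry one mesh per
*individual neuron* (AVKL, AVKR, VA1..VA12). `wormsight` bridges the
two: it resolves class labels to the 302 neurons of the adult
hermaphrodite, partitions neurons by which subset of a multi-gene query
each one expresses, colors and renders the anatomy accordingly, and
exports the colored scene in standard 3D formats. It is aimed at
neuroscientists who want publication-style expression overlays, or
reproducible sender/receiver maps of peptidergic signaling, without a
GUI in the loop.

## The core computation

Given an expression matrix $x_{g,k} \ge 0$ over genes $g$ and neuron
classes $k$, an ordered query $G = (g_1, \dots, g_m)$ and a strict
detection cutoff $\tau$ (default 0, since CeNGEN matrices are already
thresholded), every neuron cell $c$ with class $k(c)$ gets an
**expression signature**

$$s(c) \in \{0,1\}^m, \qquad s(c)_i = \big[\, x_{g_i,\,k(c)} > \tau \,\big].$$

Grouping cells by exact signature yields a disjoint **signature
partition**; cells with $s(c) = 0$ form the background. With the query
(*cat-1*, *tdc-1*, *tbh-1*) the three non-empty blocks are exactly the
classic green (cat-1 only), blue (cat-1 + tdc-1) and orange (all three)
monoamine co-expression groups. A ligand/receptor **sender–receiver
overlay** is the $m = 2$ special case with the four signatures renamed
to roles: sender (ligand only, dark red), receiver (receptor only,
light blue), both, none.

Colors are assigned deterministically: blocks ordered by (number of
expressed genes, then the signature as a binary number) take successive
palette colors, so deeper co-expression gets later colors; explicit
user maps override. Scenes render with a built-in deterministic
flat-shading rasterizer (identical input gives byte-identical PNGs),
and export to glTF 2.0, OBJ+MTL, or per-object PLY with colors
quantized to 8 bits per channel, so export → import round-trips are
exact.

## Worked example

A synthetic worm (6 soma spheres on a translucent body tube) with the
nested three-gene design `g1 ⊃ g2 ⊃ g3`:

```r
library(wormsight)

dir  <- file.path(tempdir(), "demo")
spec <- fixture_spec(design = nested_design())
model_files <- make_synthetic_model(spec, dir)
expr <- make_synthetic_expression(spec, file.path(dir, "expression.csv"))

tab    <- load_expression_csv(expr$csv_path, threshold_label = "synthetic")
roster <- load_roster()
part   <- partition_by_signature(compute_signatures(tab, c("g1", "g2", "g3"), roster))
part
#> <signature_partition> 3 gene(s): g1, g2, g3
#>   [100] {g1}: 2 cells
#>   [110] {g1+g2}: 2 cells
#>   [111] {g1+g2+g3}: 2 cells
#>   background: 296 cells
```

Each block is a set of individual neurons: the `100` block (g1 only) is
the AVK pair, `110` the RIM pair, `111` the RIC pair, and the other 296
of the 302 neurons express none of the query. Color, render, export,
and identify:

```r
cm    <- assign_colors(part, explicit = list("100" = "green", "110" = "blue",
                                             "111" = "orange"))
model <- load_model(model_files$obj_path, roster)
scene <- build_scene(model, cm, part)
cam   <- camera_spec(preset = "whole_worm", model = model, width = 320, height = 240)
render_scene(scene, cam, file.path(dir, "worm.png"))   # deterministic flat PNG
export_scene(scene, file.path(dir, "worm.gltf"), "gltf")

pick_neuron(scene, c(50, 0, 8))
#> $cell
#> [1] "RIML"
#> $distance
#> [1] 0
```

The picked point lies inside the RIML soma sphere, so the distance is
0 — the headless analogue of clicking that neuron in a viewport. The
per-cell result table:

```r
df <- partition_to_csv(part, cm, roster)
head(df[df$color_hex != "", ], 6)
#>     cell_name class_name signature_bits color_hex role
#> 69       AVKL        AVK            100   #00FF00
#> 70       AVKR        AVK            100   #00FF00
#> 192      RICL        RIC            111   #FFA500
#> 193      RICR        RIC            111   #FFA500
#> 200      RIML        RIM            110   #0000FF
#> 201      RIMR        RIM            110   #0000FF
```

The same workflow is available from a shell via the installed launcher
(`system.file("cli", "wormsight.R", package = "wormsight")`), with
subcommands `simulate | query | render | export | roster | pick`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","wormsight.R",package="wormsight"))')" \
  simulate --out demo --design nested
```

Real CeNGEN matrices load the same way: `load_expression_csv()`
auto-detects orientation against the class vocabulary, flags
non-neuronal columns, and `lookup_gene(tab, "FLP-1")` resolves queries
case-insensitively with edit-distance suggestions on a miss.

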