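# cofoldviz

Batch visualization of cotranscriptional RNA folding trajectories.

RNA folds while it is transcribed: the chain grows, helices form, compete
and are displaced, and the structural ensemble keeps shifting long after
the polymerase has finished. Simulators of this process write tables of
`(id, time, occupancy, structure, energy)` rows — one structure lineage per
id, one occupancy per structure and time point — that are nearly impossible
to read by eye. cofoldviz renders such tables, for people who run
cotranscriptional folding simulations, as composite SVG figures and frame
series:

* a **treemap panel** per time point, one rectangle per displayed
  structure with area proportional to its occupancy (most occupied
  leftmost), each rectangle holding a deterministic 2D drawing of the
  structure;
* an **overview strip** of the dominant structure's per-nucleotide colors
  over the whole simulation, on a composite time axis that is linear during
  transcription and logarithmic afterwards, with the end of transcription
  pinned at 75% of the axis width;
* annotations for the displayed time point and the sum of displayed
  occupancies.

Two small formulas do the scientific work. Base pairs `(i, j)` are colored
by their *imaginary center* `c = (i + j) / 2` through the hue map

    H(c) = (floor(c / 9) + 160 c) mod 360

so each 0.5-nt center shift advances the hue by 80°, cycling through nine
base colors — a perfect helix is one color, and identically centered
helices share a color across panels and frames. The time axis maps

    x(t) = 0.75 (t − t0) / (t_end − t0)                      for t ≤ t_end
    x(t) = 0.75 + 0.25 log(t / t_end) / log(t_max / t_end)   for t > t_end

so the short cotranscriptional phase always gets three quarters of the
width regardless of how long the simulation ran afterwards.

## Worked example

```r
library(cofoldviz)

traj <- generate_fixture("helix-competition", seed = 1,
                         n_timepoints = 12, final_length = 30)
traj
#> <fold_trajectory> 32 records, 12 time points, max length 30 nt, with sequence
#>   time range: 0.0666667 .. 600 s

te <- transcription_end_time(traj)   # 0.6 s
time_axis(traj)
#> <time_axis> mode composite: t0 = 0.0666667, t_end = 0.6 (x = 0.75), t_max = 600

slice_at_time(traj, te)
#> <time_slice> t = 0.6 s, 3 structures, sum of occupancies 1.0000
summary_table(slice_at_time(traj, te))
#>   id time occupancy                      structure energy
#> 1  1  0.6 0.8335012 ..((((((................))))))     -9
#> 2  0  0.6 0.1264988 ((((....))))..................     -6
#> 3  2  0.6 0.0400000 ..............................      0

hue_for_center(c(1.5, 2.0))          # 240 320  (one 80-degree step)

write_svg(render_frame(traj, te), "frame.svg")
render_animation(traj, render_config(speed = 4), outdir = "frames")
#> <fold_animation> 12 frames at 4 fps (250 ms/frame)
```

At `t = 0.6` s (the end of transcription) the ensemble has already moved:
the 3'-reaching helix (id 1) holds 83% of the ensemble, the early
5'-proximal hairpin (id 0) is down to 13%, and the treemap in `frame.svg`
shows exactly that — a large left tile, a small right one, the black
end-of-transcription line at 75% of the strip width and the red cursor on
top of it.

Real simulation output is read the same way:

```r
traj <- parse_trajectory("simulation.drf")
traj <- trajectory(traj$records, sequence = load_sequence("sequence.fasta"))
```

A command-line wrapper with `render`, `animate`, `validate`, `summary` and
`fixtures` subcommands is installed at
`system.file("cli", "cofoldviz.R", package = "cofoldviz")`.

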