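# notgate

Discovery of NOT-gated CAR T-cell target combinations from cell-surface
proteomics, healthy-tissue proteomics and CRISPR dependency screens.

## The problem

Every candidate CAR T-cell surface antigen on a tumour is also expressed on
at least one essential healthy cell type, so on-target, off-tumour toxicity
cannot be avoided by antigen choice alone. A NOT-gate CAR T-cell carries a
second, inhibitory receptor (iCAR): the T-cell kills only cells that express
the activating **principal** antigen AND lack the **iCAR** antigen. If the
iCAR antigen is present on every healthy tissue that expresses the principal
antigen — but absent from the tumour — the gate restores tissue specificity,
and even essential housekeeping proteins become usable targets (targeting
essential genes limits antigen-escape variants).

`notgate` turns that idea into a reproducible pipeline for anyone selecting
immunotherapy targets from three tabular inputs:

1. a **tumour surfaceome** — one row per surface protein with median
   expression on a 0–5 AU scale and extracellular-domain (ECD) length;
2. a **healthy-tissue proteome matrix** — protein × tissue expression with
   per-tissue flags (`essential`, `t_cell`);
3. a **gene × cell-line dependency table** of Chronos scores (more negative
   = stronger loss of viability on knockout), collapsed per gene by the
   median over the disease cell lines;
4. optionally, an **in-vivo CRISPR screen** gene list.

## The rules and the score

A principal target must be (1) expressed on the tumour surface membrane,
(2) carry an extracellular domain, (3) be essential for tumour viability,
and (4) be absent from T cells (no fratricide). An iCAR target must
(5) not be expressed on tumour cells, (6) carry an extracellular domain,
and (7) be co-ordinately expressed with the principal in **every** healthy
tissue where the principal is on. Default thresholds: expression > 3.5 AU
(strict), ECD > 175 aa (strict), Chronos ≤ −0.25 (inclusive).

Candidates are ranked by a vector score. With `e` the min–max-normalised
surface expression and `s` the min–max-normalised essentiality (−Chronos),

    score = sqrt(e² + s²),   0 ≤ score ≤ √2,

so "highly expressed AND essential" ranks first and Pareto order is
preserved. Rule 7 is a set-coverage test: an iCAR partner is *feasible* when
its expression exceeds the detection threshold in all of the principal's
ON tissues (coverage = 1); missing measurements never count as coverage.

## Worked example

Everything below is computed from a synthetic fixture with planted ground
truth (no downloads). The generator plants 3 principals that pass all rules,
and for each principal 4 feasible + 6 partial iCAR partners:

```r
library(notgate)
bundle <- generate_fixture(fixture_spec(seed = 1))
paths  <- write_fixture(bundle, "fixtures")
surf <- read_surfaceome(paths[["surfaceome"]])
tiss <- read_tissue_proteome(paths[["tissue_matrix"]], paths[["tissue_meta"]])
ess  <- aggregate_chronos(read_dependency(paths[["dependency"]]), bundle$disease_lines)
cfg  <- filter_config()

principals <- filter_principal(surf, ess, tiss, cfg)
rank_targets(principals)
#>     gene median_expression   chronos expression_norm essentiality_norm     score rank
#> 1 PRIN01          4.800000 -1.567403       1.0000000         1.0000000 1.4142136    1
#> 2 PRIN03          4.343712 -0.732862       0.2088305         0.0000000 0.2088305    2
#> 3 PRIN02          4.223274 -0.842304       0.0000000         0.1311404 0.1311404    3

icars <- filter_icar(tiss, surf, read_ecd_catalog(paths[["ecd_catalog"]]), cfg)
count_combinations(principals, icars)
#> NOT-gate combinations: 3 principals x 136 iCARs = 408 theoretical pairs

pairs <- find_icar_partners("PRIN01", icars, tiss, cfg)
head(pairs[, 1:7], 6)
#>   principal    icar icar_ecd n_covered n_uncovered coverage feasible
#> 1    PRIN01 IC01F01      748         5           0      1.0     TRUE
#> 2    PRIN01 IC01F02      317         5           0      1.0     TRUE
#> 3    PRIN01 IC01F03      260         5           0      1.0     TRUE
#> 4    PRIN01 IC01F04      666         5           0      1.0     TRUE
#> 5    PRIN01 IC01P01      373         4           1      0.8    FALSE
#> 6    PRIN01 IC01P04      607         4           1      0.8    FALSE
```

Reading: `PRIN01` dominates both ranking axes (score √2, rank 1). Of its
iCAR candidates, exactly the four planted partners (`IC01F*`) cover all 5
tissues where `PRIN01` is on (`coverage = 1`, feasible); the partial
partners miss at least one tissue and are reported as near-misses, never as
feasible. `partner_heatmap_table(pairs, tiss, ...)` exports the long-format
expression table behind the co-expression heatmap (principal on the first
row, one `tumour` column that is 0 for every feasible iCAR).

## Command line

```sh
exec/notgate simulate --seed 1 --out fixtures/
exec/notgate run      --config cfg.yaml          # full pipeline + manifest
exec/notgate filter   --config cfg.yaml --out principals.tsv \
                      --icars icars.tsv --explain rejected.tsv
exec/notgate rank     --in principals.tsv --out ranked.tsv
exec/notgate partners --principal PRIN01 --config cfg.yaml \
                      --out pairs.tsv --heatmap heatmap.tsv
exec/notgate combos   --config cfg.yaml --json
```

The YAML config schema is documented in `?run_pipeline`. All outputs are
TSV/JSON with fixed column order and formatting; rerunning an identical
config yields bit-identical tables, and `manifest.json` records input/output
checksums and per-stage row accounting (input = accepted + rejected).

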