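# exonLDM

Gene- and isoform-level RNA-Seq expression from **exon-level fragment
counts**, using a latent Dirichlet–Multinomial model fitted by variational
EM — plus the matching generative simulator.

## Who this is for

Anyone quantifying transcript expression from RNA-Seq libraries aligned to
a known transcriptome annotation who needs (a) reads shared between
isoforms deconvolved, (b) isoform- and exon-specific coverage bias learned
per gene rather than imposed by a global bias model, and (c) a measurement
variance alongside every estimate. The model exploits the technical
replicate structure of multiple *lanes* of a single library: each lane gets
its own isoform-fraction vector drawn from a shared Dirichlet prior, and
that between-lane variation identifies the per-exon sequencing rates.

## The model

For one gene with $K$ isoforms and $E$ exon units, per lane $l$:

1. $\theta_l \sim \mathrm{Dirichlet}(\alpha)$ — isoform fractions;
2. each observed exon occurrence draws an isoform label
   $t \sim \mathrm{Multinomial}(1, \theta_l)$;
3. and an exon unit $e \sim \mathrm{Multinomial}(1, \beta^{t})$, where row
   $\beta^k$ is isoform $k$'s exon-specific read sequencing rate, zero off
   its exon support.

The observed data are length-normalized exon fragment counts $n_{li}$.
Genes are expanded beforehand into disjoint exon units, junction units of
length $2(L-1)$ that catch splice-spanning reads, and an appended **noise
isoform** covering all units that absorbs reads from noise and undiscovered
isoforms. Inference is variational EM: Dirichlet factors $\eta_l$ and
responsibilities $\lambda$ in the E-step, closed-form $\beta$ and
Newton–Raphson $\alpha$ in the M-step. Expression is reported as

$$\langle\theta_k\rangle = \frac{\alpha_k}{\sum_k \alpha_k},\qquad
  f_k = \frac{10^9\,\theta_k}{N_s}\sum_{l,i} n_{li}\ \ (\text{FPKM}),$$

with variances from Monte-Carlo draws $\theta^{(m)}\sim\mathrm{Dirichlet}(\hat\alpha)$.
See `vignettes/exon-ldm-methods.Rmd` for assumptions, tuning parameters and
design decisions.

## Worked example

Simulate a 3-lane paired-end library for a toy two-isoform gene and
quantify it end to end:

```r
library(exonLDM)

gtf <- "toy.gtf"
write_annotation(list(gene_from_exons("toy", "chr1", list(
  I1 = data.frame(start = c(100, 700), end = c(300, 900)),
  I2 = data.frame(start = c(100, 400, 1000), end = c(300, 600, 1200))))), gtf)

gm <- expand_gene_model(parse_annotation(gtf)$toy, read_length = 50)
gm
#> gene_model toy : 7 units ( 3 junction ), 3 isoforms (incl. noise), L = 50

hp <- random_hyperparameters(gm, seed = 8)
tr <- simulate_reads(gm, hp$alpha, hp$beta, mode = "paired", lanes = 3,
                     fragments_per_lane = 2000, seed = 42,
                     sam_path = "toy.sam")
res <- run_quantify(gtf, setNames(tr$files, rownames(tr$raw)),
                    read_length = 50, out_dir = "toy_out", M = 100, seed = 1)
res$expression
#>   gene_id isoform_id is_noise theta_mean    fpkm fpkm_variance
#> 1     toy         I1    FALSE   0.819116 4726466     5.400e+11
#> 2     toy         I2    FALSE   0.179753 1037210     5.400e+11
#> 3     toy      noise     TRUE   0.001131    6527     3.915e+05
```

Reading the output: `theta_mean` is the estimated fraction of the gene's
transcripts attributable to each isoform. The realized per-lane fractions in
this simulation averaged (0.808, 0.192), so the fit recovers them closely,
and the noise isoform — which received no simulated reads — absorbs only
0.1%. `fpkm` is each isoform's expression; the gene total (`res$genes`)
sums the annotated isoforms, excluding noise by default. `fpkm_variance`
is the Monte-Carlo measurement variance; the two annotated isoforms share
a large variance (their fractions are anticorrelated on the simplex) while
the gene total's variance is small because those fluctuations cancel.

`toy_out/` holds TSV tables (isoform and gene expression, expanded gene
models, exon counts) plus a JSON run report capturing every setting, so a
run is reproducible from its own output.

A command-line wrapper with verbs `quantify`, `simulate`, `expand-model`
and `count` is installed at `exec/exonldm`, e.g.

```sh
Rscript <library>/exonLDM/exec/exonldm quantify \
  --annotation genes.gtf --alignments lane1.bam,lane2.bam \
  --read-length 50 --out results/
```

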