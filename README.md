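# meripmix

Detection of enriched regions in MeRIP-Seq experiments by mixture
negative-binomial modelling of transcriptome bin counts.

MeRIP-Seq (methylated RNA immunoprecipitation sequencing) profiles RNA
modifications such as m6A with a pair of libraries: an antibody-enriched
IP sample and an input sample measuring baseline transcript abundance.
`meripmix` tiles the concatenated union exons of expressed genes with
200 bp bins, counts the 5' positions of IP and input reads per bin, and
models the IP counts as

    P(Y_j) = (1 − π_s) · NB(a, a/(a+μ_j))  +  π_s · P_signal(Y_j)

where the background mean μ_j is regressed on the bin's input count
(robust linear model or penalized spline on the log-log scale, selected
by BIC) and the signal density is the exact convolution of the
background NB with a signal NB, offset by a minimum signal count k that
is optimized over 0..10 by BIC. A two-component signal variant (2S) is
fit alongside and the mode is chosen by BIC. Parameters are estimated
by EM; enriched bins are selected by direct posterior-probability FDR
control, merged along transcript coordinates, and written as BED12 with
junction-aware blocks. The fitted signal proportion π_s doubles as an
intuitive indicator of global treatment effect.

See `vignettes/meripmix-methods.Rmd` for the full model description,
estimation details and known limitations.

## Worked example

The package ships a read-level simulator, so a complete run needs no
external data:

```r
library(meripmix)

## simulate a small read-level dataset (GTF + IP/input SAM)
dataDir <- file.path(tempdir(), "meripmix-demo")
d <- writeSyntheticDataset(dataDir, seed = 1)

## run the full pipeline
cfg <- runConfig(d$ip, d$input, d$gtf, strandedness = "forward",
                 outputDir = file.path(dataDir, "out"), seed = 1)
res <- runPipeline(cfg)

res$fit
#> MixtureFit, mode 1S
#>   piS = 0.1695 | k = 9 | BIC 1S = 736.268 | BIC 2S = 750.492

res$summary
#>   dataset   pi_s   BIC_1S   BIC_2S optim_k optim_reg
#> 1  sample 0.1695 736.2675 750.4925       9       rlm

head(res$regions, 3)
#> GRanges object with 3 ranges and 9 metadata columns:
#>     seqnames    ranges strand |      geneId     score     nBins   txStart
#>        <Rle> <IRanges>  <Rle> | <character> <integer> <integer> <integer>
#>   1    chrS1 2700-3099      - |        g002        73         2       400
#>   2    chrS1 4200-4599      + |        g003        36         2       200
#>   3    chrS1 6100-6299      - |        g004        73         1       200
#>   ...

readLines(file.path(dataDir, "out", "regions.bed"), n = 2)
#> [1] "chrS1\t2699\t3099\tg002:1\t73\t-\t2699\t3099\t0\t1\t400,\t0,"
#> [2] "chrS1\t4199\t4599\tg003:1\t36\t+\t4199\t4599\t0\t1\t400,\t0,"
```

The output directory also receives `summary.tsv`, a goodness-of-fit
frequency table `gof.tsv` (observed vs re-simulated counts per mode)
and `run.log`. The truth generated at `piS = 0.15` is recovered as
`piS = 0.1695` on this 90-bin toy; at realistic bin numbers the
estimate tightens (see below).

A command-line front end with the same options is installed at
`inst/scripts/meripmix` (`meripmix run --ip ip.bam --input in.bam
--gtf genes.gtf --strandedness reverse -o out/`).

## Package layout

- `R/annotation.R` — GTF parsing, union exons, TPM filter, transcript
  coordinate system, bin construction
- `R/counting.R` — BAM/SAM reading, 5'-position events, strand-aware
  bin and gene counting
- `R/background.R` — input-count grouping, robust moments, NB size
  estimation, RLM/GAM mean regression
- `R/mixture.R` — convolution densities, EM fitters, k optimization,
  mode selection
- `R/calling.R` — posterior probabilities, direct-posterior FDR
  selection, region merging, BED12 I/O
- `R/simulate.R` — generative simulators, goodness-of-fit table,
  fixture writers
- `R/pipeline.R` — configuration and the end-to-end runner
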