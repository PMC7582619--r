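# kaspforge

Design and score Kompetitive Allele-Specific PCR (KASP) genotyping assays
from the variant calls of two inbred lines mapped to a shared reference.

## What problem this solves

Breeding programs need cheap, robust SNP markers that distinguish two
parental lines - for example a heat-sensitive and a heat-tolerant maize
inbred whose F2 progeny are being mapped for stress tolerance. Deep
sequencing of both lines against a reference yields hundreds of thousands
of variant calls; only a fraction of those sites can be turned into a
working KASP assay, and turning them requires careful flanking-sequence
screening and allele-specific primer construction. `kaspforge` covers the
whole post-variant-calling workflow:

1. **Compare** the two lines' VCFs site by site (`diff_sites`): sites
   unique to one line, concordant-shared between both (polymorphic against
   the reference but identical between lines), or discordant-overlapping
   (same position, different alleles).
2. **Summarise** the panel (`chrom_variant_rates`, `window_densities`,
   `ts_tv_ratio`, `impact_summary`, `mapping_percentages`).
3. **Filter** candidate SNPs for assay suitability (`apply_filter`): no
   InDel within the 101-bp window (a), at most 4 ambiguous flank bases
   (b), depth >= 5 across the window (c), no >4-copy tandem repeat of any
   1-5 bp motif (d), homozygous-alternate genotype (e); then cull SNPs
   within 20 bp of each other (`proximity_cull`) and pick an evenly spaced
   genome-wide panel, 10 per chromosome (`select_genomewide`).
4. **Design** the assays (`design_assays`): two allele-specific forward
   primers ending on the SNP base, carrying the universal FAM
   (`GAAGGTGACCAAGTTCATGCT`) and HEX (`GAAGGTCGGAGTCAACGGATT`) tails, plus
   a common reverse primer, amplicon < 100 bp, Tm from the unified
   nearest-neighbor model (target 57 +/- 3 degC on the untailed portion),
   named `MKAM_<chrom>_<serial>`.
5. **Score** genotyping plates (`classify_marker`, `summarize_panel`):
   per-marker status (polymorphic / monomorphic / partial / failed) from
   discrete allele calls, and the panel conversion metrics - design
   success rate = designed / selected, work success rate = (designed -
   failed) / designed, polymorphic rate.

A seeded synthetic-data generator (`fixture_spec`, `simulate_fixture`,
`simulate_f2_calls`) produces complete miniature studies - genome, two
VCFs with exactly known site classes and planted filter violations, depth
track, F2 plates - so every stage is testable with no external data.

## Worked example

```r
library(kaspforge)

spec <- fixture_spec(seed = 42)          # 3 x 1 Mb synthetic study
fx   <- simulate_fixture(spec)

pa  <- filter_pass(fx$vcf_a, keep_unfiltered = FALSE)
pb  <- filter_pass(fx$vcf_b, keep_unfiltered = FALSE)
cls <- diff_sites(pa, pb)
summarize_comparison(cls)
#> Two-line site comparison: 990 distinct sites
#>   unique_a             360
#>   unique_b             300
#>   concordant_shared    250
#>   discordant_overlap   80

ua   <- cls[cls$class == "unique_a", ]
snps <- pa[paste(pa$chrom, pa$pos) %in% paste(ua$chrom, ua$pos) & pa$is_snp, ]
res  <- apply_filter(snps, fx$genome, pa[!pa$is_snp, c("chrom", "pos")],
                     fx$depth_track)
res$report$after_e                       # 300 of 350 SNPs survive a-e
sel  <- select_genomewide(proximity_cull(res$survivors),
                          contig_lengths(fx$genome), per_chrom = 10)
des  <- design_assays(sel, names(fx$genome))
des$assays[1, c("marker_id", "allele_x", "allele_y", "amplicon_len")]
#>     marker_id allele_x allele_y amplicon_len
#> 1 MKAM_01_001        G        A           41
des$assays$primer_x[1]
#> "GAAGGTGACCAAGTTCATGCTAACTTCGATATTCGCCGGTTAG"   # FAM tail + ...G
des$assays$primer_y[1]
#> "GAAGGTCGGAGTCAACGGATTAACTTCGATATTCGCCGGTTAA"   # HEX tail + ...A

sim <- simulate_f2_calls(des$assays$marker_id, spec)
summarize_panel(classify_panel(sim$table), selected_sites = nrow(sel))
#> KASP panel: 30 assays designed from 30 selected SNP sites
#>   polymorphic  17
#>   monomorphic  2
#>   partial      9
#>   failed       2
#>   design success 100.0%, work success 93.3%, polymorphic 56.7%
```

The two forward primers are identical apart from their final (3') base,
which is the SNP allele each reports; the assay's amplicon stays under
100 bp so the PCR needs no extension step. The panel summary decomposes
the SNP conversion rate into its design and work components.

A command-line wrapper over the same functions ships in
`inst/scripts/kaspforge.R` with subcommands `simulate`, `compare`,
`filter`, `design` and `genotype`:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/kaspforge.R", package="kaspforge"))') \
    filter --vcf-a line_a.vcf --vcf-b line_b.vcf --ref genome.fa \
    --depth depth.bedgraph --per-chrom 10 --out candidates.tsv --report report.json
```

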