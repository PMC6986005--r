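#!/usr/bin/env Rscript
## Quadripartite structure and summary statistics of a full-scale synthetic
## plastome (91,210 / 14,058 / 2 x 31,844 bp; 107 genes), plus the ycf2
## repeat case: a 6,930 bp CDS carrying 45 bp and 48 bp tandem duplications
## that short-read assemblies are prone to collapsing.

library(chloroplastr)

dir.create("results", showWarnings = FALSE)

full <- generate_genome(plastome_spec(scale = 1, seed = 7L))
part <- partition_quadripartite(full$genome)
summ <- genome_summary(full$genome, part,
                       reads = list(count = 239086, total_nt = 2579414638),
                       annotation = full$annotation)
print(summ)
write_tsv(as.data.frame(summ), "results/genome_summary_full_scale.tsv")
write_partition_bed(part, "results/partition_full_scale.bed")

gcd <- region_gc(full$genome, part)
write_tsv(gcd, "results/region_gc_full_scale.tsv")
cat(sprintf("overall GC %.2f%% (length-weighted across LSC/SSC/2xIR)\n",
            attr(gcd, "overall")))

ycf2 <- gene_cds(full$genome, full$annotation, "ycf2")
reps <- find_direct_repeats(plastome(ycf2, circular = FALSE),
                            window = 100, min_len = 40)
write_tsv(reps, "results/ycf2_direct_repeats.tsv")
cat(sprintf("ycf2: %d bp = %d codons; tandem duplications of %s bp at offsets %s\n",
            nchar(ycf2), nchar(ycf2) / 3,
            paste(sort(reps$length), collapse = " and "),
            paste(sort(reps$start1), collapse = ", ")))
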