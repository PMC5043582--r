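#!/usr/bin/env Rscript
# Variant census of the two singleton-gene allele sets: how many
# positions vary, and whether changes are synonymous, non-synonymous or
# non-coding.

suppressPackageStartupMessages(library(segscan))
meta <- jsonlite::read_json("results/systems_meta.json", simplifyVector = TRUE)

census_one <- function(name, fasta, cr, frame) {
  aln <- read_alignment(fasta)
  vc <- variant_census(aln, cr, frame)
  utils::write.table(vc, sprintf("results/census_%s.tsv", name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- table(factor(vc$effect, levels = c("non-coding", "synonymous",
                                               "non-synonymous", "indel")))
  cat(sprintf("%s: %d variable positions (%s)\n", name, nrow(vc),
              paste(names(counts), counts, sep = " = ", collapse = ", ")))
  vc
}

vc1 <- census_one("monomorphic", "results/monomorphic_alleles.fasta",
                  meta$monomorphic$coding_range, meta$monomorphic$frame)
vc2 <- census_one("point_mutation", "results/point_mutation_alleles.fasta",
                  meta$point_mutation$coding_range,
                  meta$point_mutation$frame)

cat("\nThe monomorphic set varies at only", nrow(vc1), "isolated positions,\n")
cat("consonant with a conserved housekeeping gene; the polymorphic set\n")
cat("carries", sum(vc2$effect == "non-synonymous"), "non-synonymous and",
    sum(vc2$effect == "synonymous"), "synonymous coding positions.\n")
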