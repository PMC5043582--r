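#!/usr/bin/env Rscript
# Build the synthetic study systems used throughout the analysis and
# write them, with their ground truth, under results/.
#
# Three systems mirror the three modes of gene-family variation studied:
#   (1) a nearly monomorphic singleton gene (housekeeping-like),
#   (2) a polymorphic singleton evolving by scattered point mutation,
#       plus repeat-unit copy-number variants of its cytoplasmic tail,
#   (3) a five-gene family in which a recipient carries two short
#       cassettes copied from a donor paralog (segmental exchange).

suppressPackageStartupMessages(library(segscan))
seed <- 1L
dir.create("results", showWarnings = FALSE)

mono <- monomorphic_family_fixture(seed = seed)
write_alignment(mono$aln, "results/monomorphic_alleles.fasta")

pm <- point_mutation_family_fixture(seed = seed)
write_alignment(pm$aln, "results/point_mutation_alleles.fasta")

fx <- cassette_family_fixture(seed = seed)
write_alignment(fx$aln, "results/cassette_family.fasta")
write_intervals(cbind(id = fx$recipient, fx$truth),
                "results/cassette_truth_intervals.tsv")

# repeat-unit copy-number variants: three distinguishable exon-scale
# units, the middle one expanding between one and three copies
units <- c(head_exon = "ATGGCTACCGTTGCTCCAGGTTCAG",
           repeat_exon = "GGTGAACTTCCTCAAGCTGGTAAGC",
           tail_exon = "CCTTCAGCTGAAACTGCTGCTTAAG")
cnv <- simulate_repeat_cnv(units, "repeat_exon", copy_range = 1:3,
                           flank_left = "head_exon",
                           flank_right = "tail_exon",
                           n_variants = 6, seed = seed)
writeLines(paste0(">", names(cnv$sequences), "\n", cnv$sequences),
           "results/repeat_cnv_variants.fasta")
utils::write.table(
  data.frame(variant = names(cnv$sequences), true_copies = cnv$truth),
  "results/repeat_cnv_truth.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

meta <- list(
  seed = seed,
  monomorphic = list(coding_range = mono$coding_range, frame = mono$frame),
  point_mutation = list(coding_range = pm$coding_range, frame = pm$frame),
  cassette = list(recipient = fx$recipient, donor = fx$donor,
                  background = fx$background),
  repeat_units = as.list(units), repeat_block = "repeat_exon")
jsonlite::write_json(meta, "results/systems_meta.json", auto_unbox = TRUE,
                     pretty = TRUE)

cat("Simulated systems written to results/:\n")
cat(" - monomorphic alleles:", length(aln_ids(mono$aln)), "sequences x",
    aln_length(mono$aln), "columns\n")
cat(" - point-mutation alleles:", length(aln_ids(pm$aln)), "x",
    aln_length(pm$aln), "\n")
cat(" - cassette family:", length(aln_ids(fx$aln)), "x",
    aln_length(fx$aln), "; true tracts",
    paste(sprintf("[%d,%d)", fx$truth$start, fx$truth$end), collapse = " "),
    "\n")
cat(" - repeat CNV variants with true copy numbers",
    paste(cnv$truth, collapse = ","), "\n")
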