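#!/usr/bin/env Rscript
# Repeat-unit decomposition of the cytoplasmic-tail-like CNV variants:
# greedy tiling by exon-scale units recovers each variant's copy number.

suppressPackageStartupMessages(library(segscan))
meta <- jsonlite::read_json("results/systems_meta.json", simplifyVector = TRUE)
units <- unlist(meta$repeat_units)

aln_lines <- readLines("results/repeat_cnv_variants.fasta")
heads <- grep("^>", aln_lines)
seqs <- vapply(seq_along(heads), function(i) {
  to <- if (i < length(heads)) heads[i + 1] - 1L else length(aln_lines)
  paste0(aln_lines[(heads[i] + 1L):to], collapse = "")
}, "")
names(seqs) <- sub("^>", "", aln_lines[heads])

truth <- utils::read.table("results/repeat_cnv_truth.tsv", header = TRUE,
                           sep = "\t")
res <- lapply(seqs, repeat_unit_decomposition, unit_library = units,
              repeat_unit = meta$repeat_block)
tab <- data.frame(variant = names(seqs),
                  units = vapply(res, function(r)
                    paste(r$units, collapse = "+"), ""),
                  copies = vapply(res, `[[`, 0L, "copy_number"),
                  remainder_nt = nchar(vapply(res, `[[`, "", "remainder")))
tab <- merge(tab, truth, by = "variant")
utils::write.table(tab, "results/repeat_cnv_decomposition.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(tab)
cat(sprintf("\nCopy number recovered exactly for %d / %d variants.\n",
            sum(tab$copies == tab$true_copies), nrow(tab)))
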