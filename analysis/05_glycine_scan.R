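#!/usr/bin/env Rscript
# Virtual glycine scan of both complexes: every binding-site residue is
# truncated to glycine in turn and the change in ligand-environment
# interaction energy (ddG, kcal/mol; positive = side chain favours
# binding) is recorded. The side-by-side table is the synthetic analog
# of a per-residue binding-contribution comparison between isoenzymes.

library(carbscan)

out <- "results/scan"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

template <- read_structure("results/fixtures/holo_template.pdb")
target <- read_structure("results/fixtures/apo_homolog.pdb")
res <- run_caix_pipeline(template, target, keep_waters = 272L,
                         settings = minimizer_settings(max_iter = 800L))

st <- res$scan_table
write.table(st, file.path(out, "glycine_scan_side_by_side.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

st_ord <- st[order(-st$ddg_model), ]
cat("Top model-side contributors (ddG, kcal/mol):\n")
for (i in seq_len(min(5L, nrow(st_ord)))) {
  cat(sprintf("  %-4s%-4d model %+6.2f   template (%s) %+6.2f\n",
              st_ord$resname_model[i], st_ord$resno[i],
              st_ord$ddg_model[i], st_ord$resname_template[i],
              st_ord$ddg_template[i]))
}
delta <- st$ddg_model - st$ddg_template
sw <- which(st$resname_model != st$resname_template)
cat("Substituted positions change their contribution by",
    paste(sprintf("%+.2f", delta[sw]), collapse = ", "), "kcal/mol\n")

# bar figure of the side-by-side scan
pdf(file.path(out, "glycine_scan.pdf"), width = 7, height = 4)
ord <- order(st$resno)
m <- t(as.matrix(st[ord, c("ddg_template", "ddg_model")]))
barplot(m, beside = TRUE, names.arg = st$resno[ord], las = 2,
        col = c("grey60", "steelblue"),
        ylab = expression(Delta * Delta * G ~ "(kcal/mol)"),
        xlab = "residue")
legend("topright", c("II-like template", "IX-like model"),
       fill = c("grey60", "steelblue"), bty = "n")
dev.off()
cat("Wrote", file.path(out, "glycine_scan_side_by_side.tsv"),
    "and glycine_scan.pdf\n")
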