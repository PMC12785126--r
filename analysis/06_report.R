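#!/usr/bin/env Rscript
# Stage 6: collated report.
#
# Gathers the funnel, the per-contrast up/down tallies, the Venn of the
# three contrasts and the browning-candidate ranking (identified novel
# lncRNAs ranked by beige-specific expression: mean beige FPKM over the
# mean of white and brown), plus a provenance block (seed, config
# checksum, package version).

library(adipolnc)

simdir <- file.path("results", "sim")
iddir <- file.path("results", "identify")
dedir <- file.path("results", "diffexp")
intdir <- file.path("results", "integrate")

needed <- c(file.path(iddir, "funnel.json"),
            file.path(dedir, "updown_table.tsv"),
            file.path(intdir, "venn.json"))
missing <- needed[!file.exists(needed)]
if (length(missing)) {
  stop("upstream outputs missing: ", paste(missing, collapse = ", "),
       " -- run the earlier stages first")
}

funnel <- jsonlite::read_json(file.path(iddir, "funnel.json"),
                              simplifyVector = TRUE)
updown <- utils::read.table(file.path(dedir, "updown_table.tsv"),
                            header = TRUE, sep = "\t")
venn <- jsonlite::read_json(file.path(intdir, "venn.json"),
                            simplifyVector = TRUE)

counts <- read_tsv_matrix(file.path(simdir, "counts.tsv"))
cfg_json <- jsonlite::read_json(file.path(simdir, "config.json"),
                                simplifyVector = TRUE)
novel_ids <- parse_gtf(file.path(iddir,
                                 "novel_lncrnas.gtf"))$transcripts$transcript_id
assembled <- parse_gtf(file.path(simdir, "assembled.gtf"))
lengths <- stats::setNames(assembled$transcripts$length,
                           assembled$transcripts$transcript_id)
fpkm <- compute_fpkm(counts, lengths)

beige <- rowMeans(fpkm[novel_ids, cfg_json$groups == "Beige",
                       drop = FALSE])
others <- rowMeans(fpkm[novel_ids, cfg_json$groups != "Beige",
                        drop = FALSE])
ranking <- data.frame(lncrna_id = novel_ids, beige_fpkm = beige,
                      other_fpkm = others,
                      beige_ratio = (beige + 0.01) / (others + 0.01))
ranking <- ranking[order(-ranking$beige_ratio), ]
utils::write.table(ranking, file.path("results",
                                      "browning_candidates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

report <- list(
  provenance = list(
    seed = cfg_json$seed,
    config_md5 = unname(tools::md5sum(file.path(simdir,
                                                "config.json"))),
    package_version = as.character(utils::packageVersion("adipolnc"))),
  funnel = funnel,
  updown = updown,
  venn = venn,
  top_browning_candidates = utils::head(ranking, 10))
jsonlite::write_json(report, file.path("results", "report.json"),
                     auto_unbox = TRUE, digits = 6, pretty = TRUE)

message("top browning candidates (beige-specific novel lncRNAs):")
print(utils::head(ranking, 5), row.names = FALSE)
message("report written to results/report.json")
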