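#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the structure of the three-adipocyte bulk RNA-seq design
# (white / brown / beige, two replicates each): a two-chromosome toy
# genome carrying coding genes, annotated lncRNAs, planted true-novel
# lncRNAs and five single-violation decoy classes, plus NB counts with
# planted group effects, a conservation track and a term map. Every
# downstream stage reads only the files written here.

library(adipolnc)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- file.path("results", "sim")

cfg <- simulation_config(seed = seed)
message("simulating with seed ", seed, " ...")
sim <- simulate_experiment(cfg, dir = out)

message("wrote ", length(sim$paths), " files under ", out)
message("feature classes:")
print(table(sim$truth$class))
message("samples: ", paste(colnames(sim$counts), collapse = ", "))
message("planted beige-up novel lncRNAs: ",
        sum(sim$truth_de$class == "true_novel" &
              sim$truth_de$mult_Beige > 1))
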