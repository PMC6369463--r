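#!/usr/bin/env Rscript
# Best-effort external validation on the public benchmark data sets
# (WPBC, WDBC and Heart-Cleveland from the UCI repository).  Requires
# network access and is NOT part of the test suite or acceptance run: the
# published per-dataset accuracies depend on preprocessing and
# cross-validation details that are not fully specified, so results here
# are indicative only.
#
#   Rscript scripts/reproduce_tables.R [--dataset wpbc|wdbc|heart] [--seed 42]

suppressPackageStartupMessages(library(rumselect))

args <- commandArgs(trailingOnly = TRUE)
dataset <- if ("--dataset" %in% args) args[which(args == "--dataset") + 1L] else "wpbc"
seed <- if ("--seed" %in% args) as.integer(args[which(args == "--seed") + 1L]) else 42L

base <- "https://archive.ics.uci.edu/ml/machine-learning-databases"
sources <- list(
  wpbc = list(url = paste0(base, "/breast-cancer-wisconsin/wpbc.data"),
              labelCol = 2L, drop = 1L, alpha = 0.1, beta = 0.25),
  wdbc = list(url = paste0(base, "/breast-cancer-wisconsin/wdbc.data"),
              labelCol = 2L, drop = 1L, alpha = 0.1, beta = 0.1),
  heart = list(url = paste0(base, "/heart-disease/processed.cleveland.data"),
               labelCol = 14L, drop = integer(0), alpha = 0.35, beta = 0.35)
)
src <- sources[[dataset]]
if (is.null(src)) stop("unknown dataset: ", dataset)

raw <- utils::read.csv(src$url, header = FALSE, na.strings = c("?", ""))
raw <- raw[stats::complete.cases(raw), ]
labels <- as.character(raw[[src$labelCol]])
keep <- setdiff(seq_along(raw), c(src$labelCol, src$drop))
values <- as.matrix(raw[keep])
colnames(values) <- paste0("a", seq_len(ncol(values)))

tab <- normalizeTable(DecisionTable(values, labels))
cfg <- selectionConfig(alpha = src$alpha, beta = src$beta, seed = seed)
trace <- selectFeatures(tab, cfg)
show(trace)
idx <- match(selectedAttributes(trace), attributeNames(tab))
cat("selected attribute indices (1-based):", paste(idx, collapse = ", "), "\n")
if (length(selectedAttributes(trace))) {
  print(evaluateSubset(tab, selectedAttributes(trace), cfg))
}
print(evaluateSubset(tab, attributeNames(tab), cfg))  # raw-data baseline
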