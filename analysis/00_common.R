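## Shared setup for the numbered analysis scripts: load the package, fix the
## study seed, and point every step at the same results directory.
suppressMessages({
  if (!requireNamespace("jumbophage", quietly = TRUE)) {
    stop("install the package first: R CMD INSTALL .")
  }
  library(jumbophage)
})

STUDY_SEED <- 1L
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

tsv <- function(df, name) {
  path <- file.path(RESULTS, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
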