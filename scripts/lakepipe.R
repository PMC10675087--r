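#!/usr/bin/env Rscript
# Thin shell entry point over the twinlake pipeline commands.
#
#   Rscript scripts/lakepipe.R <command> [--config cfg.json] [--seed N]
#                          [--out-dir DIR] [--log-level info|quiet]
#
# Commands: simulate, build-twin, fai, video, krige, slice, fuse, pipeline

suppressMessages(library(twinlake))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv) || argv[1] %in% c("-h", "--help")) {
  cat("usage: lakepipe.R <simulate|build-twin|fai|video|krige|slice|fuse|pipeline>",
      "[--config FILE] [--seed N] [--out-dir DIR] [--log-level LEVEL]\n")
  quit(status = if (length(argv)) 0 else 2)
}
command <- argv[1]
rest <- argv[-1]
arg <- function(flag) {
  i <- match(flag, rest)
  if (is.na(i) || i == length(rest)) NULL else rest[i + 1]
}

status <- tryCatch({
  config <- if (!is.null(arg("--config"))) run_config(arg("--config"))
            else run_config(list())
  if (!is.null(arg("--seed"))) config$seed <- as.integer(arg("--seed"))
  if (!is.null(arg("--out-dir"))) config$out_dir <- arg("--out-dir")
  if (!is.null(arg("--log-level"))) config$log_level <- arg("--log-level")
  fn <- switch(command,
               "simulate" = cmd_simulate, "build-twin" = cmd_build_twin,
               "fai" = cmd_fai, "video" = cmd_video, "krige" = cmd_krige,
               "slice" = cmd_slice, "fuse" = cmd_fuse,
               "pipeline" = run_pipeline,
               stop("unknown command: ", command))
  fn(config)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
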