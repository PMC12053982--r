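#!/usr/bin/env Rscript
# Thin command-line front end over the dancedsp package.
#
#   Rscript scripts/dance_dsp.R schedule   --config cfg.yaml --out DIR
#   Rscript scripts/dance_dsp.R simulate   --config cfg.yaml --out DIR
#   Rscript scripts/dance_dsp.R erds       --config cfg.yaml --out DIR
#   Rscript scripts/dance_dsp.R kinematics --config cfg.yaml --out DIR
#   Rscript scripts/dance_dsp.R report     --config cfg.yaml --out DIR
#
# `report` runs the full pipeline; the other subcommands run it with the
# later stages disabled where possible. --seed overrides the config seed.

suppressPackageStartupMessages({
  library(dancedsp)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L || !argv[1] %in%
      c("schedule", "simulate", "erds", "kinematics", "report")) {
  stop("usage: dance_dsp.R <schedule|simulate|erds|kinematics|report> [options]",
       call. = FALSE)
}
cmd <- argv[1]
opts <- parse_args(
  OptionParser(option_list = list(
    make_option("--config", type = "character", default = NULL),
    make_option("--seed", type = "integer", default = NULL),
    make_option("--out", type = "character", default = "dancedsp_out")
  )),
  args = argv[-1]
)

cfg <- if (is.null(opts$config)) list() else read_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed

if (cmd == "schedule") {
  cfg$write_bundle <- FALSE
  cb <- build_counterbalance_set(
    if (!is.null(cfg$sequences$A)) cfg$sequences$A else "LRUDRL",
    if (!is.null(cfg$sequences$B)) cfg$sequences$B else "RULURD")
  pair <- assign_participant_pair(cb, if (!is.null(cfg$participant_index))
    cfg$participant_index else 0)
  novel <- list(
    dance_sequence(if (!is.null(cfg$novel$A)) cfg$novel$A else "UDLRUD"),
    dance_sequence(if (!is.null(cfg$novel$B)) cfg$novel$B else "DRULLU"))
  sess <- schedule_session(pair, novel,
                           participant_index = if (!is.null(cfg$participant_index))
                             cfg$participant_index else 0,
                           seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  write_schedule(sess, opts$out)
  cat(sprintf("schedule: %d blocks, %d Go steps -> %s\n",
              length(sess$blocks), session_step_count(sess), opts$out))
} else {
  if (cmd == "simulate") cfg$skip_kinematics <- TRUE
  if (cmd == "erds") { cfg$skip_kinematics <- TRUE; cfg$write_bundle <- FALSE }
  if (cmd == "kinematics") cfg$write_bundle <- FALSE
  res <- run_pipeline(cfg, opts$out)
  cat(sprintf("%s: outputs in %s\n", cmd, res$out_dir))
}
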