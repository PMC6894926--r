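#!/usr/bin/env Rscript

# Thin shell wrapper over the actionrsa package.
#
#   actionrsa run-all   [--config cfg.yaml] [--out dir] [--seed n]
#   actionrsa simulate  [--seed n] [--out dir]     # events + arrangement data
#   actionrsa validate  <files...>                 # format checks
#   actionrsa config    [--out cfg.yaml]           # write a default config

suppressPackageStartupMessages(library(actionrsa))

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else "help"
rest <- args[-1]

flag <- function(name, default = NULL) {
  hit <- which(rest == paste0("--", name))
  if (length(hit) && hit < length(rest)) rest[hit + 1] else default
}

switch(cmd,
  "run-all" = {
    cfg_path <- flag("config")
    cfg <- if (!is.null(cfg_path)) read_pipeline_config(cfg_path) else
      pipeline_config(seed = as.integer(flag("seed", 1)),
                      out_dir = flag("out", "actionrsa_run"))
    if (!is.null(flag("out"))) cfg$out_dir <- flag("out")
    res <- run_pipeline(cfg)
    cat("pipeline complete; artifacts in", cfg$out_dir, "\n")
    print(glance(res$group_result))
  },
  "simulate" = {
    seed <- as.integer(flag("seed", 1))
    out <- flag("out", "actionrsa_sim")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    ev <- generate_trial_sequence(design_config(), seed = seed)
    write_events_tsv(ev, file.path(out, "events"))
    gt <- make_ground_truth(seed = seed)
    sess <- simulate_arranger(gt$true_rdm, seed = seed)
    write_session_json(sess, file.path(out, "arrangement_session.json"))
    write_rdm(gt$true_rdm, file.path(out, "true_rdm.tsv"))
    cat("wrote synthetic inputs to", out, "\n")
  },
  "validate" = {
    rep <- validate_inputs(rest)
    print(rep, n = Inf)
    if (!all(rep$ok)) quit(status = 1)
  },
  "config" = {
    out <- flag("out", "actionrsa_config.yaml")
    write_pipeline_config(pipeline_config(), out)
    cat("wrote default config to", out, "\n")
  },
  {
    cat("usage: actionrsa <run-all|simulate|validate|config> [options]\n")
  }
)
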