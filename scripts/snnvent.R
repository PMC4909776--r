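#!/usr/bin/env Rscript
# Thin command-line front end over the snnvent package.
#
#   Rscript scripts/snnvent.R calibrate [--out params.json]
#   Rscript scripts/snnvent.R run --wi 0.8 --mode closed_loop [--mbc 1.11]
#          [--on-t 15] [--duration 70] [--seed 1] [--trace trace.csv]
#          [--summary summary.json]
#   Rscript scripts/snnvent.R sweep-bits [--duration 30]
#   Rscript scripts/snnvent.R network-stats [--config file.yaml]
#          [--closed-loop] [--with-external]
#   Rscript scripts/snnvent.R fixtures --out-dir DIR [--seed 1]

suppressMessages(library(snnvent))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: snnvent.R <calibrate|run|sweep-bits|network-stats|fixtures> [options]")
cmd <- args[1]
opts <- list()
i <- 2
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opts[[key]] <- if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
    v <- args[i + 1]; i <- i + 1; v
  } else TRUE
  i <- i + 1
}
num <- function(key, default) if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
chr <- function(key, default) if (is.null(opts[[key]])) default else opts[[key]]

if (cmd == "calibrate") {
  plant <- calibrate_plant()
  rep <- attr(plant, "report")
  cat(sprintf("F_max = %.1f\nk_ex = %.5f\nRR(mbc) = %.3f + %.3f*mbc\n",
              rep$F_max, rep$k_ex, plant$rr_reg[1], plant$rr_reg[2]))
  out <- chr("out", NULL)
  if (!is.null(out)) {
    jsonlite::write_json(plant[setdiff(names(plant), "")], out,
                         auto_unbox = TRUE, digits = NA)
    cat("parameters written to ", out, "\n", sep = "")
  }
} else if (cmd == "run") {
  mode <- chr("mode", "closed_loop")
  wi <- num("wi", 1); mbc <- num("mbc", 1)
  sc <- scenario(
    name = sprintf("%s wi=%g mbc=%g", mode, wi, mbc), wi = wi,
    mbc_schedule = data.frame(t_s = 0, multiplier = mbc),
    controller_mode = mode,
    controller_on_t = num("on-t", 0),
    duration_s = num("duration", 60),
    seed = as.integer(num("seed", 1))
  )
  plant <- calibrate_plant()
  cfg <- if (mode == "off") NULL else reference_config(mode)
  run <- run_scenario(
    sc, plant, cfg,
    plasticity = if (mode == "closed_loop") reference_plasticity(),
    p_inj = if (mode == "closed_loop") reference_p_inj(wi, mbc)
  )
  s <- run$summary
  cat(sprintf("%d breaths | RR %.1f breaths/min | Vt %.2f mL | Min.Vent. %.0f mL/min | CV %.2f%%\n",
              s$n_breaths, s$rr, s$vt, s$minute_ventilation, s$cv_rr))
  if (!is.null(opts$trace)) write_trace_csv(run, opts$trace)
  if (!is.null(opts$summary)) write_summary_json(run, opts$summary)
} else if (cmd == "sweep-bits") {
  plant <- calibrate_plant()
  sw <- bit_accuracy_sweep(plant, duration_s = num("duration", 30))
  print(round(sw$rr, 2))
  cat("max |RR(width) - RR(", sw$ref_bits, "-bit)|:\n", sep = "")
  print(round(sw$max_dev, 2))
} else if (cmd == "network-stats") {
  ros <- if (!is.null(opts$config)) {
    read_roster_yaml(opts$config)
  } else if (isTRUE(opts[["closed-loop"]])) {
    build_closed_loop()
  } else {
    build_open_loop()
  }
  st <- connectivity_stats(ros, include_external = isTRUE(opts[["with-external"]]))
  cat(sprintf("C %d | N %d | MaxC %d | all-to-all %.1f%% | MaxC-to-all %.1f%% | 8-to-all %.1f%% | C/N %.1f\n",
              st$C, st$N, st$MaxC, st$all_to_all, st$maxc_to_all,
              st$eight_to_all, st$c_per_n))
} else if (cmd == "fixtures") {
  dir <- chr("out-dir", "fixtures")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plant <- calibrate_plant()
  f <- generate_fixtures(plant, seed = as.integer(num("seed", 1)))
  utils::write.csv(data.frame(time_s = f$time_s, volume_mL = f$volume,
                              volume_noisy_mL = f$volume_noisy),
                   file.path(dir, "eupneic_reference.csv"), row.names = FALSE)
  utils::write.csv(f$raster, file.path(dir, "test_raster.csv"), row.names = FALSE)
  cat("fixtures written to ", dir, "\n", sep = "")
} else {
  stop("unknown subcommand: ", cmd)
}
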