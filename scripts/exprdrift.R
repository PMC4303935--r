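#!/usr/bin/env Rscript
# Command-line front end for the exprdrift package.
#
# Subcommands:
#   simulate   generate a synthetic cohort (matrix.tsv + metadata.tsv)
#   all        run the full distance analysis on a matrix + metadata
#   profile | classify | associate | plot
#              stages of `all`; each runs the same pipeline and the named
#              outputs are among the files written (the stages share all
#              upstream computation, so they are bundled)
#
# Common options can also be read from a key=value config file via --config.

suppressPackageStartupMessages({
  library(exprdrift)
  library(optparse)
})

usage <- function() {
  cat("usage: exprdrift.R <simulate|all|profile|classify|associate|plot> [options]\n",
      "run 'exprdrift.R <subcommand> --help' for options\n")
  quit(status = 1L)
}

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L) usage()
cmd <- argv[1L]
argv <- argv[-1L]

read_config_file <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) trimws(x[2L])),
                  trimws(vapply(kv, `[[`, character(1L), 1L)))
}

if (cmd == "simulate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--n-genes", type = "integer", default = 2000L),
    make_option("--groups", type = "character",
                default = "normal:8:0:0.05,tumor:8:0.3:0.15,metastasis:8:0.25:0.12",
                help = "label:n:drift:dispersion, comma-separated [%default]"),
    make_option("--survival", action = "store_true", default = FALSE,
                help = "attach survival times coupled to distance-to-normal"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", type = "character", default = "."))), args = argv)
  groups <- lapply(strsplit(strsplit(opts$groups, ",")[[1L]], ":"),
                   function(g) list(label = g[1L], n = as.integer(g[2L]),
                                    drift = as.numeric(g[3L]),
                                    dispersion = as.numeric(g[4L])))
  des <- simulation_design(n_genes = opts$`n-genes`, groups = groups,
                           seed = opts$seed)
  coh <- generate_cohort(des)
  meta <- coh$metadata
  if (opts$survival) {
    cs <- compute_centers(coh$matrix, meta)
    prof <- distance_profiles(coh$matrix, cs)
    meta <- attach_survival(meta, prof, des)
  }
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_expression(coh$matrix, file.path(opts$out, "matrix.tsv"))
  write_metadata(meta, file.path(opts$out, "metadata.tsv"))
  cat("wrote", file.path(opts$out, "matrix.tsv"), "and metadata.tsv\n")
} else if (cmd %in% c("all", "profile", "classify", "associate", "plot")) {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--matrix", type = "character"),
    make_option("--metadata", type = "character"),
    make_option("--normal-label", type = "character"),
    make_option("--metric", type = "character", default = "pearson"),
    make_option("--transform", type = "character", default = "none"),
    make_option("--centroid-mode", type = "character", default = "naive"),
    make_option("--covariance", type = "character", default = "centered"),
    make_option("--inverse", type = "character", default = "pseudo"),
    make_option("--lambda", type = "double", default = 0),
    make_option("--test", type = "character", default = "welch"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--config", type = "character", default = NULL,
                help = "key=value file overriding defaults"),
    make_option("--out", type = "character", default = "."))), args = argv)
  if (!is.null(opts$config)) {
    cfg_file <- read_config_file(opts$config)
    for (k in names(cfg_file)) opts[[k]] <- cfg_file[[k]]
  }
  if (is.null(opts$matrix) || is.null(opts$metadata) ||
      is.null(opts$`normal-label`)) {
    stop("--matrix, --metadata and --normal-label are required",
         call. = FALSE)
  }
  cfg <- run_config(normal_label = opts$`normal-label`,
                    metric = opts$metric, transform = opts$transform,
                    centroid_mode = opts$`centroid-mode`,
                    covariance = opts$covariance, inverse = opts$inverse,
                    lambda = as.numeric(opts$lambda), test = opts$test,
                    seed = as.integer(opts$seed), out_dir = opts$out,
                    plots = cmd %in% c("all", "plot"))
  res <- tryCatch(run_pipeline(cfg, opts$matrix, opts$metadata),
                  error = function(e) {
                    cat("error:", conditionMessage(e), "\n", file = stderr())
                    quit(status = 1L)
                  })
  cat("wrote:\n"); cat(paste(" ", res$files), sep = "\n")
} else {
  usage()
}
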