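# Orchestration: seeded end-to-end runs, manifests, the acceptance
# experiment drivers and a small subcommand CLI.

#' Build a run configuration
#'
#' @param scenarios character vector of scenario names ([build_scenario()]).
#' @param seed top-level seed; every stage derives its own stream from it.
#' @param outdir output directory for artifacts and the manifest.
#' @param gen generator parameters ([generator_params()]); the seed field
#'   is overridden per run from `seed`.
#' @param rsp read-simulation parameters ([read_sim_params()]).
#' @param caller caller parameters (T, G, S, min_overlap).
#' @param mode "noise_free" (analytic tracks from truth) or "reads"
#'   (sampled reads).
#' @export
run_config <- function(scenarios = c("insertional", "reciprocal",
                                     "quasiterminal", "insertional_to_mid",
                                     "terminal_shift", "tert",
                                     "telomere_insertion_17"),
                       seed = 1L, outdir = tempfile("telorun"),
                       gen = generator_params(), rsp = read_sim_params(),
                       caller = list(T = 2.0, G = 10e3, S = 500,
                                     min_overlap = 0.5),
                       mode = c("noise_free", "reads")) {
  list(scenarios = scenarios, seed = as.integer(seed), outdir = outdir,
       gen = gen, rsp = rsp, caller = caller, mode = match.arg(mode))
}

#' Serialize / load a run configuration (round-trips unchanged)
#' @param config from [run_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$gen$seed <- as.integer(cfg$gen$seed)
  cfg$rsp$seed <- as.integer(cfg$rsp$seed)
  cfg$gen$n_chromosomes <- as.integer(cfg$gen$n_chromosomes)
  cfg
}

# simulate -> coverage -> normalize -> call for one scenario
scenario_calls <- function(sc, rsp, chroms = NULL,
                           caller = list(T = 2.0, G = 10e3, S = 500)) {
  chroms <- chroms %||% sc$genome$chromosomes$name
  chip <- simulate_chip_reads(sc$genome, rsp, "chip", chroms = chroms)
  inp <- simulate_chip_reads(sc$genome, rsp, "input", chroms = chroms)
  sub <- subset_genome(sc$genome, chroms)
  ct <- window_coverage(chip, sub)
  it <- window_coverage(inp, sub)
  ct <- normalize_track(ct, scaling_factor(nrow(chip), nrow(inp)), "input")
  calls <- call_domains(ct, it, T = caller$T, G = caller$G, S = caller$S)
  list(chip = ct, input = it, calls = calls,
       n_chip = nrow(chip), n_input = nrow(inp))
}

#' Run the full pipeline for a configuration
#'
#' Per scenario: generate the wild-type genome, build the scenario, derive
#' chip/input tracks (analytic or sampled), call domains on both genomes,
#' classify gained/lost/invariant through the liftover, and write
#' artifacts (BED calls, differential table, JSON manifest with digests
#' and summary metrics).
#' @param config from [run_config()].
#' @return the manifest (also written to `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- config$gen
  gen$seed <- derive_seed(config$seed, "genome")
  manifest <- list(config = config, scenarios = list())
  stage <- "generate_wt_genome"
  result <- tryCatch({
    genome <- generate_wt_genome(do.call(generator_params, gen))
    wt_tracks <- noise_free_tracks(genome, e = config$rsp$enrichment)
    wt_calls <- call_domains(wt_tracks$chip, wt_tracks$input,
                             T = config$caller$T, G = config$caller$G,
                             S = config$caller$S)
    for (nm in config$scenarios) {
      stage <- paste0("scenario:", nm)
      sc <- build_scenario(nm, genome, seed = derive_seed(config$seed, "sc", nm))
      if (config$mode == "noise_free") {
        tr <- noise_free_tracks(sc$genome, e = config$rsp$enrichment)
        n_chip <- NA; n_input <- NA
        calls <- call_domains(tr$chip, tr$input, T = config$caller$T,
                              G = config$caller$G, S = config$caller$S)
      } else {
        rsp <- config$rsp
        rsp$seed <- derive_seed(config$seed, "rsp", nm)
        res <- scenario_calls(sc, rsp, caller = config$caller)
        calls <- res$calls
        n_chip <- res$n_chip; n_input <- res$n_input
      }
      diff <- classify_differential(wt_calls, calls, sc$map,
                                    min_overlap = config$caller$min_overlap)
      files <- character()
      f_calls <- file.path(config$outdir, paste0(nm, "_calls.bed"))
      write_bed6(data.frame(chrom = calls$chrom, start = calls$start,
                            end = calls$end, name = "domain",
                            score = round(calls$mean_enrichment, 3),
                            strand = "."), f_calls)
      f_diff <- file.path(config$outdir, paste0(nm, "_differential.bed"))
      write_bed6(data.frame(chrom = diff$chrom, start = diff$start,
                            end = diff$end, name = diff$label, score = 0,
                            strand = "."), f_diff)
      files <- c(calls = f_calls, differential = f_diff)
      manifest$scenarios[[nm]] <- list(
        seed = derive_seed(config$seed, "sc", nm),
        n_chip_reads = n_chip, n_input_reads = n_input,
        metrics = list(
          n_calls = nrow(calls),
          n_gained = sum(diff$label == "gained"),
          n_lost = sum(diff$label == "lost"),
          n_invariant = sum(diff$label == "invariant"),
          truth_domains = nrow(sc$truth$domains)),
        files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        names(files))))
    }
    manifest
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  jsonlite::write_json(result, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  result
}

## ---------------------------------------------------------------------------
## Acceptance experiment drivers
## ---------------------------------------------------------------------------

#' One parameter-recovery run of the interstitial repeat insertion scenario
#'
#' Builds `telomere_insertion_17` on a default wild-type genome, simulates
#' chip/input reads on the insertion chromosome (e = 8, 20x by default),
#' runs coverage -> normalization -> domain calling, and measures the
#' anchor-connected run at the insertion site.
#' @param seed integer seed for genome, scenario and reads.
#' @param depth,enrichment read-simulation settings.
#' @return list(span_kb, farthest_kb, n_genes).
#' @export
insertion_recovery_run <- function(seed, depth = 20, enrichment = 8) {
  g <- generate_wt_genome(generator_params(seed = derive_seed(seed, "g")))
  sc <- build_scenario("telomere_insertion_17", g, seed = derive_seed(seed, "s"))
  rsp <- read_sim_params(depth = depth, enrichment = enrichment,
                         seed = derive_seed(seed, "r"))
  cc <- sc$truth$anchor_chrom
  res <- scenario_calls(sc, rsp, chroms = cc)
  asg <- anchored_span_and_genes(res$calls, cc, sc$truth$anchor_pos,
                                 sc$genome$genes)
  list(span_kb = asg$span_bp / 1000, farthest_kb = asg$farthest_bp / 1000,
       n_genes = asg$n_genes)
}

#' De-novo subtelomeric extensions across end-creating translocations
#'
#' Simulates `n_scenarios` end-creating translocations (alternating
#' quasiterminal and reciprocal classes) on a default genome, runs the
#' read-level pipeline on each chromosome carrying a new end, and measures
#' the called end-anchored extension there.
#' @param seed integer seed.
#' @param n_scenarios number of rearrangements (default 7).
#' @param depth,enrichment read-simulation settings.
#' @return numeric vector of extensions (kb), one per new end.
#' @export
new_end_extension_run <- function(seed, n_scenarios = 7, depth = 20,
                                  enrichment = 8) {
  g <- generate_wt_genome(generator_params(seed = derive_seed(seed, "g")))
  classes <- rep(c("quasiterminal", "reciprocal"), length.out = n_scenarios)
  exts <- numeric(0)
  for (j in seq_len(n_scenarios)) {
    sc <- build_scenario(classes[j], g, seed = derive_seed(seed, "s", j))
    rsp <- read_sim_params(depth = depth, enrichment = enrichment,
                           seed = derive_seed(seed, "r", j))
    ne <- sc$truth$new_ends
    for (i in seq_len(nrow(ne))) {
      res <- scenario_calls(sc, rsp, chroms = ne$chrom[i])
      ext <- subtelomeric_extension(res$calls, ne$chrom[i], ne$side[i],
                                    chrom_length(sc$genome, ne$chrom[i]))
      exts <- c(exts, ext / 1000)
    }
  }
  exts
}

#' Compute all acceptance targets
#'
#' Recomputes every reported quantity from scratch by running the
#' generator and pipeline: genome coverage fraction and domain count under
#' default parameters, parameter recovery for the 17-repeat insertion
#' scenario (span / farthest peak / gene count), and the mean de-novo
#' subtelomeric extension across seven end-creating translocations.
#' @param seed top-level seed; per-replicate seeds are derived from it.
#' @param quiet suppress progress messages.
#' @return named list of list(value, n), one entry per target.
#' @export
acceptance_targets <- function(seed = 1L, quiet = FALSE) {
  msg <- function(...) if (!quiet) message(sprintf(...))

  msg("[t5/t6] generator fidelity over 10 seeds")
  fractions <- vapply(1:10, function(i) {
    g <- generate_wt_genome(generator_params(seed = derive_seed(seed, "t5", i)))
    methylated_fraction(g) * 100
  }, numeric(1))
  g6 <- generate_wt_genome(generator_params(seed = derive_seed(seed, "t6")))

  msg("[t7-t9] insertion recovery over 10 seeds")
  rec <- lapply(1:10, function(i)
    insertion_recovery_run(derive_seed(seed, "t789", i)))
  span <- mean(vapply(rec, `[[`, numeric(1), "span_kb"))
  farthest <- mean(vapply(rec, `[[`, numeric(1), "farthest_kb"))
  genes <- mean(vapply(rec, `[[`, numeric(1), "n_genes"))

  msg("[t10] de-novo extensions, 7 scenarios x 10 seeds")
  exts <- unlist(lapply(1:10, function(i)
    new_end_extension_run(derive_seed(seed, "t10", i))))

  list(
    t5 = list(value = mean(fractions), n = 10),
    t6 = list(value = nrow(g6$domains), n = 1),
    t7 = list(value = span, n = 10),
    t8 = list(value = genes, n = 10),
    t9 = list(value = farthest, n = 10),
    t10 = list(value = mean(exts), n = length(exts)))
}

#' Acceptance report table
#' @param targets from [acceptance_targets()].
#' @param expected named numeric vector of expected values.
#' @param tol named numeric vector of relative tolerances.
#' @return data.frame id/value/expected/tolerance/pass.
#' @export
acceptance_report <- function(targets,
                              expected = c(t5 = 7, t6 = 200, t7 = 225,
                                           t8 = 30, t9 = 170, t10 = 180),
                              tol = c(t5 = 1 / 7, t6 = 0, t7 = 0.15,
                                      t8 = 0.2, t9 = 0.15, t10 = 0.15)) {
  ids <- names(targets)
  value <- vapply(targets, function(x) x$value, numeric(1))
  pass <- vapply(ids, function(id) {
    if (id == "t6") return(value[id] >= expected[id])
    abs(value[id] - expected[id]) <= tol[id] * expected[id]
  }, logical(1))
  data.frame(id = ids, value = unname(value), expected = unname(expected[ids]),
             tolerance = unname(tol[ids]), pass = unname(pass),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## CLI
## ---------------------------------------------------------------------------

.cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      flags[[substring(a, 3)]] <- if (i < length(args) &&
                                      !startsWith(args[i + 1], "--")) {
        i <- i + 1
        args[i]
      } else TRUE
    }
    i <- i + 1
  }
  flags
}

#' Subcommand command-line interface
#'
#' Subcommands: `simulate` (write a wild-type genome: `--seed`, `--outdir`,
#' `--sequence`), `run` (full pipeline: `--config` or `--seed`/`--outdir`),
#' `acceptance` (`--seed`, `--out`).
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
telo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: telo_cli <simulate|run|acceptance> [--flags]")
    return(invisible(1L))
  }
  cmd <- args[1]
  fl <- .cli_flags(args[-1])
  seed <- as.integer(fl$seed %||% 1L)
  if (cmd == "simulate") {
    outdir <- fl$outdir %||% "."
    p <- generator_params(seed = seed,
                          with_sequence = isTRUE(fl$sequence == TRUE))
    g <- generate_wt_genome(p)
    paths <- genome_to_files(g, outdir)
    message("wrote ", paste(basename(paths), collapse = ", "), " to ", outdir)
  } else if (cmd == "run") {
    cfg <- if (!is.null(fl$config)) read_config(fl$config)
           else run_config(seed = seed, outdir = fl$outdir %||% "telorun")
    if (!is.null(fl$outdir)) cfg$outdir <- fl$outdir
    run_pipeline(cfg)
    message("manifest written to ", file.path(cfg$outdir, "manifest.json"))
  } else if (cmd == "acceptance") {
    out <- fl$out %||% "acceptance.json"
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    res <- acceptance_targets(seed)
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
    message("acceptance targets written to ", out)
  } else {
    message("unknown subcommand '", cmd, "'")
    return(invisible(1L))
  }
  invisible(0L)
}
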