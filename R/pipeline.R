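# End-to-end experiment helpers and restartable file-based pipeline stages.

#' Run one simulated imaging field end to end
#'
#' Roster -> latent kinetics -> rendered stack -> segmentation + gating ->
#' statistic traces -> response calls. This is the in-memory composition
#' the file-based stages and the share-recovery studies build on.
#'
#' @param config a [spark_config()].
#' @param protocol a [stim_protocol()].
#' @param kinetics a [kinetic_params()].
#' @param optics an [optics_config()]; its `seed` is set to the config seed
#'   plus one unless given a non-`NULL` `render_seed`.
#' @param quant a [quant_params()].
#' @param calling a [call_params()].
#' @param statistic statistic for [build_traces()]; droplet area by default,
#'   the strategy with the lowest resting signal and highest contrast.
#' @param render_seed optional explicit rendering seed.
#' @param keep_stack keep the rendered stack in the result (memory-heavy).
#' @return List with `roster`, `mask`, `traces`, `calls` and optionally
#'   `stack`.
#' @export
run_field <- function(config, protocol = protocol_forskolin(),
                      kinetics = kinetic_params(), optics = optics_config(),
                      quant = quant_params(), calling = call_params(),
                      statistic = "area", render_seed = NULL,
                      keep_stack = FALSE) {
  roster <- simulate_roster(config)
  act <- simulate_activity(roster, protocol, kinetics)
  optics$seed <- as.integer(if (is.null(render_seed)) config$seed + 1L
                            else render_seed)
  if (is.null(optics$frame_shape)) optics$frame_shape <- config$frame_shape
  stack <- render_stack(roster, act, optics)
  traces <- build_traces(stack, quant, statistic = statistic)
  calls <- call_responses(traces, calling)
  out <- list(roster = roster, mask = traces$mask, traces = traces,
              calls = calls)
  if (keep_stack) out$stack <- stack
  out
}

#' Share-recovery study over replicate fields
#'
#' Simulates `length(field_seeds)` independent imaging fields from the same
#' configuration (only the seed differs), runs the full pipeline on each,
#' and summarises the share of responding cells across fields as
#' mean +/- SE — the estimator used for population shares.
#'
#' @inheritParams run_field
#' @param field_seeds integer vector of per-field seeds.
#' @return A [population_share()] summary with attribute `calls` (the
#'   row-bound per-field calls with a `field` column).
#' @export
#' @examples
#' \donttest{
#' cfg <- spark_config(n_cells = 40, frac_capable = 0.5)
#' run_population_study(cfg, field_seeds = 1:2)
#' }
run_population_study <- function(config, protocol = protocol_forskolin(),
                                 kinetics = kinetic_params(),
                                 optics = optics_config(),
                                 quant = quant_params(),
                                 calling = call_params(),
                                 statistic = "area", field_seeds = 1:4) {
  all_calls <- list()
  for (s in field_seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    fld <- run_field(cfg, protocol, kinetics, optics, quant, calling,
                     statistic = statistic)
    all_calls[[length(all_calls) + 1]] <-
      cbind(field = paste0("field", s), fld$calls)
  }
  calls <- do.call(rbind, all_calls)
  out <- population_share(calls, replicate = calls$field)
  attr(out, "calls") <- calls
  out
}

#' Clone study: replicate single-cell-derived clones
#'
#' Simulates `n_clones` small fields ("clones") with a common capable
#' fraction and clone sizes drawn uniformly from `cells_range`, runs the
#' pipeline with a forskolin protocol on each, and summarises shares across
#' clones.
#'
#' @inheritParams run_field
#' @param n_clones number of clones (>= 2).
#' @param cells_range `c(min, max)` cells per clone.
#' @param frac_capable common ground-truth capable fraction.
#' @param seed study seed; clone `i` uses `seed * 100 + i`.
#' @return A [clone_summary()], with attribute `calls`.
#' @export
run_clone_study <- function(n_clones = 7, cells_range = c(36, 44),
                            frac_capable = 0.436,
                            protocol = protocol_forskolin(),
                            kinetics = kinetic_params(),
                            optics = optics_config(),
                            quant = quant_params(), calling = call_params(),
                            seed = 1L) {
  sizes <- with_seed(seed, sample(cells_range[1]:cells_range[2], n_clones,
                                  replace = TRUE))
  all_calls <- list()
  for (i in seq_len(n_clones)) {
    cfg <- spark_config(n_cells = sizes[i], frac_capable = frac_capable,
                        hormone_panel = list(), seed = seed * 100L + i)
    fld <- run_field(cfg, protocol, kinetics, optics, quant, calling)
    all_calls[[i]] <- cbind(clone = paste0("clone", i), fld$calls)
  }
  calls <- do.call(rbind, all_calls)
  out <- clone_summary(calls, clone = calls$clone)
  attr(out, "calls") <- calls
  out
}

# ---- restartable file-based stages -----------------------------------------

traces_schema <- "sparkdrop_traces_v1"

#' Pipeline stage: simulate and write a synthetic experiment
#'
#' Writes `roster.csv`, `stack.tif` and `stack.tif.json` into `outdir`
#' (created if missing). Deterministic per seed: re-running with identical
#' inputs reproduces the files byte for byte.
#'
#' @inheritParams run_field
#' @param outdir output directory.
#' @return Named list of file paths, invisibly.
#' @export
stage_simulate <- function(outdir, config = spark_config(),
                           protocol = protocol_forskolin(),
                           kinetics = kinetic_params(),
                           optics = optics_config()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  roster <- simulate_roster(config)
  act <- simulate_activity(roster, protocol, kinetics)
  optics$seed <- config$seed + 1L
  if (is.null(optics$frame_shape)) optics$frame_shape <- config$frame_shape
  stack <- render_stack(roster, act, optics)
  p_roster <- file.path(outdir, "roster.csv")
  p_stack <- file.path(outdir, "stack.tif")
  p_config <- file.path(outdir, "config.json")
  write_roster(roster, p_roster)
  write_stack(stack, p_stack)
  jsonlite::write_json(list(schema = "sparkdrop_config_v1",
                            config_hash = config_hash(unclass(config)),
                            config = unclass(config)),
                       p_config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(roster = p_roster, stack = p_stack,
                 sidecar = paste0(p_stack, ".json"), config = p_config))
}

#' Pipeline stage: quantify a written stack
#'
#' Reads a stack written by [stage_simulate()] (or assembled from real
#' data in the same layout), builds per-cell statistic traces, and writes
#' `traces.csv` (long format with `#` schema headers), `droplets.csv` and
#' the label mask `mask.tif`.
#'
#' @param stack_path path to the stack TIFF.
#' @param outdir output directory.
#' @param params a [quant_params()].
#' @param statistic statistic name.
#' @return Named list of file paths, invisibly.
#' @export
stage_quantify <- function(stack_path, outdir, params = quant_params(),
                           statistic = "area") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stack <- read_stack(stack_path)
  traces <- build_traces(stack, params, statistic = statistic,
                         keep_droplets = statistic == "area")
  p_traces <- file.path(outdir, "traces.csv")
  p_drop <- file.path(outdir, "droplets.csv")
  p_mask <- file.path(outdir, "mask.tif")
  write_traces(traces, p_traces)
  dd <- traces$droplets
  if (is.null(dd)) dd <- data.frame(frame = integer(0), label = integer(0),
                                    droplet_id = integer(0), area = integer(0),
                                    intensity = numeric(0))
  con <- file(p_drop, "w"); on.exit(close(con))
  writeLines(sprintf("# %s", traces_schema), con)
  utils::write.csv(dd, con, row.names = FALSE)
  tiff::writeTIFF(traces$mask$labels / 65535, p_mask, bits.per.sample = 16L)
  invisible(list(traces = p_traces, droplets = p_drop, mask = p_mask))
}

#' Write / read a trace table (long CSV with schema headers)
#'
#' @param traces a [build_traces()] result.
#' @param path CSV path.
#' @return `write_traces` returns `path` invisibly; `read_traces` a
#'   `spark_traces` object (without the mask).
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "spark_traces"))
  prot <- traces$protocol
  meta <- jsonlite::toJSON(list(
    statistic = traces$statistic, timestamps = traces$timestamps,
    events = as.data.frame(prot), duration = attr(prot, "duration"),
    baseline = attr(prot, "baseline")), auto_unbox = TRUE, digits = NA)
  long <- data.frame(
    cell = rep(as.integer(rownames(traces$values)), each = ncol(traces$values)),
    frame = rep(seq_len(ncol(traces$values)), nrow(traces$values)),
    time_min = rep(traces$timestamps, nrow(traces$values)),
    statistic = traces$statistic,
    value = as.vector(t(traces$values)),
    gated = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# %s", traces_schema),
               sprintf("# meta: %s", meta)), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  head2 <- readLines(path, n = 2)
  if (!identical(head2[1], sprintf("# %s", traces_schema)))
    stopf("'%s' does not carry the expected trace schema header (%s)",
          path, traces_schema)
  meta <- jsonlite::fromJSON(sub("^# meta: ", "", head2[2]))
  long <- utils::read.csv(path, comment.char = "#")
  cells <- sort(unique(long$cell))
  vals <- matrix(NA_real_, length(cells), length(meta$timestamps),
                 dimnames = list(as.character(cells), NULL))
  vals[cbind(match(long$cell, cells), long$frame)] <- long$value
  prot <- stim_protocol(meta$events$time, meta$events$agent, meta$events$kind,
                        duration = meta$duration, baseline = meta$baseline)
  structure(list(values = vals, timestamps = meta$timestamps,
                 statistic = meta$statistic, protocol = prot, mask = NULL),
            class = "spark_traces")
}

#' Pipeline stage: call responses from a written trace table
#'
#' Reads `traces.csv`, calls responders, and writes `calls.csv` plus
#' `summary.json` (per-stimulus shares with SE).
#'
#' @param traces_path path to a `traces.csv` from [stage_quantify()].
#' @param outdir output directory.
#' @param params a [call_params()].
#' @param replicate replicate label recorded in the summary.
#' @return Named list of file paths, invisibly.
#' @export
stage_call <- function(traces_path, outdir, params = call_params(),
                       replicate = "field1") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  traces <- read_traces(traces_path)
  calls <- call_responses(traces, params)
  summ <- population_share(calls, replicate = replicate)
  p_calls <- file.path(outdir, "calls.csv")
  p_summ <- file.path(outdir, "summary.json")
  con <- file(p_calls, "w"); on.exit(close(con))
  writeLines(sprintf("# %s", traces_schema), con)
  utils::write.csv(as.data.frame(calls), con, row.names = FALSE)
  jsonlite::write_json(list(schema = traces_schema,
                            summary = as.data.frame(summ)),
                       p_summ, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(calls = p_calls, summary = p_summ))
}

#' Pipeline stage: gene-set zero-expression census of an MTX directory
#'
#' @param mtx_dir directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @param gene_set gene symbols (default: human adenylyl cyclases).
#' @param out_path JSON output path, or `NULL` to skip writing.
#' @param ... passed to [zero_expression_census()].
#' @return The `census_result`, invisibly when writing.
#' @export
stage_census <- function(mtx_dir, gene_set = adcy_genes(), out_path = NULL,
                         ...) {
  m <- read_count_matrix(mtx_dir)
  res <- zero_expression_census(m, gene_set, ...)
  if (!is.null(out_path)) {
    jsonlite::write_json(list(n_zero = res$n_zero, n_total = res$n_total,
                              percent = res$percent,
                              genes_used = res$genes_used),
                         out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(res))
  }
  res
}
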