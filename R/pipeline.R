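#' Build and validate a pipeline run configuration
#'
#' A run configuration drives [run_pipeline()] end to end. In `simulate`
#' mode the genome, annotation, library and selection scenario are generated
#' from the single seed; in `real` mode per-replicate alignment files (SAM
#' or BED6) and a GenBank annotation are supplied. Validation happens here,
#' before any compute.
#'
#' @param mode `"simulate"` or `"real"`.
#' @param seed Integer master seed; every random draw in the run derives
#'   from it.
#' @param min_sites Minimum-site filter threshold (default 3).
#' @param replicates In simulate mode, the number of biological replicates
#'   (default 3). In real mode, a list with one element per replicate, each
#'   a list of `list(sample_id =, path =, format =)` alignment entries.
#' @param genome Simulate mode: `list(length =, gc =)`.
#' @param annotation Simulate mode: `list(n_genes =, mean_gene_len =)`.
#' @param library Simulate mode: `list(density =)`.
#' @param scenario Simulate mode: arguments for [selection_scenario()]
#'   (minus `seed`), e.g. `survival_factor`, `baseline_survival`,
#'   `plating_counts`, `read_depth`, `control`.
#' @param emit_fastq Simulate mode: if `TRUE` the run round-trips through
#'   read emission, trimming and placement rather than using the simulated
#'   site tables directly (slower; exercises the full read path).
#' @param junction Junction sequence used when `emit_fastq = TRUE`.
#' @param genbank Real mode: path to the GenBank annotation.
#' @param control Sample id of the control in each replicate.
#' @return A validated object of class `tn_run_config`.
#' @export
run_config <- function(mode = c("simulate", "real"),
                       seed = 1L,
                       min_sites = 3L,
                       replicates = 3L,
                       genome = list(length = 200000L, gc = 0.5),
                       annotation = list(n_genes = 150L, mean_gene_len = 900L),
                       library = list(density = 1 / 20),
                       scenario = list(),
                       emit_fastq = FALSE,
                       junction = tn_junction(),
                       genbank = NULL,
                       control = "control") {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, seed = as.integer(seed),
              min_sites = as.integer(min_sites), replicates = replicates,
              genome = genome, annotation = annotation, library = library,
              scenario = scenario, emit_fastq = isTRUE(emit_fastq),
              junction = junction, genbank = genbank, control = control)
  validate_run_config(cfg)
  structure(cfg, class = "tn_run_config")
}

validate_run_config <- function(cfg) {
  err <- function(msg) abort(msg, class = c("tnseqsi_config_error",
                                            "tnseqsi_error"))
  if (cfg$mode == "simulate") {
    if (!is.numeric(cfg$replicates) || cfg$replicates < 1)
      err("simulate mode needs `replicates` >= 1")
    if (is.null(cfg$genome$length) || cfg$genome$length < 1)
      err("simulate mode needs a positive genome length")
    # scenario arguments must construct (control present, samples consistent)
    sc <- do.call(selection_scenario,
                  c(cfg$scenario, list(control = cfg$control, seed = cfg$seed)))
    if (!cfg$control %in% sc$samples)
      err(sprintf("control sample '%s' absent from scenario", cfg$control))
  } else {
    if (is.null(cfg$genbank) || !file.exists(cfg$genbank))
      err("real mode needs an existing `genbank` path")
    if (!is.list(cfg$replicates) || length(cfg$replicates) < 1)
      err("real mode needs `replicates` as a list of alignment entries")
    for (r in seq_along(cfg$replicates)) {
      entries <- cfg$replicates[[r]]
      ids <- vapply(entries, function(e) e$sample_id %||% "", "")
      if (sum(ids == cfg$control) != 1)
        err(sprintf("replicate %d must contain exactly one control sample '%s'",
                    r, cfg$control))
      for (e in entries) {
        if (is.null(e$path) || !file.exists(e$path))
          err(sprintf("replicate %d: alignment file missing: %s",
                      r, e$path %||% "<unset>"))
      }
    }
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A validated `tn_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("survival_factor", "baseline_survival", "plating_counts",
               "read_depth")) {
    if (!is.null(y$scenario[[nm]])) y$scenario[[nm]] <- unlist(y$scenario[[nm]])
  }
  do.call(run_config, y)
}

#' Write a selection scenario to YAML
#'
#' @param scenario A `tn_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(scenario, path) {
  yaml::write_yaml(lapply(unclass(scenario), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

stage_abort <- function(stage, e) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        class = c("tnseqsi_runtime_error", "tnseqsi_error"))
}

#' Run the Tn-seq pipeline end to end
#'
#' Executes simulate-and-analyse (or ingest-and-analyse) in stages —
#' simulate / ingest, site enumeration, feature aggregation, Dval, SI,
#' replicate combination — writing per-sample site tables, per-replicate
#' feature counts, one ranked SI report per treated sample, a summary JSON
#' and a manifest recording the configuration hash, seed, versions,
#' per-stage record counts and output checksums. A simulate-mode run with a
#' fixed configuration is reproducible byte for byte.
#'
#' @param config A `tn_run_config`.
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the combined results (one `tn_si_combined`
#'   per treated sample), the annotation, and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "tn_run_config"))
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  counts_log <- list()

  if (config$mode == "simulate") {
    prep <- tryCatch({
      genome <- make_genome(config$genome$length, config$genome$gc %||% 0.5,
                            seed = config$seed)
      ann <- make_annotation(genome, config$annotation$n_genes %||% 150L,
                             config$annotation$mean_gene_len %||% 900L,
                             seed = config$seed + 1L)
      lib <- make_library(ann, config$library$density %||% (1 / 20),
                          seed = config$seed + 2L)
      list(genome = genome, ann = ann, lib = lib)
    }, error = function(e) stage_abort("simulate:setup", e))
    log("simulate: genome %d bp, %d features, %d library sites",
        prep$genome$length, nrow(prep$ann$features), nrow(prep$lib))

    replicate_tables <- lapply(seq_len(config$replicates), function(r) {
      sc <- do.call(selection_scenario,
                    c(config$scenario, list(control = config$control,
                                            seed = config$seed + 100L + r)))
      sim <- tryCatch(simulate_selection(prep$lib, prep$ann, sc),
                      error = function(e) stage_abort("simulate:selection", e))
      if (config$emit_fastq) {
        sim <- tryCatch(
          roundtrip_reads(sim, prep$genome, config$junction,
                          seed = config$seed + 200L + r,
                          counts_hook = function(x) counts_log[[length(counts_log) + 1L]] <<- x,
                          replicate = r),
          error = function(e) stage_abort("readprep", e))
      }
      sim
    })
    annotation <- prep$ann
  } else {
    annotation <- tryCatch(derive_intergenic(read_genbank(config$genbank)),
                           error = function(e) stage_abort("ingest:genbank", e))
    log("real: annotation %d features over %d bp",
        nrow(annotation$features), annotation$genome$length)
    replicate_tables <- lapply(seq_along(config$replicates), function(r) {
      entries <- config$replicates[[r]]
      bind_rows(lapply(entries, function(e) {
        pl <- tryCatch(ingest_alignments(e$path, e$format %||% "auto"),
                       error = function(e2) stage_abort("ingest:alignments", e2))
        dropped <- attr(pl, "dropped")
        counts_log[[length(counts_log) + 1L]] <<- list(
          replicate = r, sample = e$sample_id, stage = "ingest",
          records_in = attr(pl, "n_input"), placed = nrow(pl),
          dropped = as.list(dropped))
        enumerate_sites(pl, e$sample_id)
      }))
    })
  }

  results <- tryCatch({
    per_rep <- lapply(seq_along(replicate_tables), function(r) {
      tab <- replicate_tables[[r]]
      counts <- aggregate_counts(tab, annotation)
      dv <- add_dval(counts, annotation)
      treated <- setdiff(unique(tab$sample_id), config$control)
      res <- lapply(treated, function(tr) {
        survival_results(dv, config$control, tr, min_sites = config$min_sites)
      })
      names(res) <- treated
      list(sites = tab, counts = counts, res = res)
    })
    treated_ids <- names(per_rep[[1]]$res)
    combined <- lapply(treated_ids, function(tr) {
      combine_replicates(lapply(per_rep, function(p) p$res[[tr]]))
    })
    names(combined) <- treated_ids
    list(per_rep = per_rep, combined = combined)
  }, error = function(e) stage_abort("stats", e))

  paths <- character(0)
  for (r in seq_along(results$per_rep)) {
    p <- results$per_rep[[r]]
    paths <- c(paths, write_site_tables(p$sites, out_dir,
                                        prefix = sprintf("sites_rep%d", r)))
    cpath <- file.path(out_dir, sprintf("feature_counts_rep%d.tsv", r))
    readr::write_tsv(as_tibble(p$counts), cpath, progress = FALSE)
    paths <- c(paths, cpath)
    log("replicate %d: %d sites, %d reads", r,
        nrow(distinct(p$sites, .data$position, .data$orientation)),
        sum(p$sites$count))
  }
  for (tr in names(results$combined)) {
    rpath <- file.path(out_dir, sprintf("si_%s.tsv", tr))
    write_si_report(rank_report(results$combined[[tr]], "resistant"), rpath)
    paths <- c(paths, rpath)
  }

  summary <- list(
    mode = config$mode,
    n_replicates = length(results$per_rep),
    n_features = nrow(annotation$features),
    filter = lapply(results$combined, function(cb) {
      list(min_sites = config$min_sites,
           genes_pass = sum(cb$passes_filter & cb$kind == "gene"),
           intergenic_pass = sum(cb$passes_filter & cb$kind == "intergenic"))
    }),
    unassigned_reads = sum(vapply(results$per_rep, function(p) {
      ua <- attr(p$counts, "unassigned")
      if (is.null(ua)) 0 else sum(ua$reads)
    }, numeric(1))))
  spath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, spath)

  manifest <- list(
    package = "tnseqsi",
    version = as.character(utils::packageVersion("tnseqsi")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_sha256 = digest::digest(unclass(config), algo = "sha256"),
    seed = config$seed,
    stage_counts = counts_log,
    outputs = lapply(stats::setNames(nm = basename(paths)), function(b) {
      digest::digest(file = file.path(out_dir, b), algo = "sha256")
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(combined = results$combined, annotation = annotation,
                 out_dir = out_dir, paths = paths))
}

# Replace simulated site tables by the full read path: emit FASTQ-style
# reads, trim junction/poly(C), place fragments, re-enumerate sites.
# Asserts the record bookkeeping: reads in = placed + unmapped + ambiguous
# + rejected.
roundtrip_reads <- function(sim, genome, junction, seed, counts_hook = NULL,
                            replicate = NA_integer_) {
  reads <- emit_reads(sim, genome, junction = junction, seed = seed)
  out <- lapply(unique(sim$sample_id), function(sm) {
    r <- filter(reads, .data$sample_id == sm)
    pl <- locate_fragments(trim_reads(r, junction = junction), genome)
    tally <- table(factor(pl$status, levels = c("placed", "unmapped",
                                                "ambiguous", "no_junction",
                                                "too_short")))
    stopifnot(sum(tally) == nrow(r))
    if (!is.null(counts_hook)) {
      counts_hook(list(replicate = replicate, sample = sm, stage = "readprep",
                       reads_in = nrow(r), placed = unname(tally[["placed"]]),
                       unmapped = unname(tally[["unmapped"]]),
                       ambiguous = unname(tally[["ambiguous"]]),
                       rejected = unname(tally[["no_junction"]] +
                                           tally[["too_short"]])))
    }
    enumerate_sites(filter(pl, .data$status == "placed"), sm)
  })
  bind_rows(out)
}
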