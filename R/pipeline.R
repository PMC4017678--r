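# End-to-end pipeline: YAML config -> landscape -> simulation -> profile
# (-> comparison / plasticity), with a run manifest for provenance.

.cfg_get <- function(cfg, path, default = NULL, required = FALSE) {
  node <- cfg
  for (key in strsplit(path, "/", fixed = TRUE)[[1]]) {
    if (!is.list(node) || is.null(node[[key]])) {
      if (required) stop("config error at '", path, "': missing")
      return(default)
    }
    node <- node[[key]]
  }
  node
}

.cfg_file <- function(path, what) {
  if (is.null(path)) stop("config error: missing input path for ", what)
  if (!file.exists(path)) stop("input file not found: ", path)
  path
}

#' Run the full replication-timing pipeline from a configuration
#'
#' Stages: build the landscape (from a BED/FASTA input or a synthetic
#' fixture), simulate the population, gate it into a timing profile, and
#' optionally compare against an empirical profile and call plasticity
#' regions. All stage seeds derive from the single master seed, and a
#' `manifest.json` (config echo, seeds, input digests, package version,
#' per-chromosome fork counts, cycle/snapshot tallies) is written next to
#' the outputs, so a re-run from the manifest is byte-identical.
#'
#' Configuration (YAML file or equivalent list):
#' \preformatted{
#' seed: 1
#' output_dir: out
#' genome: {chrom_sizes: genome.chrom.sizes, bin_width: 500}
#' ipls:
#'   builder: score        # score|tss|gc|cpg|g4|fixture
#'   bed: sites.bed        # score/tss builders
#'   fasta: genome.fa      # gc/cpg/g4 builders
#'   amplitude: linear
#'   background: 1.0e-4
#'   bin_mode: max
#'   fixture: {n_bins: 2000, sites: clustered}   # fixture builder
#' simulate: {forks: auto, cycles: 100, snapshot_period: 10}
#' profile: {gates: 6}     # or an explicit boundary list
#' compare: {empirical: timing.bedGraph, flip: false}   # optional
#' plasticity: {versus: other.bedGraph, alpha: 0.001, min_run: 3} # optional
#' }
#'
#' @param config Path to a YAML file, or a config list.
#' @param output_dir Overrides `output_dir` from the config.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- .cfg_file(config, "config")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  seed <- as.integer(.cfg_get(config, "seed", 1))
  out_dir <- output_dir %||% .cfg_get(config, "output_dir", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()

  builder <- .cfg_get(config, "ipls/builder", required = TRUE)
  bg <- as.numeric(.cfg_get(config, "ipls/background", 1e-4))
  amp <- .cfg_get(config, "ipls/amplitude", "linear")

  if (builder == "fixture") {
    fx <- .cfg_get(config, "ipls/fixture", required = TRUE)
    spec <- do.call(fixture_spec,
                    c(fx, list(background = bg, seed = seed)))
    built <- make_ipls_fixture(spec)
    genome <- built$genome
    ip <- built$ipls
  } else {
    cs <- .cfg_file(.cfg_get(config, "genome/chrom_sizes", required = TRUE),
                    "genome/chrom_sizes")
    inputs <- c(inputs, cs)
    genome <- read_chrom_sizes(cs, bin_width =
                                 .cfg_get(config, "genome/bin_width", 500))
    ip <- switch(builder,
      score = {
        bed <- .cfg_file(.cfg_get(config, "ipls/bed"), "ipls/bed")
        inputs <- c(inputs, bed)
        ipls_from_scores(read_bed(bed), genome, amplitude_map = amp,
                         background = bg,
                         mode = .cfg_get(config, "ipls/bin_mode", "max"))
      },
      tss = {
        bed <- .cfg_file(.cfg_get(config, "ipls/bed"), "ipls/bed")
        inputs <- c(inputs, bed)
        ipls_from_tss(read_bed(bed), genome, background = bg)
      },
      gc = , cpg = , g4 = {
        fa <- .cfg_file(.cfg_get(config, "ipls/fasta"), "ipls/fasta")
        inputs <- c(inputs, fa)
        fn <- switch(builder, gc = ipls_from_gc, cpg = ipls_from_cpg,
                     g4 = ipls_from_g4)
        fn(fa, genome, amplitude_map = amp, background = bg)
      },
      stop("config error at 'ipls/builder': unknown builder '", builder, "'")
    )
  }
  ipls_path <- file.path(out_dir, "ipls.bedGraph")
  write_track(ip, ipls_path)

  forks <- .cfg_get(config, "simulate/forks", "auto")
  st <- simulate_replication(
    ip, n_factors = forks,
    n_cycles = as.integer(.cfg_get(config, "simulate/cycles", 100)),
    snapshot_period =
      as.integer(.cfg_get(config, "simulate/snapshot_period", 10)),
    g_to_s_prob = as.numeric(.cfg_get(config, "simulate/g_to_s_prob",
                                      1 / 500)),
    seed = seed)

  gates_cfg <- .cfg_get(config, "profile/gates", 6)
  gates <- if (length(gates_cfg) == 1) equidistant_gates(as.integer(gates_cfg))
           else gate_spec(as.numeric(gates_cfg))
  prof <- timing_profile(st, gates)
  timing_path <- file.path(out_dir, "timing.bedGraph")
  write_track(prof, timing_path)
  outputs <- c(ipls_path, timing_path)

  comparison <- NULL
  if (!is.null(.cfg_get(config, "compare"))) {
    emp_path <- .cfg_file(.cfg_get(config, "compare/empirical"),
                          "compare/empirical")
    inputs <- c(inputs, emp_path)
    emp <- read_track(emp_path, genome)
    cmp <- compare_profiles(prof, emp,
                            flip = isTRUE(.cfg_get(config, "compare/flip",
                                                   FALSE)))
    comparison <- list(mean_r = cmp$mean, sem = cmp$sem,
                       per_chromosome = as.list(cmp$per_chromosome))
    jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, file.path(out_dir, "comparison.json"))
  }

  if (!is.null(.cfg_get(config, "plasticity"))) {
    vs_path <- .cfg_file(.cfg_get(config, "plasticity/versus"),
                         "plasticity/versus")
    inputs <- c(inputs, vs_path)
    vs <- read_track(vs_path, genome)
    regs <- call_plasticity_regions(
      prof, vs,
      alpha = as.numeric(.cfg_get(config, "plasticity/alpha", 0.001)),
      min_run = as.integer(.cfg_get(config, "plasticity/min_run", 3)))
    write_regions_bed(regs, file.path(out_dir, "plasticity.bed"))
    outputs <- c(outputs, file.path(out_dir, "plasticity.bed"))
  }

  manifest <- list(
    package = "replitimer",
    version = as.character(packageVersion("replitimer")),
    seed = seed,
    config = config,
    config_file = cfg_path,
    inputs = as.list(setNames(as.character(tools::md5sum(inputs)), inputs)),
    forks = as.list(st$forks),
    cycles = st$n_cycles,
    incomplete_cycles = sum(vapply(st$chromosomes,
                                   function(r) sum(!r$completed),
                                   numeric(1))),
    snapshots = sum(vapply(st$chromosomes,
                           function(r) length(r$snap_step), numeric(1))),
    outputs = as.list(setNames(as.character(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  message("pipeline complete: ", length(outputs), " output(s) in ", out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
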