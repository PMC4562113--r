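# End-to-end orchestration: simulate -> classify -> rscan -> enrich ->
# profiles from one configuration, with a manifest recording seed, config
# hash and checksums of every written file. Reruns with the same config are
# byte-identical.

#' Pipeline configuration
#'
#' Either a synthesis block (`synth`) or a list of input paths (`inputs`
#' with elements `sites`, `h3k4me3_a`, `h3k4me3_b`, `dmc1`, `snps`,
#' `genome_sizes`, optionally `gaps`) must be present.
#'
#' @param synth A [synth_config()] (or `NULL` when `inputs` is given).
#' @param inputs Named list of input file paths (or `NULL`).
#' @param rscan An [rscan_config()] for the deficiency stage.
#' @param stages Character vector of stages to run, from
#'   `c("simulate", "classify", "rscan", "enrich", "profiles")`.
#' @param seed Integer master seed; overrides the seeds in `synth` and
#'   `rscan` so one value controls the whole run.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synth = synth_config(), inputs = NULL,
                            rscan = rscan_config(n_null = 1000),
                            stages = c("simulate", "classify", "rscan",
                                       "enrich", "profiles"),
                            seed = 1L) {
  known <- c("simulate", "classify", "rscan", "enrich", "profiles")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (is.null(synth) && is.null(inputs))
    stop("either a synthesis block or input paths must be present")
  structure(list(synth = synth, inputs = inputs, rscan = rscan,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `seed`, `stages`, `synth` (fields of
#' [synth_config()]), `rscan` (fields of [rscan_config()]), `inputs`.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) {
    a <- y$synth
    if (!is.null(a$genome)) a$genome <- unlist(a$genome)
    if (!is.null(a$activation$barrier_penalty))
      a$activation$barrier_penalty <- unlist(a$activation$barrier_penalty)
    do.call(synth_config, a)
  } else NULL
  rs <- if (!is.null(y$rscan)) do.call(rscan_config, y$rscan)
        else rscan_config(n_null = 1000)
  pipeline_config(synth = synth, inputs = y$inputs, rscan = rs,
                  stages = y$stages %||% c("simulate", "classify", "rscan",
                                           "enrich", "profiles"),
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the configured stages and writes each stage's artifacts under
#' `out_dir/<stage>/`, plus `manifest.json` covering every written file with
#' an MD5 checksum. No stage mutates another stage's outputs; rerunning with
#' the same config and seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "hotspotUsage",
                   version = as.character(utils::packageVersion("hotspotUsage")),
                   seed = config$seed, stages = list(), files = list())
  written <- character(0)
  note <- function(stage, status, files = character(0)) {
    manifest$stages[[stage]] <<- status
    written <<- c(written, files)
  }

  ## ---- inputs ---------------------------------------------------------
  if (!is.null(config$inputs)) {
    need <- c("sites", "h3k4me3_a", "h3k4me3_b", "dmc1", "snps",
              "genome_sizes")
    missing_in <- setdiff(need, names(config$inputs))
    if (length(missing_in))
      stop("missing input path(s): ", paste(missing_in, collapse = ", "))
    absent <- !vapply(unlist(config$inputs), file.exists, logical(1))
    if (any(absent))
      stop("input file(s) not found: ",
           paste(unlist(config$inputs)[absent], collapse = ", "))
  }

  ## ---- simulate -------------------------------------------------------
  if ("simulate" %in% stages) {
    cfg <- config$synth
    if (is.null(cfg)) stop("simulate stage requested but no synth block")
    cfg$seed <- config$seed
    sim_dir <- file.path(out_dir, "simulate")
    truth <- simulate_dataset(cfg, dir = sim_dir)
    note("simulate", "done", list.files(sim_dir, full.names = TRUE))
    genome <- truth$genome
    sites <- truth$sites
    peaks <- truth$peaks
    snps <- truth$snps
    domains <- truth$domains
    genes <- truth$genes
    gaps_bed <- if (!is.null(cfg$gaps))
      as_interval_set(cfg$gaps, label = "gaps") else NULL
  } else {
    note("simulate", "skipped")
    if (is.null(config$inputs))
      stop("simulate stage disabled and no input paths supplied")
    inp <- config$inputs
    genome <- read_chrom_sizes(inp$genome_sizes)
    sites <- read_bed(inp$sites, "binding_sites")
    peaks <- list(h3k4me3_a = read_bed(inp$h3k4me3_a, "H3K4me3_strainA"),
                  h3k4me3_b = read_bed(inp$h3k4me3_b, "H3K4me3_strainB"),
                  dmc1 = read_bed(inp$dmc1, "DMC1"))
    snps <- read_bed(inp$snps, "SNPs")
    domains <- NULL
    genes <- if (!is.null(inp$genes)) read_bed(inp$genes, "genes") else NULL
    gaps_bed <- if (!is.null(inp$gaps)) read_bed(inp$gaps, "gaps") else NULL
    truth <- NULL
  }

  ## ---- classify -------------------------------------------------------
  cls <- NULL
  if ("classify" %in% stages) {
    cls_dir <- file.path(out_dir, "classify")
    dir.create(cls_dir, showWarnings = FALSE)
    cls <- classify_sites(sites, peaks$h3k4me3_a, peaks$h3k4me3_b,
                          peaks$dmc1)
    f <- write_classification(cls, file.path(cls_dir, "classified.tsv"),
                              file.path(cls_dir, "summary.json"))
    note("classify", "done", f)
  } else note("classify", "skipped")

  ## ---- rscan ----------------------------------------------------------
  if ("rscan" %in% stages) {
    if (is.null(cls)) stop("rscan stage requires the classify stage")
    rs_dir <- file.path(out_dir, "rscan")
    dir.create(rs_dir, showWarnings = FALSE)
    rcfg <- config$rscan
    rcfg$seed <- config$seed + 1L
    in_vivo <- cls$sites[cls$sites$status == "in_vivo", , drop = FALSE]
    res <- rscan(in_vivo, genome, background = sites, gaps = gaps_bed,
                 config = rcfg)
    f1 <- write_bed(res$regions, file.path(rs_dir, "deficient_regions.bed"))
    f2 <- write_tsv(res$spans, file.path(rs_dir, "spans.tsv"))
    yaml::write_yaml(unclass(rcfg), file.path(rs_dir, "rscan_config.yaml"))
    xr <- cross_reference_deficiency(res$regions, sites, genome)
    f3 <- write_tsv(xr$regions, file.path(rs_dir, "regions_crossref.tsv"))
    note("rscan", "done", c(f1, f2, file.path(rs_dir, "rscan_config.yaml"),
                            f3))
  } else note("rscan", "skipped")

  ## ---- enrich ---------------------------------------------------------
  if ("enrich" %in% stages) {
    if (is.null(cls)) stop("enrich stage requires the classify stage")
    en_dir <- file.path(out_dir, "enrich")
    dir.create(en_dir, showWarnings = FALSE)
    rows <- list(usage_fraction(cls))
    if (!is.null(domains)) {
      for (d in names(domains)) {
        rows <- c(rows,
                  list(usage_fraction(cls, domains[[d]], paste0(d, "+")),
                       usage_fraction(cls, domains[[d]], paste0(d, "-"),
                                      complement = TRUE)))
      }
    }
    if (!is.null(genes)) {
      rows <- c(rows, list(usage_fraction(cls, genes, "genic"),
                           usage_fraction(cls, genes, "intergenic",
                                          complement = TRUE)))
      qs <- expression_quartiles(genes)
      rows <- c(rows, lapply(qs, function(g) usage_fraction(cls, g)))
    }
    f1 <- write_tsv(do.call(rbind, rows), file.path(en_dir, "usage.tsv"))
    fq <- character(0)
    if (!is.null(domains) &&
        all(c("H3K9me2", "H3K9me3") %in% names(domains))) {
      closed <- merge_intervals(interval_set(
        c(domains$H3K9me2$chrom, domains$H3K9me3$chrom),
        c(domains$H3K9me2$start, domains$H3K9me3$start),
        c(domains$H3K9me2$end, domains$H3K9me3$end),
        label = "closed_chromatin"), gap = 0)
      q <- affinity_quintile_ratio(cls, closed)
      fq <- write_tsv(q, file.path(en_dir, "quintile_ratios.tsv"))
    }
    note("enrich", "done", c(f1, fq))
  } else note("enrich", "skipped")

  ## ---- profiles -------------------------------------------------------
  if ("profiles" %in% stages) {
    if (is.null(cls)) stop("profiles stage requires the classify stage")
    pr_dir <- file.path(out_dir, "profiles")
    dir.create(pr_dir, showWarnings = FALSE)
    in_vivo <- cls$sites[cls$sites$status == "in_vivo", , drop = FALSE]
    prof <- snp_density_profile(snps, in_vivo)
    f1 <- write_tsv(prof, file.path(pr_dir, "snp_ratio_profile.tsv"))
    f2 <- character(0)
    if (!is.null(truth)) {
      set.seed(config$seed + 2L)
      cov <- simulate_affinity_coverage(truth$sites,
                                        truth$config$fragment_length,
                                        depth = 50)
      comp <- composite_profile(cov, truth$sites, genome, half_width = 400)
      f2 <- write_tsv(comp, file.path(pr_dir, "composite_profile.tsv"))
    }
    note("profiles", "done", c(f1, f2))
  } else note("profiles", "skipped")

  ## ---- manifest -------------------------------------------------------
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(list(seed = config$seed, stages = stages), cfg_path)
  written <- c(written, cfg_path)
  sums <- tools::md5sum(sort(unique(written)))
  manifest$files <- as.list(unname(sums))
  pref <- paste0(out_dir, "/")
  names(manifest$files) <- ifelse(startsWith(names(sums), pref),
                                  substring(names(sums), nchar(pref) + 1),
                                  names(sums))
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$manifest_hash <- as.character(
    tools::md5sum(textConnection_md5(paste(sums, collapse = ""))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# md5 of an in-memory string (tools::md5sum wants a file)
textConnection_md5 <- function(x) {
  tf <- tempfile()
  writeLines(x, tf)
  tf
}
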