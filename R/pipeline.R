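#' Run the full seascape-genetics pipeline from a config
#'
#' Orchestrates the requested stages - `synth_field` -> `dispersal` ->
#' `connectivity`, `synth_genotypes` -> `popgen`, and `forward_sim` - with
#' per-stage seeds, writes CSV/JSON outputs under `out_dir`, and records a
#' run manifest (config snapshot, seeds, input digests, stage timings,
#' output paths, package version). Reruns with an identical config and
#' seeds reproduce identical outputs.
#'
#' @param config Path to a YAML config, or an equivalent named list. Top
#'   level: `out_dir`, `seed`, and a `stages` block; see the packaged
#'   `demo_config.yaml` for the schema.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a YAML path or a list")
  for (field in c("out_dir", "stages"))
    if (is.null(config[[field]]))
      abort(sprintf("config is missing required field '%s'", field))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_seed <- as.integer(config$seed %||% 1L)
  st <- config$stages
  manifest <- list(
    package_version = as.character(utils::packageVersion("seascaper")),
    config = config, seeds = list(), timings = list(), outputs = list(),
    input_digests = list())
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(name, seed, t0, outs) {
    manifest$seeds[[name]] <<- seed
    manifest$timings[[name]] <<- round(tic() - t0, 3)
    manifest$outputs[[name]] <<- outs
    message(sprintf("[%s] seed=%d elapsed=%.2fs", name, seed,
                    manifest$timings[[name]]))
  }

  field <- NULL
  flux <- NULL
  if (!is.null(st$synth_field)) {
    t0 <- tic(); seed <- base_seed + 101L
    sf <- st$synth_field
    g <- grid_spec(sf$lon_min, sf$lon_max, sf$lat_min, sf$lat_max,
                   d_lon = sf$d_lon %||% (1 / 45),
                   d_lat = sf$d_lat %||% (1 / 45),
                   depth_levels = sf$depth_levels %||% c(0, 10, 20),
                   time_origin = sf$time_origin %||% "2004-01-01",
                   n_days = sf$n_days %||% 365L)
    field <- make_synthetic_field(
      g, gyre_strength = sf$gyre_strength %||% 0.2,
      mean_temp_winter = sf$mean_temp_winter %||% 13,
      mean_temp_summer = sf$mean_temp_summer %||% 26,
      temp_peak_day = sf$temp_peak_day %||% 225,
      noise_sd = sf$noise_sd %||% 0, seed = seed)
    fpath <- file.path(out_dir, "field.oceanfield.json")
    write_field(field, fpath)
    log_stage("synth_field", seed, t0, fpath)
  }
  if (!is.null(st$dispersal)) {
    t0 <- tic(); seed <- base_seed + 202L
    dp <- st$dispersal
    if (is.null(field)) {
      if (is.null(dp$field))
        abort("dispersal stage needs a 'field' path (no synth_field stage ran)")
      manifest$input_digests[["field"]] <-
        unname(tools::md5sum(dp$field))
      field <- load_field(dp$field)
    }
    sites <- if (is.null(dp$sites)) release_sites()
    else release_sites(dp$sites)
    if (!is.null(dp$site_subset))
      sites <- sites[sites$acronym %in% dp$site_subset, ]
    cfg_args <- dp$config %||% list()
    cfg_args$seed <- seed
    cfg <- do.call(dispersal_config, cfg_args)
    flux <- run_simulation(field, sites, cfg)
    fpath <- file.path(out_dir, "flux.csv")
    write.csv(tidy(flux), fpath, row.names = FALSE)
    log_stage("dispersal", seed, t0, fpath)
  }
  if (!is.null(st$connectivity)) {
    t0 <- tic(); seed <- base_seed + 303L
    if (is.null(flux)) abort("connectivity stage needs the dispersal stage")
    norm <- st$connectivity$normalization %||% "actual"
    eff <- effectiveness(flux, norm)
    per <- persistence(flux)
    outs <- c(file.path(out_dir, "effectiveness.csv"),
              file.path(out_dir, "persistence.csv"),
              file.path(out_dir, "rates.csv"),
              file.path(out_dir, "trends.json"))
    write_connectivity_csv(eff, outs[1])
    write_connectivity_csv(per, outs[2])
    rates <- rate_decomposition(flux)
    write.csv(rates, outs[3], row.names = FALSE)
    ann <- dplyr::summarise(
      dplyr::group_by(flux$releases, .data$year),
      release_rate = sum(.data$released_actual) /
        sum(.data$released_potential), .groups = "drop")
    trend <- if (nrow(ann) >= 4)
      as.list(tidy(hamed_rao_trend(ann$release_rate)))
    else list(note = "fewer than 4 years; trend not tested")
    jsonlite::write_json(trend, outs[4], auto_unbox = TRUE, digits = NA)
    log_stage("connectivity", seed, t0, outs)
  }

  geno <- NULL
  if (!is.null(st$synth_genotypes)) {
    t0 <- tic(); seed <- base_seed + 404L
    sg <- st$synth_genotypes
    args <- sg[names(sg) %in% names(formals(simulate_genotype_dataset))]
    args$seed <- seed
    geno <- do.call(simulate_genotype_dataset, args)
    gpath <- file.path(out_dir, "genotypes.gen")
    write_genepop(geno, gpath)
    log_stage("synth_genotypes", seed, t0, gpath)
  }
  if (!is.null(st$popgen)) {
    t0 <- tic(); seed <- base_seed + 505L
    pg <- st$popgen
    if (is.null(geno)) {
      if (is.null(pg$genepop))
        abort("popgen stage needs a 'genepop' path (no synth_genotypes stage ran)")
      manifest$input_digests[["genepop"]] <-
        unname(tools::md5sum(pg$genepop))
      geno <- read_genepop(pg$genepop)
    }
    filt <- apply_filters(geno)
    flog <- attr(filt, "filter_log")
    for (nm in names(flog))
      message(sprintf("[popgen] %s: %s", nm,
                      paste(names(flog[[nm]]), flog[[nm]],
                            sep = "=", collapse = " ")))
    outs <- c(file.path(out_dir, "diversity.csv"),
              file.path(out_dir, "pairwise_fst.csv"),
              file.path(out_dir, "amova.json"))
    rar <- min(table(filt$ind$pop))
    div <- diversity_summary(filt, rarefaction_n = min(16, rar))
    write.csv(div, outs[1], row.names = FALSE)
    pw <- pairwise_fst(filt, n_perm = pg$n_perm %||% 1023, seed = seed)
    write.csv(pw, outs[2], row.names = FALSE)
    am <- amova(filt, n_perm = pg$n_perm %||% 1023, seed = seed)
    jsonlite::write_json(as.list(glance(am)), outs[3],
                         auto_unbox = TRUE, digits = NA)
    log_stage("popgen", seed, t0, outs)
  }
  if (!is.null(st$forward_sim)) {
    t0 <- tic(); seed <- base_seed + 606L
    fs <- st$forward_sim
    model <- forward_model(
      n_demes = fs$n_demes %||% 8L, N = fs$N %||% 400,
      marker_type = fs$marker_type %||% "biallelic_diploid",
      init_freq = if (identical(fs$marker_type, "haplotypic"))
        sample_haplotype_frequencies(fs$n_haplotypes %||% 10, seed = seed)
      else sample_allele_frequencies(fs$n_loci %||% 1122, seed = seed),
      mutation_rate = fs$mutation_rate %||% 0,
      migrants_per_generation = fs$m %||% 0,
      sample_sizes = fs$sample_sizes %||% 30)
    res <- switch(
      fs$scenario %||% "power",
      drift = simulate_drift_fst(model, fs$t %||% 2,
                                 replicates = fs$replicates %||% 200,
                                 seed = seed),
      migration = equilibrium_migration_fst(model, seed = seed),
      power = powsim_power(model, fs$t %||% 2,
                           replicates = fs$replicates %||% 200,
                           seed = seed))
    fpath <- file.path(out_dir, "forward_sim.json")
    jsonlite::write_json(as.list(res), fpath, auto_unbox = TRUE,
                         digits = NA)
    log_stage("forward_sim", seed, t0, fpath)
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
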