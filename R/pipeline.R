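cfg_get <- function(config, path, default = NULL, required = FALSE) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      if (required) stop("config field missing: ", path)
      return(default)
    }
    node <- node[[k]]
  }
  node
}

log_stage <- function(stage, ...) {
  message(sprintf("[lemap] %s | %s", stage,
                  paste(sprintf("%s=%s", names(list(...)),
                                unlist(lapply(list(...), format))),
                        collapse = " ")))
}

#' Run the end-to-end entropy-mapping pipeline
#'
#' Wires the modules from one YAML (or list) configuration: acquire the
#' input (a seeded phantom, or CT + mask files), compute the local entropy
#' map, smooth, optionally normalize, extract VOI statistics, classify the
#' lesion pattern, optionally render a fusion slice, and write every
#' artifact plus a JSON manifest (inputs, parameters, package version, seed)
#' sufficient to reproduce the run bit-identically.
#'
#' Config schema (all stages under the top level):
#' \preformatted{
#' seed: 7                    # required when a phantom is generated
#' output_dir: out
#' phantom: {pattern: peripheral_rim_complete, ...}   # or:
#' input: {ct: ct.nii.gz, tumor: tumor.nii.gz, liver: liver.nii.gz}
#' kernel: {k: 5, bin_width: 1, padding: reflect}
#' smooth: {sigma: 1}
#' normalize: {enabled: false, method: divide}
#' stats: {stage: smoothed}   # raw | smoothed | normalized
#' classify: {z_cutoff: 1, rim_width: 3}
#' render: {enabled: false, axis: axial, index: 32, palette: viridis,
#'          alpha: 0.5}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return Invisibly, a list of output paths and the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  out_dir <- cfg_get(config, "output_dir", "lemap_out")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  has_phantom <- !is.null(config$phantom)
  has_input <- !is.null(config$input)
  if (has_phantom == has_input)
    stop("config must provide exactly one of 'phantom' or 'input'")

  if (has_phantom) {
    seed <- cfg_get(config, "seed")
    if (is.null(seed))
      stop("config field missing: seed (required for the stochastic ",
           "phantom stage; refusing silent nondeterminism)")
    ph_args <- config$phantom
    ph_args$seed <- seed
    spec <- do.call(phantom_spec, ph_args)
    t0 <- proc.time()[["elapsed"]]
    ph <- generate_phantom(spec)
    ct <- ph$ct; tumor <- ph$tumor; liver <- ph$liver
    log_stage("phantom", pattern = spec$pattern, seed = seed,
              s = round(proc.time()[["elapsed"]] - t0, 3))
  } else {
    for (f in c("ct", "tumor")) {
      p <- cfg_get(config, paste0("input.", f), required = TRUE)
      if (!file.exists(p)) stop("config field input.", f,
                                ": file not found: ", p)
    }
    ct <- read_volume(config$input$ct)
    tumor <- read_mask(config$input$tumor, ct)
    liver <- NULL
    if (!is.null(config$input$liver)) liver <- read_mask(config$input$liver, ct)
    log_stage("input", ct = config$input$ct)
  }

  normalize_on <- isTRUE(cfg_get(config, "normalize.enabled", FALSE))
  if (is.null(liver) && normalize_on)
    stop("config: normalize.enabled requires input.liver ",
         "(normalization divides by the liver-reference mean)")

  cfg <- kernel_config(k = cfg_get(config, "kernel.k", 5L),
                       bin_width = cfg_get(config, "kernel.bin_width", 1),
                       padding = cfg_get(config, "kernel.padding", "reflect"))
  t0 <- proc.time()[["elapsed"]]
  map_raw <- local_entropy_map(ct, cfg)
  log_stage("entropy", k = cfg$k, padding = cfg$padding,
            s = round(proc.time()[["elapsed"]] - t0, 3))
  sigma <- cfg_get(config, "smooth.sigma", 1)
  map_smooth <- smooth_map(map_raw, sigma = sigma)
  log_stage("smooth", sigma = sigma)
  map_norm <- NULL
  if (normalize_on) {
    map_norm <- normalize_map(map_smooth, liver,
                              method = cfg_get(config, "normalize.method",
                                               "divide"))
    log_stage("normalize", reference_mean = round(map_norm$reference_mean, 5))
  }

  stage <- cfg_get(config, "stats.stage", "smoothed")
  stats_map <- switch(stage, raw = map_raw, smoothed = map_smooth,
                      normalized = {
                        if (is.null(map_norm))
                          stop("config: stats.stage 'normalized' requires ",
                               "normalize.enabled")
                        map_norm
                      },
                      stop("config: stats.stage must be raw/smoothed/normalized"))
  st <- extract_histogram_stats(stats_map, tumor)
  hu <- hounsfield_stats(ct, tumor)
  log_stage("stats", stage = stage, voxels = st$voi_voxel_count)

  paths <- list(map = file.path(out_dir, "entropy_map.nii.gz"),
                stats = file.path(out_dir, "stats.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_volume(if (normalize_on) map_norm else map_smooth, paths$map)
  utils::write.csv(rbind(as.data.frame(st), as.data.frame(hu)),
                   paths$stats, row.names = FALSE)

  pattern <- NULL
  if (!is.null(liver)) {
    pattern <- classify_lesion(map_smooth, tumor, liver,
                               z_cutoff = cfg_get(config, "classify.z_cutoff", 1),
                               rim_width = cfg_get(config, "classify.rim_width", 3L))
    paths$pattern <- file.path(out_dir, "pattern.csv")
    utils::write.csv(as.data.frame(pattern), paths$pattern, row.names = FALSE)
    log_stage("classify", label = pattern$label, subtype = pattern$rim_subtype)
  }

  if (isTRUE(cfg_get(config, "render.enabled", FALSE))) {
    idx <- cfg_get(config, "render.index", ceiling(dim(ct$data)[3] / 2))
    ras <- render_fusion(ct, map_smooth,
                         axis = cfg_get(config, "render.axis", "axial"),
                         index = idx,
                         alpha = cfg_get(config, "render.alpha", 0.5),
                         palette = cfg_get(config, "render.palette", "viridis"))
    paths$render <- file.path(out_dir, "fusion.png")
    save_raster_png(ras, paths$render)
    log_stage("render", axis = ras$axis, index = idx)
  }

  manifest <- list(package = "lemap",
                   version = as.character(utils::packageVersion("lemap")),
                   config = config,
                   outputs = paths[setdiff(names(paths), "manifest")])
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, stats = st, hu_stats = hu, pattern = pattern,
                 map = if (normalize_on) map_norm else map_smooth))
}
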