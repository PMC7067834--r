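#' Pipeline run configuration
#'
#' Collects every tunable of the quantification pipeline with its default.
#' The effective configuration is serialized (JSON) next to the outputs of
#' [run_pipeline()], so every run is reproducible from its report directory.
#'
#' @param volume_path path to the volume to quantify (or `NULL` when a volume
#'   is passed in memory).
#' @param voxel_size_nm voxel size override for containers without one.
#' @param out_dir output directory; `NULL` disables file output.
#' @param t_seed,t_keep hysteresis thresholds ([segment_lacunae()]).
#' @param median_radius median prefilter radius (voxels; `NULL` = scaled
#'   to the canalicular width, see [segment_lacunae()]).
#' @param max_lacuna_volume_um3 Haversian canal size cutoff.
#' @param min_lacuna_volume_um3 minimum lacuna volume kept.
#' @param scales_nm vesselness scales ([segment_canaliculi()]).
#' @param vessel_alpha,vessel_beta,vessel_c vesselness sensitivities.
#' @param vrg_alpha,vrg_beta,vrg_max_iter region-growing weights/iterations.
#' @param min_component_voxels canaliculi small-component cutoff.
#' @param r_grid_um Ca.N(r) distances (um).
#' @param seed integer seed recorded with the run.
#' @return list of class `lcn_config`.
#' @export
lcn_config <- function(volume_path = NULL, voxel_size_nm = NULL,
                       out_dir = NULL,
                       t_seed = NULL, t_keep = NULL, median_radius = NULL,
                       max_lacuna_volume_um3 = 2000,
                       min_lacuna_volume_um3 = 0,
                       scales_nm = NULL, vessel_alpha = 0.5,
                       vessel_beta = 0.5, vessel_c = NULL,
                       vrg_alpha = 1, vrg_beta = 0.5, vrg_max_iter = 20,
                       min_component_voxels = 5,
                       r_grid_um = default_r_grid(), seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "lcn_config"
  cfg
}

#' Quantify one volume end to end
#'
#' Runs the full single-resolution pipeline on a gray-level volume: lacunar
#' segmentation (median filter, hysteresis, Haversian removal, labeling),
#' canalicular segmentation (vesselness, maximum-entropy initialization,
#' variational region growing, small-component removal), Voronoi
#' tessellation, ellipsoid fitting, and the lacunar and canalicular metric
#' tables.
#'
#' @param vol an [scalar_volume()].
#' @param config an [lcn_config()].
#' @return list of class `lcn_quantification`: `lacunae` and `canaliculi`
#'   metric tables, `labels`, `canals_mask`, `haversian_mask`, `partition`,
#'   `ellipsoids`, `bv_mm3`, and the segmentation by-products.
#' @export
quantify_volume <- function(vol, config = lcn_config()) {
  stopifnot(inherits(vol, "lcn_volume"), inherits(config, "lcn_config"))
  seg <- segment_lacunae(vol, t_seed = config$t_seed, t_keep = config$t_keep,
                         median_radius = config$median_radius,
                         max_lacuna_volume_um3 = config$max_lacuna_volume_um3,
                         min_lacuna_volume_um3 = config$min_lacuna_volume_um3)
  can <- segment_canaliculi(vol, lacunae = seg$labels > 0,
                            scales_nm = config$scales_nm,
                            alpha = config$vessel_alpha,
                            beta = config$vessel_beta, c = config$vessel_c,
                            alpha_data = config$vrg_alpha,
                            beta_shape = config$vrg_beta,
                            max_iter = config$vrg_max_iter,
                            min_component_voxels = config$min_component_voxels)
  h <- vol$voxel_size_nm
  bv <- bone_volume(dim(vol$values), h, canals = seg$canals)
  if (attr(seg$labels, "n_labels") == 0) {
    lm <- lacuna_metrics(seg$labels, NULL, list(), bv, h)
    return(structure(list(lacunae = lm, canaliculi = NULL, labels = seg$labels,
                          canals_mask = can$canaliculi,
                          haversian_mask = seg$canals, partition = NULL,
                          ellipsoids = list(), bv_mm3 = bv,
                          thresholds = list(t_seed = seg$t_seed,
                                            t_keep = seg$t_keep,
                                            vessel = can$threshold)),
                     class = "lcn_quantification"))
  }
  part <- voronoi_partition(seg$labels, h)
  ells <- fit_lacunae(seg$labels, h)
  lm <- lacuna_metrics(seg$labels, part, ells, bv, h)
  cm <- canal_metrics(can$canaliculi, seg$labels, part, ells, bv, h,
                      r_grid_um = config$r_grid_um,
                      lacuna_surfaces_um2 = lm$per_lacuna[["Lc.S"]])
  structure(list(lacunae = lm, canaliculi = cm, labels = seg$labels,
                 canals_mask = can$canaliculi, haversian_mask = seg$canals,
                 partition = part, ellipsoids = ells, bv_mm3 = bv,
                 thresholds = list(t_seed = seg$t_seed, t_keep = seg$t_keep,
                                   vessel = can$threshold)),
            class = "lcn_quantification")
}

#' @export
print.lcn_quantification <- function(x, ...) {
  cat("<lcn_quantification>\n")
  print(x$lacunae$summary, row.names = FALSE)
  if (!is.null(x$canaliculi)) print(x$canaliculi$summary, row.names = FALSE)
  invisible(x)
}

#' Run the pipeline from a configuration, with report files
#'
#' Reads the configured volume (unless one is passed in memory), quantifies
#' it with [quantify_volume()], and -- when `out_dir` is set -- writes the
#' lacunar and canalicular summary CSVs, the per-distance Ca.N(r) CSV, the
#' label volume (MHD), and the effective configuration with the logged
#' thresholds as JSON. Rerunning the same configuration and seed reproduces
#' the outputs exactly.
#'
#' @param config an [lcn_config()].
#' @param vol optional in-memory [scalar_volume()] (overrides `volume_path`).
#' @return the [quantify_volume()] result, invisibly when writing files.
#' @export
run_pipeline <- function(config = lcn_config(), vol = NULL) {
  stopifnot(inherits(config, "lcn_config"))
  if (is.null(vol)) {
    if (is.null(config$volume_path)) stop("no volume: set volume_path or pass vol")
    vol <- read_volume(config$volume_path, config$voxel_size_nm)
  }
  q <- quantify_volume(vol, config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(q$lacunae$summary,
              file.path(config$out_dir, "lacunae_metrics.csv"),
              row.names = FALSE)
    if (!is.null(q$canaliculi)) {
      write.csv(q$canaliculi$summary,
                file.path(config$out_dir, "canaliculi_metrics.csv"),
                row.names = FALSE)
      write.csv(q$canaliculi$ca_n,
                file.path(config$out_dir, "ca_n_profile.csv"),
                row.names = FALSE)
    }
    lab_vol <- scalar_volume(array(as.numeric(q$labels), dim = dim(q$labels)),
                             vol$voxel_size_nm, vol$origin_um)
    write_volume(lab_vol, file.path(config$out_dir, "lacuna_labels.mhd"))
    eff <- config
    class(eff) <- NULL
    eff$logged_thresholds <- q$thresholds
    jsonlite::write_json(eff, file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(q))
  }
  q
}

#' Quantify a registered fine/coarse pair of volumes
#'
#' The dual-resolution comparison workflow: registers the fine volume inside
#' the coarse one by phase correlation ([register_pair()]), crops the
#' site-matched coarse VOI, quantifies both with the same configuration, and
#' returns both quantifications with the registration offset.
#'
#' @param fine,coarse [scalar_volume()]s of the same site.
#' @param factor integer voxel-size ratio coarse/fine.
#' @param config an [lcn_config()] applied to both volumes.
#' @return list: `fine` and `coarse` quantifications, `offset`, `pcm`.
#' @export
quantify_pair <- function(fine, coarse, factor, config = lcn_config()) {
  reg <- register_pair(fine, coarse, factor)
  qf <- quantify_volume(fine, config)
  qc <- quantify_volume(reg$pcm, config)
  list(fine = qf, coarse = qc, offset = reg$offset, pcm = reg$pcm)
}
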