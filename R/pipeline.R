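#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()] with every analysis
#' parameter at its published default: discard 10 volumes, 3 mm / 3 degree
#' motion exclusion, 0.01-0.1 Hz band, gray-matter probability threshold
#' 0.3, degree threshold r >= 0.25, 6 mm FWHM smoothing, voxel p < 0.005
#' with cluster p < 0.05, impairment cut z < -1, and CSF A\eqn{\beta}42
#' positivity below 192 pg/mL. Configs round-trip through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer master seed; every stochastic stage derives its
#'   stream from it.
#' @param simulate Generate the cohort and phantoms (default `TRUE`). When
#'   `FALSE`, `paths$phenotypes` (TSV) and `paths$images` (directory of
#'   [write_bold_run()] prefixes) must exist.
#' @param longitudinal Also generate/analyze month-6 runs and the
#'   group-by-time interaction (default `FALSE`).
#' @param write_cleaned Also write each cleaned 4D run to disk (default
#'   `FALSE`: standardized/smoothed maps and their provenance JSON are always
#'   written, but cleaned series are large at study scale).
#' @param cohort,phantom,preprocess,centrality,stats,paths Named lists
#'   overriding individual stage parameters (see Details in the package
#'   vignette).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("objscd_run_"), seed = 1L,
                            simulate = TRUE, longitudinal = FALSE,
                            write_cleaned = FALSE,
                            cohort = list(), phantom = list(), preprocess = list(),
                            centrality = list(), stats = list(), paths = list()) {
  # like modifyList() but keeps explicit NULL overrides as NULL entries,
  # so configs survive YAML round-trips unchanged
  merge_cfg <- function(base, override) {
    for (nm in names(override)) base[nm] <- list(override[[nm]])
    base
  }
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = simulate,
    longitudinal = longitudinal,
    write_cleaned = write_cleaned,
    cohort = merge_cfg(list(
      n_per_group = c(42L, 29L, 55L), preset = "cross_sectional",
      n_normative = 239L, noise_scale = 1, missing_rate = 0
    ), cohort),
    phantom = merge_cfg(list(
      grid = c(24L, 24L, 16L), voxel_size_mm = 3.31, n_volumes = 140L,
      tr_s = 3, excess_motion_fraction = 0, n_imaging_per_group = NULL
    ), phantom),
    preprocess = merge_cfg(list(
      discard = 10L, trans_limit_mm = 3, rot_limit_deg = 3,
      low = 0.01, high = 0.1, bandpass_method = "ideal"
    ), preprocess),
    centrality = merge_cfg(list(
      gm_threshold = 0.3, r_threshold = 0.25, fwhm_mm = 6,
      standardize_method = "zscore"
    ), centrality),
    stats = merge_cfg(list(
      voxel_p = 0.005, cluster_p = 0.05, n_perm = 1000L, connectivity = 26L,
      z_cut = -1, abeta_cutoff = 192
    ), stats),
    paths = merge_cfg(list(phenotypes = NULL, images = NULL), paths)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> seed ", x$seed, ", out_dir ", x$out_dir, "\n", sep = "")
  cat("  simulate:", x$simulate, " longitudinal:", x$longitudinal, "\n")
  invisible(x)
}

#' Serialize a pipeline config as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, list(
    out_dir = cfg$out_dir, seed = cfg$seed, simulate = cfg$simulate,
    longitudinal = cfg$longitudinal,
    write_cleaned = isTRUE(cfg$write_cleaned),
    cohort = cfg$cohort, phantom = cfg$phantom,
    preprocess = cfg$preprocess, centrality = cfg$centrality, stats = cfg$stats,
    paths = cfg$paths
  ))
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$simulate) {
    if (is.null(config$paths$phenotypes) || !file.exists(config$paths$phenotypes)) {
      stopf("validation: `paths$phenotypes` must exist when simulate is disabled")
    }
    if (is.null(config$paths$images) || !dir.exists(config$paths$images)) {
      stopf("validation: `paths$images` must exist when simulate is disabled")
    }
  }
  if (config$preprocess$low >= config$preprocess$high) {
    stopf("validation: band low >= high")
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain simulate -> classify -> preprocess -> centrality
#' -> inference under one configuration and seed, writing every intermediate
#' artifact (phenotype TSVs, QC report, NIfTI maps, cluster tables, run
#' manifest JSON) into `config$out_dir`. Identical config and seed give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param log Print stage progress (default `TRUE`).
#' @return A list of class `pipeline_result`: classification, QC table,
#'   per-metric cluster results, ROI tables, post hoc tests, optional
#'   longitudinal interactions, and the run manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), log = TRUE) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("objscd")),
                   seed = config$seed, started = format(t0), stages = list())
  logf <- file.path(config$out_dir, "pipeline.log")
  say <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(msg, "\n", file = logf, append = TRUE)
    if (log) message(msg)
  }
  record <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(..., seed = config$seed)
  }

  ## ---- stage: simulate / load phenotypes -------------------------------
  timepoints <- if (config$longitudinal) c("baseline", "month6") else "baseline"
  if (config$simulate) {
    say("simulate: generating cohort (%s)", paste(config$cohort$n_per_group, collapse = "/"))
    cspec <- cohort_spec(
      n_per_group = config$cohort$n_per_group, preset = config$cohort$preset,
      n_normative = config$cohort$n_normative, noise_scale = config$cohort$noise_scale,
      missing_rate = config$cohort$missing_rate, seed = child_seed(config$seed, "cohort")
    )
    cohort <- generate_phenotypes(cspec)
    phen <- cohort$phenotypes
    pspec <- phantom_spec(
      grid = config$phantom$grid, voxel_size_mm = config$phantom$voxel_size_mm,
      n_volumes = config$phantom$n_volumes, tr_s = config$phantom$tr_s,
      excess_motion_fraction = config$phantom$excess_motion_fraction,
      seed = child_seed(config$seed, "phantom")
    )
  } else {
    say("load: reading phenotypes from %s", config$paths$phenotypes)
    phen <- read_phenotypes(config$paths$phenotypes)
    cohort <- NULL
    pspec <- NULL
  }
  write_phenotypes(phen, file.path(config$out_dir, "phenotypes.tsv"))
  write_phenotypes(phenotype_dictionary(),
                   file.path(config$out_dir, "phenotypes_dictionary.tsv"))
  record("simulate", phenotypes = "phenotypes.tsv",
         dictionary = "phenotypes_dictionary.tsv",
         n = nrow(phen), simulated = config$simulate)

  ## ---- stage: classify -------------------------------------------------
  say("classify: fitting norms and applying actuarial criteria")
  cls <- classify_cohort(phen, z_cut = config$stats$z_cut,
                         abeta_cutoff = config$stats$abeta_cutoff)
  write_norms(cls$norms, file.path(config$out_dir, "norms.json"))
  write_phenotypes(cls$labels, file.path(config$out_dir, "labels.tsv"))
  demo <- demographics_table(dplyr::filter(cls$labels, !.data$is_normative %in% TRUE))
  write_phenotypes(demo, file.path(config$out_dir, "demographics.tsv"))
  record("classify", labels = "labels.tsv", norms = "norms.json",
         demographics = "demographics.tsv",
         counts = as.list(setNames(cls$counts$n, cls$counts$label)))

  ## ---- stage: preprocess + centrality ----------------------------------
  analysis <- phen[!(phen$is_normative %in% TRUE), ]
  if (!is.null(config$phantom$n_imaging_per_group)) {
    analysis <- analysis %>%
      dplyr::group_by(.data$group) %>%
      dplyr::slice_head(n = config$phantom$n_imaging_per_group) %>%
      dplyr::ungroup()
  }
  say("preprocess+centrality: %d subjects x %d timepoint(s)",
      nrow(analysis), length(timepoints))
  map_dir <- file.path(config$out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)

  qc_rows <- list()
  maps <- list(DC = list(), EC = list())
  mask <- NULL
  for (tp in timepoints) maps$DC[[tp]] <- maps$EC[[tp]] <- list()
  for (i in seq_len(nrow(analysis))) {
    pid <- analysis$participant_id[i]
    for (tp in timepoints) {
      run <- if (config$simulate) {
        generate_bold_run(pspec, pid, analysis$group[i], tp)
      } else {
        read_bold_run(file.path(config$paths$images, paste0(pid, "_", tp)),
                      tr = config$phantom$tr_s)
      }
      clean <- preprocess_run(
        run, discard = config$preprocess$discard,
        low = config$preprocess$low, high = config$preprocess$high,
        trans_limit_mm = config$preprocess$trans_limit_mm,
        rot_limit_deg = config$preprocess$rot_limit_deg,
        bandpass_method = config$preprocess$bandpass_method
      )
      qc <- clean$qc
      qc$participant_id <- pid
      qc$timepoint <- tp
      qc_rows[[length(qc_rows) + 1]] <- qc
      if (qc$exclude) next
      if (is.null(mask)) {
        mask <- gm_mask(clean$run$gm_prob %||% run$gm_prob,
                        threshold = config$centrality$gm_threshold)
      }
      if (isTRUE(config$write_cleaned)) {
        write_bold_run(clean$run, file.path(map_dir, paste0(pid, "_", tp, "_clean")))
      }
      for (metric in c("DC", "EC")) {
        m <- if (metric == "DC") {
          degree_centrality(clean, mask, r_threshold = config$centrality$r_threshold)
        } else {
          fast_ecm(clean, mask)
        }
        m <- smooth_map(standardize_map(m, config$centrality$standardize_method),
                        fwhm_mm = config$centrality$fwhm_mm,
                        voxel_size_mm = config$phantom$voxel_size_mm)
        stem <- file.path(map_dir, paste0(pid, "_", tp, "_", tolower(metric)))
        write_centrality_map(m, paste0(stem, ".nii.gz"),
                             voxel_size_mm = config$phantom$voxel_size_mm)
        jsonlite::write_json(
          list(participant = pid, timepoint = tp, metric = metric,
               params = m$params, standardized = m$standardized,
               smoothed_fwhm = m$smoothed_fwhm, provenance = m$provenance),
          paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
        maps[[metric]][[tp]][[pid]] <- m
      }
    }
  }
  qc_tab <- purrr::list_rbind(qc_rows)
  write_phenotypes(qc_tab, file.path(config$out_dir, "qc.tsv"))
  record("preprocess", qc = "qc.tsv", excluded = sum(qc_tab$exclude))

  ## ---- stage: inference ------------------------------------------------
  keep_ids <- names(maps$DC[["baseline"]])
  if (config$longitudinal) {
    keep_ids <- intersect(keep_ids, names(maps$DC[["month6"]]))
  }
  design <- analysis[match(keep_ids, analysis$participant_id),
                     c("participant_id", "group", "age", "sex", "education")]
  design$mean_fd <- qc_tab$mean_fd[match(paste(keep_ids, "baseline"),
                                         paste(qc_tab$participant_id, qc_tab$timepoint))]
  results <- list()
  for (metric in c("DC", "EC")) {
    say("inference: %s ANCOVA + permutation cluster correction", metric)
    base_maps <- maps[[metric]][["baseline"]][keep_ids]
    sm <- voxelwise_ancova(base_maps,
                           design[, c("group", "age", "sex", "education", "mean_fd")])
    cr <- cluster_correct(sm, voxel_p = config$stats$voxel_p,
                          cluster_p = config$stats$cluster_p,
                          n_perm = config$stats$n_perm,
                          connectivity = config$stats$connectivity,
                          seed = child_seed(config$seed, "perm", metric))
    write_phenotypes(cr$clusters, file.path(config$out_dir,
                                            paste0(tolower(metric), "_clusters.tsv")))
    fvals <- array(0, dim(mask)); fvals[mask] <- sm$f
    RNifti::writeNifti(RNifti::asNifti(fvals), file.path(
      map_dir, paste0(tolower(metric), "_fmap.nii.gz")))
    res <- list(stat_map = sm, clusters = cr)
    if (nrow(cr$clusters) > 0) {
      roi <- extract_roi_means(base_maps, cr)
      res$roi <- tibble::tibble(participant_id = keep_ids, group = design$group,
                                roi_mean = roi)
      res$posthoc <- purrr::list_rbind(purrr::map(
        list(c("Obj-SCD", "CN"), c("Obj-SCD", "MCI"), c("MCI", "CN")),
        function(pr) posthoc_lsd(roi, design[, c("group", "age", "sex",
                                                 "education", "mean_fd")], pr)
      ))
      write_phenotypes(res$posthoc, file.path(config$out_dir,
                                              paste0(tolower(metric), "_posthoc.tsv")))
      if (config$longitudinal) {
        long_tab <- purrr::list_rbind(purrr::map(c("baseline", "month6"), function(tp) {
          tibble::tibble(
            subject = keep_ids, group = design$group, time = tp,
            value = extract_roi_means(maps[[metric]][[tp]][keep_ids], cr)
          )
        }))
        res$interaction <- purrr::list_rbind(purrr::map(
          list(c("CN", "Obj-SCD"), c("CN", "MCI"), c("Obj-SCD", "MCI")),
          function(pr) dplyr::mutate(rm_interaction(long_tab, pr),
                                     contrast = paste(pr, collapse = " vs "))
        ))
        write_phenotypes(res$interaction, file.path(
          config$out_dir, paste0(tolower(metric), "_interaction.tsv")))
      }
    }
    results[[metric]] <- res
  }
  record("inference",
         dc_clusters = nrow(results$DC$clusters$clusters),
         ec_clusters = nrow(results$EC$clusters$clusters))

  manifest$finished <- format(Sys.time())
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done in %.1f s", manifest$elapsed_s)
  structure(list(classification = cls, qc = qc_tab, results = results,
                 design = design, cohort = cohort, manifest = manifest,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$config$seed, "\n", sep = "")
  print(x$classification$counts)
  for (m in names(x$results)) {
    cl <- x$results[[m]]$clusters$clusters
    cat(m, ": ", nrow(cl), " cluster(s), ", sum(cl$significant), " significant\n", sep = "")
  }
  invisible(x)
}
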