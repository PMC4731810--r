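#' Compute all camouflage metrics for one nest under one or more predators
#'
#' For each predator visual system: maps the calibrated stack to cone catches,
#' builds the luminance channel, computes mean luminance and contrast of
#' target and background, the 32-bin luminance-histogram difference, the
#' 17-scale pattern-energy difference, and (optionally) the colour-cluster
#' best/mean JND match of the most abundant target colour against the
#' surrounds. One record per visual system.
#'
#' @param image calibrated [msimage].
#' @param regions a [region_set()].
#' @param predators a [predator_model()] or list of them.
#' @param nest_id,species,target_kind record identifiers (`target_kind` is
#'   "egg" or "adult" depending on which appearance selection acts on).
#' @param colour run the colour-clustering match metrics (the slowest stage;
#'   set `FALSE` for pattern/luminance-only runs).
#' @param local_thresh,global_thresh,max_colours,coverage_stop passed to
#'   [cluster_colours()].
#' @return data.frame with one row per visual system (a camouflage record).
#' @export
run_nest <- function(image, regions, predators, nest_id = "nest",
                     species = NA_character_,
                     target_kind = c("egg", "adult"), colour = TRUE,
                     local_thresh = 0.05, global_thresh = 1,
                     max_colours = 32L, coverage_stop = 0.99) {
  target_kind <- match.arg(target_kind)
  if (inherits(predators, "predator_model")) predators <- list(predators)
  records <- lapply(predators, function(pm) {
    sys <- pm$system
    cone <- apply_mapping(image, pm$mapping, system = sys)
    lum <- luminance_image(cone, sys)
    spec_t <- pattern_spectrum(lum, regions$target)
    spec_b <- pattern_spectrum(lum, regions$background)
    rec <- data.frame(
      nest_id = nest_id, species = species, visual_system = sys$name,
      target_kind = target_kind,
      mean_luminance_target = mean_luminance(lum, regions$target),
      mean_luminance_background = mean_luminance(lum, regions$background),
      contrast_target = contrast(lum, regions$target),
      contrast_background = contrast(lum, regions$background),
      luminance_diff = luminance_diff(
        luminance_histogram(lum, regions$target),
        luminance_histogram(lum, regions$background)),
      pattern_diff = pattern_diff(spec_t, spec_b),
      best_jnd = NA_real_, mean_jnd = NA_real_)
    if (colour) {
      cl_t <- cluster_colours(cone, regions$target, sys$weber,
                              local_thresh, global_thresh,
                              max_colours, coverage_stop)
      cl_b <- cluster_colours(cone, regions$background, sys$weber,
                              local_thresh, global_thresh,
                              max_colours, coverage_stop)
      match <- colour_match_metrics(cl_t, cl_b, sys$weber)
      rec$best_jnd <- match$best_jnd
      rec$mean_jnd <- match$mean_jnd
    }
    rec
  })
  do.call(rbind, records)
}

#' Batch metric computation with per-nest error capture
#'
#' Runs [run_nest()] over a list of nests; a nest that fails (missing mask,
#' degenerate region, ...) is recorded in the `errors` attribute and the batch
#' continues.
#'
#' @param nests list of lists with elements `image`, `regions`, `nest_id` and
#'   optional `species`, `target_kind`.
#' @param predators passed to [run_nest()].
#' @param ... further arguments to [run_nest()].
#' @return records data.frame with attribute `errors` (named character vector,
#'   possibly empty).
#' @export
run_nests <- function(nests, predators, ...) {
  errors <- character(0)
  records <- list()
  for (nest in nests) {
    res <- tryCatch(
      run_nest(nest$image, nest$regions, predators,
               nest_id = nest$nest_id %||% "nest",
               species = nest$species %||% NA_character_,
               target_kind = nest$target_kind %||% "egg", ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[nest$nest_id %||% paste0("nest", length(errors) + 1L)] <-
        conditionMessage(res)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  out <- if (length(records)) do.call(rbind, records) else NULL
  attr(out, "errors") <- errors
  out
}

#' Associate camouflage records with nest fates
#'
#' Joins per-nest camouflage records to the outcome table on `nest_id`,
#' then per visual system and per requested metric fits a median-split
#' Kaplan-Meier pair of curves and a Cox proportional-hazards model (species
#' as strata when present). Optionally writes `km_curves.csv`,
#' `cox_results.json` and `summary_stats.csv` to `out_dir`.
#'
#' @param records data.frame from [run_nest()]/[run_nests()]; duplicated
#'   `nest_id` within one visual system and target kind is an error.
#' @param outcomes data.frame with `nest_id`, `time_days`, `event`.
#' @param metrics camouflage metric columns to analyse.
#' @param use_strata stratify the Cox fit by species when available.
#' @param out_dir optional output directory.
#' @return list with `km` (curves per system x metric), `cox` (coefficient
#'   tables), `summaries` (per-species metric summaries) and `unmatched`
#'   (nest ids that failed to join).
#' @export
run_study <- function(records, outcomes,
                      metrics = c("contrast_target", "pattern_diff"),
                      use_strata = TRUE, out_dir = NULL) {
  key <- paste(records$nest_id, records$visual_system, records$target_kind)
  if (anyDuplicated(key))
    stop("duplicated nest_id within a visual system: ",
         paste(unique(records$nest_id[duplicated(key)]), collapse = ", "))
  merged <- merge(records, outcomes, by = "nest_id",
                  suffixes = c("", ".outcome"))
  unmatched <- setdiff(union(records$nest_id, outcomes$nest_id),
                       merged$nest_id)
  if (!nrow(merged)) stop("no records joined to outcomes")
  km <- list(); cox <- list()
  for (vs in unique(merged$visual_system)) {
    sub <- merged[merged$visual_system == vs, ]
    for (m in metrics) {
      tag <- paste(vs, m, sep = ".")
      grp <- median_split(sub[[m]])
      curves <- kaplan_meier(sub, grp)
      curves$visual_system <- vs
      curves$metric <- m
      km[[tag]] <- curves
      strat <- if (use_strata && "species" %in% names(sub) &&
                   length(unique(sub$species)) > 1) sub$species else NULL
      cox[[tag]] <- tryCatch(
        cbind(visual_system = vs, metric = m,
              cox_ph(sub, setNames(sub[m], m), strata = strat)),
        error = function(e) {
          warning("Cox fit skipped for ", tag, ": ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
    }
  }
  summaries <- do.call(rbind, lapply(split(merged, merged[c("species", "visual_system")]),
    function(d) {
      if (!nrow(d)) return(NULL)
      do.call(rbind, lapply(metrics, function(m) data.frame(
        species = d$species[1], visual_system = d$visual_system[1], metric = m,
        n = nrow(d), mean = mean(d[[m]]), min = min(d[[m]]),
        max = max(d[[m]]), sd = sd(d[[m]]))))
    }))
  rownames(summaries) <- NULL
  out <- list(km = do.call(rbind, km), cox = do.call(rbind, cox),
              summaries = summaries, unmatched = unmatched)
  if (!is.null(out$km)) rownames(out$km) <- NULL
  if (!is.null(out$cox)) rownames(out$cox) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out$km, file.path(out_dir, "km_curves.csv"), row.names = FALSE)
    write.csv(out$summaries, file.path(out_dir, "summary_stats.csv"),
              row.names = FALSE)
    jsonlite::write_json(out$cox %||% list(),
                         file.path(out_dir, "cox_results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' End-to-end synthetic recovery experiment (one replicate)
#'
#' Generates `n_nests` scenes along a target/background pattern-scale mismatch
#' gradient, runs the imaging pipeline (cone-catch mapping, luminance channel,
#' granularity spectra) to measure each nest's pattern difference, simulates
#' nest fates whose log hazard increases by `beta` per SD of the measured
#' pattern difference, and fits the Cox model to test whether the association
#' is recovered.
#'
#' @param seed replicate seed.
#' @param predator a [predator_model()]; built from the ferret system, a
#'   Gaussian camera and a seeded spectral library when omitted.
#' @param n_nests number of nests.
#' @param beta true log hazard ratio per SD of pattern difference.
#' @param max_pattern_scale mismatch gradient upper end (scenes span texture
#'   scale factors 1 to this value).
#' @param scene_size scene side, px.
#' @return one-row data.frame: `beta_hat`, `se`, `z`, `n_events`.
#' @export
recovery_replicate <- function(seed, predator = NULL, n_nests = 150L,
                               beta = 1, max_pattern_scale = 4,
                               scene_size = 96L) {
  if (is.null(predator)) {
    lib <- generate_spectra(100, seed = seed)
    predator <- fit_predator_model(vs_ferret(), lib, camera_gaussian())
  }
  sys <- predator$system
  scale_grad <- seq(1, max_pattern_scale, length.out = n_nests)
  pdiff <- vapply(seq_len(n_nests), function(i) {
    scene_seed <- (abs(seed) %% 2000000L) * 1000L + i
    sc <- generate_scene(scene_spec(size = scene_size,
                                    pattern_scale = scale_grad[i],
                                    seed = scene_seed))
    cone <- apply_mapping(sc$image, predator$mapping, system = sys)
    lum <- luminance_image(cone, sys)
    pattern_diff(pattern_spectrum(lum, sc$regions$target),
                 pattern_spectrum(lum, sc$regions$background))
  }, numeric(1))
  study <- generate_study(study_spec(n_nests = n_nests, beta = beta,
                                     seed = seed),
                          mismatch = pdiff)
  fit <- cox_ph(study, setNames(study["mismatch"], "pattern_diff"))
  data.frame(beta_hat = fit$beta, se = fit$se, z = fit$z,
             n_events = sum(study$event))
}
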